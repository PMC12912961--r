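# oligocount

Inference of membrane-protein oligomeric state from single-molecule TIRF
copy-number counting, written for reconstitution experiments in which a
protein (e.g. the synaptic priming factor Munc13-1) clusters on lipid
microdomains and its per-cluster copy number is measured by photobleaching.
The package is aimed at single-molecule biophysicists who have per-cluster
copy numbers (or raw bleaching traces) and want a defensible answer to "are
these monomers, trimers, or hexamers — and what does that imply for vesicle
capture?"

## What it computes

1. **Copy numbers from bleaching traces.** Small clusters bleach in
   discrete steps: change points are found by penalized binary segmentation
   and counted on the unit-step lattice. Large clusters bleach smoothly:
   `N = round(I0/a)` from an exponential-decay fit, with the single-
   fluorophore unit step `a` calibrated from the small clusters of the same
   experiment.
2. **Oligomeric state.** A dual Poisson mixture in which monomers (mean
   `m`) and fixed-size K-mers (mean `k`) are independently Poisson within
   each cluster:

   `P_Total(N) = sum_j Pois(j; k) * Pois(N - K*j; m)`

   `m` is fitted on the sub-K histogram bins, `k = (mean(N) - m)/K` needs no
   fit, and candidate K are ranked by the inverse squared-error score `V`
   and the weighted relative-error score `O` over `N = 1..10`.
3. **Cooperative vesicle capture.** The latent oligomer-count posterior
   `P_n(N)` feeds `P_bind(N) = sum p_n P_n(N)`; the per-oligomer-count
   capture probabilities `p_n` are fitted from `(N, bound)` observations by
   Bernoulli maximum likelihood.
4. **Quench-corrected lipid enrichment.** For two-channel domain images,
   segmentation plus a fluorescence-redistribution estimator that corrects
   for in-domain self-quenching and is exactly the density ratio under
   uniform enrichment.
5. **Synthetic data.** A fully seeded generator for cluster compositions,
   capture outcomes, bleaching traces and domain-image pairs with known
   ground truth, so the entire chain is testable without a microscope.

## Worked example

```r
library(oligocount)

cfg <- synthetic_config(seed = 42, K = 3, monomer_mean = 2.2,
                        oligomer_mean = 1.5, n_clusters = 878,
                        capture_probs = c(0, 0.17, 0.55, 1))
report <- run_pipeline(cfg)
report
#> Pipeline report: 843 clusters, mean N = 6.915
#>   selected oligomer size: K = 3 (V), K = 3 (O); m = 2.381, k = 1.511
#>   capture probabilities: 0, 0.184, 0.664, 1
```

Reading the output: of 878 generated clusters, 843 contain at least one
fluorophore and are observable (average 6.9 copies each); the K-scan picks
trimers by both scores; the refitted monomer and trimer means land near the
generating values (2.2 and 1.5 — the small upward shift in `m` is the
truncation bias of conditioning on observable clusters, discussed in the
vignette), and the refitted capture probabilities recover the generating
0.17/0.55/1 for one, two, and three or more trimers to within sampling
error at this sample size. The same functions accept experimental cluster tables
(`read_cluster_table()`) and traces (`read_bleach_traces()`); see the
vignette in `vignettes/oligomer-counting-methods.Rmd` for the models,
assumptions and numerical choices.

Individual stages are exposed directly, e.g.:

```r
pred <- predict_dual_poisson(K = 3, m = 2.2, k = 1.5)
prediction_peaks(pred, 2:10)
#> [1] 4 7

oligomer_posterior(19, list(K = 3, m = 2.2, k = 1.5))$n
#> [1] 0 1 2 3 4 5 6
```

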
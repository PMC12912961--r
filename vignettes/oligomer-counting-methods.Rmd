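---
title: "Counting oligomers on membrane domains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting oligomers on membrane domains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocount)
```

## The scientific problem

Membrane proteins such as the synaptic priming factor Munc13-1 concentrate on
lipid microdomains — here, PI(4,5)P₂-rich domains assembled by a cationic
Syntaxin-1A juxtamembrane lipopeptide in supported bilayers — and may
oligomerize there. TIRF microscopy resolves each domain as a
diffraction-limited cluster and photobleaching reports how many labeled
copies `N` it holds, but it cannot directly reveal whether those copies are
free monomers, trimers, hexamers, or a mixture. `oligocount` implements the
statistical chain that turns per-cluster copy numbers into an oligomeric
state, and onward into a cooperative vesicle-capture model, together with a
seeded synthetic-data generator so that every stage can be validated against
known ground truth.

## The dual Poisson mixture

The central model assumes each cluster contains a Poisson-distributed number
of free monomers (mean `m`) and, independently, a Poisson-distributed number
of fixed-size K-mers (mean `k`). The observed copy number is
`N = monomers + K * oligomers`, so

$$P_{\mathrm{Total}}(N) = \sum_{j=0}^{\lfloor N/K\rfloor}
  \mathrm{Pois}(j; k)\,\mathrm{Pois}(N - Kj; m).$$

Fitting follows the asymmetric procedure used in the single-molecule
counting literature rather than a joint likelihood: `m` is fitted only on
the sub-K histogram bins (clusters with `N < K` cannot contain a K-mer), and
`k` then requires no fit at all — the mixture mean is `m + K k`, so
`k = (mean(N) - m)/K`. The sub-K objective includes the `exp(-k(m))`
zero-oligomer factor with `k` tied to the mean constraint; this makes even
the single sub-K bin of `K = 2` identifiable. Because the objective can be
multimodal in `m` (notably for `K = 2`), the optimizer scans a 256-point
grid over `(0, mean(N)]` and refines the best cell with golden-section
search.

Candidate oligomer sizes `K = 1..10` are ranked by two goodness-of-fit
scores computed over `N = 1..10`:

$$V = \Big[\sum_{N=1}^{10} (P_{\mathrm{obs}} - P_{\mathrm{Total}})^2\Big]^{-1},
\qquad
O = \Big[\sum_{N=1}^{10} \frac{(P_{\mathrm{obs}} -
P_{\mathrm{Total}})^2}{P_{\mathrm{obs}}}\Big]^{-1},$$

with empty observed bins excluded from `O` so that a large relative error on
a rare event cannot dominate. A perfect fit returns an `Inf` sentinel that
orders above every finite score, and ties — including multiple perfect fits —
break toward the smallest `K` (parsimony). For wild-type-like data
(`m = 2.2`, `k = 1.5`, `K = 3`, giving the measured average of 6.6 copies
per cluster) the predicted distribution has twin local maxima at `N = 4` and
`N = 7`:

```{r peaks}
pred <- predict_dual_poisson(K = 3, m = 2.2, k = 1.5)
prediction_peaks(pred, 2:10)
```

### Truncation bias, stated plainly

Empty clusters are invisible: the observed histogram is conditioned on
`N >= 1`, yet the fitting procedure (deliberately mirroring its experimental
source) compares it to the *unconditioned* model prediction and uses the
*observed* mean in `k = (mean - m)/K`. At the wild-type parameters
`P_Total(0)` is only ~0.025, but the resulting bias is measurable: on the
infinite-sample histogram the fitted `m` comes out 2.243 rather than 2.200
(+0.043) and `k` 1.542 rather than 1.500. Model *selection* is unaffected —
`K = 3` still wins both scores by nearly an order of magnitude — which is why
the package keeps the source procedure as the default and exposes
`condition_observable = TRUE` on `fit_dual_poisson()` only for sensitivity
analysis. The generator retains zero-copy draws (flagged `observable =
FALSE`) precisely so this bias stays quantifiable.

## Copy numbers from photobleaching traces

Two regimes, dispatched by `estimate_copy_number()`:

* **Step counting** (small clusters, default up to `stepwise_max = 6`; the
  experimental adjudication boundary of "5–6" is applied inclusively).
  Change points are found by binary segmentation minimizing the residual sum
  of squares, with a penalty of `1.5 * sigma^2 * log(T)` on the RSS reduction
  (`sigma` is a robust noise scale from first differences, so noise-free
  traces accept every true step). The fitted plateau levels are then snapped
  to the unit-step lattice anchored at the final plateau — each plateau is an
  integer number of surviving fluorophores — and the count is the sum of
  level decreases on the lattice. This makes a downward change of height `h`
  contribute `round(h/a)` (simultaneous double bleaches count as 2, dips
  below `min_step_fraction * a = 0.5 a` quantize to zero) while remaining
  robust to one-frame plateaus between adjacent bleach events, which plain
  per-step rounding miscounts. At noise `0.2 a` this recovers `N` exactly in
  at least 95% of simulated traces for every `N` in 1..6.
* **Exponential extrapolation** (large clusters). The smooth ensemble decay
  is fitted as `I0 exp(-rt) + b` (Levenberg–Marquardt, with a simplex
  fallback for the exactly-exponential corner where the LM gradient is
  singular), and the copy number is `round(I0 / a)` with `I0` taken as the
  first-frame intensity above baseline — the literal "initial intensity
  before bleaching" — so noise-free staircases are counted exactly at any
  `N`. Rounding is half-away-from-zero throughout.

The unit step `a` is calibrated per experiment by `calibrate_unit_step()`:
the mode of all detected step heights seeds a window `[0.5 a0, 1.5 a0)` that
separates single bleaches from simultaneous multiples, and `a` is the median
of the singles after one re-centering pass. Traces whose stepwise count
exceeds `stepwise_max`, or whose piecewise fit is beaten by the exponential
fit, take the exponential branch; near the boundary this residual-comparison
rule is a package choice, since the experimental adjudication between
"stepwise" and "smooth" profiles was visual. Blinking and labeling-efficiency
deconvolution are out of scope (labeling was >90% efficient in the source
experiments).

## From oligomer posterior to vesicle capture

Given the fitted mixture, the number of K-mers in a cluster of `N` copies
has posterior

$$P_n(N) = \frac{\mathrm{Pois}(n;k)\,\mathrm{Pois}(N-Kn;m)}
  {\sum_{j=0}^{\lfloor N/K\rfloor}\mathrm{Pois}(j;k)\,\mathrm{Pois}(N-Kj;m)},$$

so the largest observed wild-type cluster (`N = 19`) can hold at most six
trimers. If `n` oligomers capture a vesicle with probability `p_n` (with
`p_0 = 0`: clusters without oligomers showed no meaningful binding, and
`p_n` saturating at its last supplied value, mirroring the "3 or more"
grouping), the per-cluster capture probability is
`P_bind(N) = sum p_n P_n(N)`.

`fit_capture_probabilities()` estimates `p_1..p_nmax` from `(N, bound)`
observations by maximizing the Bernoulli likelihood under box constraints
(multistart L-BFGS-B). Likelihood was chosen over curve matching because the
source procedure for obtaining its capture probabilities is unstated; a
count-weighted least-squares-on-curve criterion (`criterion = "curve"`) is
provided for procedural mimicry, and an optional monotonicity constraint
(`monotone = TRUE`) is off by default. Since `P_bind` depends on the data
only through `N`, the likelihood is aggregated per copy number, making the
fit O(max N) per evaluation regardless of sample size.

## Quench-corrected domain enrichment

The PI(4,5)P₂ reporter self-quenches at domain densities, so in-domain
fluorescence only bounds the lipid density from below. The estimator uses
fluorescence redistribution between a with-lipopeptide image and a
without-lipopeptide image of the same total lipid: after background
subtraction, the deficit `dF = F_tot^without - F_tot^with` is the
fluorescence lost to quenching; redistributing it over the segmented domain
area gives

$$\mathrm{fold} = \frac{(F_{\mathrm{domain}} + \Delta F)/A_{\mathrm{dom}}}
  {F^{\mathrm{without}}_{\mathrm{tot}}/A_{\mathrm{tot}}}.$$

Under the module's model — uniform in-domain enrichment, uniform per-molecule
quench factor `q`, conserved molecule number — this identity is exact and
independent of `q`: writing the in-domain density as `E d0`,
`F_domain = c q E d0 A_dom` and `dF = c E d0 A_dom (1 - q)`, so the numerator
is `c E d0` and the ratio is exactly `E`. The tests verify this across a grid
`E ∈ {1,2,3,5} × q ∈ {0.5,0.75,1}` to float tolerance. Sub-resolution
nanodomain structure is explicitly not modeled (the ~300 nm optical
resolution cannot distinguish uniform from structured enrichment), and a
negative deficit beyond noise tolerance raises an inconsistent-pair warning
with `dF` clamped at zero. Segmentation thresholds the lipopeptide channel
(Otsu by default — the experimental mask was manual with an unstated
threshold), labels with 8-connectivity, and drops regions below 0.1 µm²,
matching "Find Particle"-style defaults.

## The synthetic-data generator

The generator emulates the study conditions with known ground truth:

* **Cluster compositions** — independent Poisson monomer and K-mer draws;
  wild-type defaults `K = 3`, `m = 2.2`, `k = 1.4667`, `n = 878` (the
  back-derived oligomer mean reproducing the measured 6.6 copies/cluster);
  the hexamer condition uses `K = 6`, `m = 2.0`, `k = 1.0`, `n = 226`.
* **Capture outcomes** — Bernoulli per cluster with the published
  probabilities (wild type 0.17/0.55/1 per 1/2/≥3 trimers; hexamer 0.8/1;
  C2C mutant 0/0.09/0.23/0.43/0.53).
* **Bleaching traces** — geometric per-fluorophore survival per frame
  (defaults: unit step 100 counts, bleach probability 0.05/frame, 200
  frames, Gaussian camera noise sd 20 = 0.2 a), which yields the exponential
  ensemble decay fitted downstream. No blinking, no EMCCD gain model.
* **Domain images** — non-overlapping disks with gamma-distributed areas
  (mean 1.7 µm², SD 0.2 µm², the reported cocluster geometry) on a 256 px
  field at 0.16 µm/px; enrichment fold 3 with quench factor 0.75 by default;
  molecule number conserved between pair members by draining the bulk. No
  PSF, no drift, no camera noise model beyond additive Gaussian.

What passing tests on these data do **not** show: robustness to blinking,
uneven illumination, detection bias at small N (spot finding is upstream of
the package and not modeled), non-uniform in-domain enrichment, or
multi-vesicle occupancy. The generator is a model of the analysis
assumptions, not of the microscope.

All generators draw from per-stage substreams derived from one root seed
(stage-name hash offsets), so adding a stage never perturbs another stage's
draws and identical seeds give bit-identical outputs.

## Numerical choices

* Prediction vectors extend to mean + 12 SD of the mixture, keeping
  truncated tail mass below 1e-9.
* Perfect-fit `V`/`O` are represented by `Inf`, documented and ordered above
  all finite scores.
* Rounding of step multiplicities and `I0/a` is half-away-from-zero
  (`round_half_up()`), avoiding platform-dependent round-half-to-even ties.
* `k` is clamped at 0 (with a warning) when the observed mean falls below
  the fitted monomer mean.
* Capture-probability likelihoods clamp `P_bind` to `[1e-9, 1 - 1e-9]` to
  keep boundary fits finite.

## Problem sizes used in the shipped checks

Model-selection recovery runs at the study sample sizes (878 and 226
clusters); capture-probability recovery at 1e5 clusters; mean-copy-number
and distribution checks at 1e5 draws; bleach-trace recovery at 200 traces
per copy number; image checks on 128–256 px fields. These sizes keep every
simulation deterministic under its seed and the whole suite in the
minutes range on one core.

## End-to-end run

```{r pipeline}
cfg <- synthetic_config(seed = 42, K = 3, monomer_mean = 2.2,
                        oligomer_mean = 1.5, n_clusters = 878,
                        capture_probs = c(0, 0.17, 0.55, 1))
report <- run_pipeline(cfg)
report
```

## Known limitations

* One oligomer size at a time; no mixtures of two oligomeric states and no
  posterior over `K`.
* Capture is a static Bernoulli event per cluster; vesicle arrival kinetics
  and multiple occupancy are not modeled.
* The V/O scores use `N <= 10` even when data extend further (wild-type
  data reach `N = 19`); observed mass above the scoring window influences
  the fit only through the mean.
* The truncation bias discussed above is inherited from the source
  procedure by design.
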
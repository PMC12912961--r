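# Independent oracles used to freeze expected values. These deliberately take
# a different computational route than the package code they check.

# Mixture pmf by explicit convolution of the two component distributions:
# the monomer count pmf and the K-mer *total-copy* pmf (Poisson mass at
# multiples of K), multiplied as polynomials. Contrast: the package evaluates
# the double sum per N directly.
oracle_dual_poisson <- function(K, m, k, n_max) {
  jmax <- max(ceiling(n_max / K) + 1, ceiling(k + 12 * sqrt(max(k, 1))))
  mono <- dpois(0:n_max, m)
  oligo_total <- numeric(K * jmax + 1)
  oligo_total[K * (0:jmax) + 1] <- dpois(0:jmax, k)
  out <- numeric(n_max + 1)
  for (i in 0:n_max) {
    j <- 0:i
    valid <- (i - j) + 1 <= length(oligo_total)
    out[i + 1] <- sum(mono[j[valid] + 1] * oligo_total[i - j[valid] + 1])
  }
  out
}

# Oligomer-count posterior by conditioning a full joint table of
# (monomers, oligomers) on the observed copy number.
oracle_posterior <- function(N, K, m, k) {
  jmax <- N %/% K
  joint <- outer(dpois(0:N, m), dpois(0:jmax, k))      # rows mono, cols oligo
  total <- outer(0:N, K * (0:jmax), "+")
  w <- vapply(0:jmax, function(n) sum(joint[total == N & col(joint) == n + 1]),
              numeric(1))
  w / sum(w)
}

# Noise-free staircase trace with prescribed per-frame drops (in units of a).
staircase_trace <- function(drops_units, a = 100, plateau = 20, baseline = 0,
                            trace_id = "stair") {
  levels <- (sum(drops_units) - cumsum(c(0, drops_units))) * a + baseline
  bleach_trace(rep(levels, each = plateau), trace_id = trace_id,
               baseline = baseline)
}

# Clusters table built directly from copy numbers (and optional latent truth).
cluster_df <- function(copy_number, true_oligomers = NA_integer_,
                       true_monomers = NA_integer_, vesicle_bound = NA) {
  df <- data.frame(cluster_id = seq_along(copy_number),
                   condition = "test", copy_number = copy_number,
                   vesicle_bound = vesicle_bound,
                   true_monomers = true_monomers,
                   true_oligomers = true_oligomers,
                   observable = copy_number >= 1)
  class(df) <- c("cluster_table", "data.frame")
  df
}

# Large synthetic sample drawn from an explicit dual-Poisson model and
# reduced to a distribution; used where an "infinite-sample" histogram is
# needed we instead pass exact probabilities through a fake distribution.
exact_distribution <- function(K, m, k, n_max = 60) {
  p <- oracle_dual_poisson(K, m, k, n_max)
  probs <- p[-1] / sum(p[-1])            # condition on N >= 1 (detectable)
  structure(list(counts = setNames(round(probs * 1e9), 1:n_max),
                 n_total = 1e9, probs = probs,
                 mean_N = sum(seq_along(probs) * probs)),
            class = "copy_number_distribution")
}
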
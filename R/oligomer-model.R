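# Dual Poisson monomer + K-mer mixture and V/O model selection.
#
# Model: within each diffraction-limited cluster, the number of free
# monomers and the number of fixed-size K-mers each follow their own
# independent Poisson distribution with means m and k. The observed copy
# number N is monomers + K * K-mers, so
#
#   P_Total(N) = sum_{j=0}^{floor(N/K)} Poisson(j; k) * Poisson(N - K*j; m).
#
# m is fitted on the sub-K bins of the observed histogram (clusters with
# N < K cannot contain a K-mer); k then follows without any fit from the
# observed mean: k = (mean_N - m) / K. Candidate K values are ranked by two
# goodness-of-fit scores over N = 1..Nmax (Nmax = 10):
#   V = 1 / sum (P_obs - P_Total)^2
#   O = 1 / sum (P_obs - P_Total)^2 / P_obs   (empty bins excluded)

#' Build a copy-number distribution from observed clusters
#'
#' Tabulates copy numbers over N >= 1 (zero-copy clusters are dropped — they
#' are not optically detectable) into observed probabilities and the observed
#' mean.
#'
#' @param clusters a cluster table, or a bare integer vector of copy numbers.
#' @return a `copy_number_distribution`: list with `counts` (named integer
#'   vector over observed N), `n_total`, `p_obs` (function of N), `probs`
#'   (vector indexed 1..max N), `mean_N`.
#' @examples
#' d <- build_distribution(c(4, 4, 7))
#' d$mean_N  # 5
#' @export
build_distribution <- function(clusters) {
  n <- if (is.data.frame(clusters)) clusters$copy_number else clusters
  n <- n[!is.na(n)]
  n <- n[n >= 1]
  check_that(length(n) >= 1, "need at least one observable cluster")
  check_that(all(n == floor(n)), "copy numbers must be integers")
  tab <- table(factor(n, levels = 1:max(n)))
  probs <- as.numeric(tab) / length(n)
  structure(
    list(counts = setNames(as.integer(tab), names(tab)),
         n_total = length(n),
         probs = probs,            # probs[N] = P_obs(N), N = 1..max
         mean_N = sum(seq_along(probs) * probs)),
    class = "copy_number_distribution")
}

#' @export
print.copy_number_distribution <- function(x, ...) {
  cat(sprintf("Copy-number distribution: %d clusters, N in 1..%d, mean %.3f\n",
              x$n_total, length(x$probs), x$mean_N))
  invisible(x)
}

# P_obs(N) with zero outside the observed range.
obs_prob <- function(dist, N) {
  ifelse(N >= 1 & N <= length(dist$probs), dist$probs[pmax(N, 1)], 0)
}

#' Predicted copy-number distribution of the monomer + K-mer mixture
#'
#' Evaluates `P_Total(N) = sum_j Poisson(j; k) Poisson(N - K j; m)` for
#' N = 0..`n_max`. For N < K this reduces to `exp(-k) * Poisson(N; m)`.
#'
#' @param K oligomer size (>= 1).
#' @param m monomer Poisson mean (>= 0).
#' @param k oligomer Poisson mean (>= 0).
#' @param n_max largest N evaluated; `NULL` chooses mean + 10 SD of the
#'   mixture so the truncated tail mass is below 1e-9.
#' @return numeric vector `p` with `p[i] = P_Total(i - 1)`, i.e. indexed from
#'   N = 0.
#' @examples
#' p <- predict_dual_poisson(3, 2.2, 1.5)
#' which(diff(sign(diff(p[3:12]))) == -2)  # interior peaks
#' @export
predict_dual_poisson <- function(K, m, k, n_max = NULL) {
  check_that(K >= 1 && K == floor(K), "K must be an integer >= 1")
  check_that(m >= 0 && k >= 0, "Poisson means must be >= 0")
  if (is.null(n_max)) {
    # mean + 12 SD of the mixture keeps the truncated tail mass below 1e-9
    mu <- m + K * k
    n_max <- max(10, ceiling(mu + 12 * sqrt(max(m + K^2 * k, 1))))
  }
  vapply(0:n_max, function(N) {
    j <- 0:(N %/% K)
    sum(dpois(j, k) * dpois(N - K * j, m))
  }, numeric(1))
}

#' Fit the monomer mean from the sub-K histogram bins
#'
#' Clusters with fewer than K copies cannot contain a K-mer, so their
#' probabilities identify m: the fit minimizes, over m in (0, mean_N],
#' `sum_{N=1}^{K-1} (P_obs(N) - exp(-k(m)) Poisson(N; m))^2` with
#' `k(m) = max(0, (mean_N - m) / K)` tied to the observed mean. The
#' `exp(-k)` factor is the probability that the cluster holds no K-mer,
#' which makes the single sub-K bin of K = 2 identifiable.
#'
#' @param dist a `copy_number_distribution`.
#' @param K oligomer size; K = 1 returns `mean_N` by convention (pure
#'   Poisson).
#' @return list with `m`, `residual` (objective at the optimum).
#' @export
fit_monomer_mean <- function(dist, K) {
  check_that(inherits(dist, "copy_number_distribution"),
             "`dist` must come from build_distribution()")
  check_that(K >= 1 && K == floor(K), "K must be an integer >= 1")
  if (K == 1) return(list(m = dist$mean_N, residual = 0))
  sub <- 1:(K - 1)
  p_sub <- obs_prob(dist, sub)
  if (all(p_sub == 0))
    stop("no observed clusters with N < K; monomer mean not identifiable",
         call. = FALSE)
  objective <- function(m) {
    k <- max(0, (dist$mean_N - m) / K)
    sum((p_sub - exp(-k) * dpois(sub, m))^2)
  }
  # the objective can be multimodal (notably for K = 2, where a single bin
  # constrains it): locate the global basin on a grid, then refine locally
  grid <- seq(1e-6, dist$mean_N, length.out = 256)
  i <- which.min(vapply(grid, objective, numeric(1)))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(objective, interval = c(lo, hi), tol = 1e-9)
  list(m = opt$minimum, residual = opt$objective)
}

#' Oligomer mean from the observed mean copy number
#'
#' With m fixed, the K-mer Poisson mean needs no fit: the mixture mean is
#' `m + K k`, so `k = (mean_N - m) / K`, clamped at zero (with a warning)
#' when the observed mean falls below the monomer mean.
#'
#' @param mean_N observed mean copy number per cluster.
#' @param m monomer mean.
#' @param K oligomer size.
#' @return k (>= 0).
#' @examples
#' oligomer_mean_from_totals(6.6, 2.2, 3)  # 1.4667 -> "1.5" at one decimal
#' @export
oligomer_mean_from_totals <- function(mean_N, m, K) {
  check_that(K >= 1, "K must be >= 1")
  k <- (mean_N - m) / K
  if (k < 0) {
    warning(sprintf(
      "observed mean (%.3g) below monomer mean (%.3g); clamping k to 0",
      mean_N, m))
    k <- 0
  }
  k
}

#' Goodness-of-fit scores V and O
#'
#' `score_V()` is the inverse summed squared difference between observed and
#' predicted probabilities over N = 1..`n_score_max`;
#' `score_O()` additionally divides each squared difference by the observed
#' probability, down-weighting rare bins so that a large relative error on a
#' rare event cannot dominate — bins with `P_obs(N) = 0` are excluded from
#' the sum. Both return `Inf` for a perfect match; larger is better.
#'
#' @param dist a `copy_number_distribution`.
#' @param pred predicted probability vector from [predict_dual_poisson()]
#'   (indexed from N = 0).
#' @param n_score_max largest N entering the score (default 10).
#' @return a single score; `Inf` on perfect agreement.
#' @examples
#' d <- build_distribution(rep(1:10, 10))
#' score_V(d, rep(0, 11))  # 1 / (10 * 0.1^2) = 10
#' @export
score_V <- function(dist, pred, n_score_max = 10L) {
  check_that(n_score_max >= 1, "n_score_max must be >= 1")
  N <- 1:n_score_max
  p_o <- obs_prob(dist, N)
  p_t <- ifelse(N + 1 <= length(pred), pred[N + 1], 0)
  s <- sum((p_o - p_t)^2)
  if (s == 0) Inf else 1 / s
}

#' @rdname score_V
#' @export
score_O <- function(dist, pred, n_score_max = 10L) {
  check_that(n_score_max >= 1, "n_score_max must be >= 1")
  N <- 1:n_score_max
  p_o <- obs_prob(dist, N)
  p_t <- ifelse(N + 1 <= length(pred), pred[N + 1], 0)
  keep <- p_o > 0
  if (!any(keep))
    stop("all scored bins are empty; O score undefined", call. = FALSE)
  s <- sum((p_o[keep] - p_t[keep])^2 / p_o[keep])
  if (s == 0) Inf else 1 / s
}

#' Fit the mixture for one oligomer size K
#'
#' Runs the full per-K procedure: m from the sub-K bins
#' ([fit_monomer_mean()]), k from the observed mean
#' ([oligomer_mean_from_totals()]), prediction and both scores. K = 1 is the
#' pure-Poisson null model with mean `mean_N`.
#'
#' Following the source procedure, the predicted distribution is NOT
#' renormalized to condition on N >= 1 even though the observed histogram
#' only contains detectable clusters; `condition_observable = TRUE` enables
#' that conditioning for sensitivity analysis.
#'
#' @inheritParams score_V
#' @param K oligomer size.
#' @param condition_observable renormalize the prediction over N >= 1.
#' @return a `dual_poisson_fit`: list with `K`, `m`, `k`, `pred` (indexed
#'   from N = 0), `V`, `O`, `n_score_max`, `m_residual`.
#' @export
fit_dual_poisson <- function(dist, K, n_score_max = 10L,
                             condition_observable = FALSE) {
  if (K == 1) {
    m <- dist$mean_N; k <- 0; m_res <- 0
    pred <- dpois(0:max(10, ceiling(m + 12 * sqrt(max(m, 1)))), m)
  } else {
    mf <- fit_monomer_mean(dist, K)
    m <- mf$m; m_res <- mf$residual
    k <- oligomer_mean_from_totals(dist$mean_N, m, K)
    pred <- predict_dual_poisson(K, m, k)
  }
  if (condition_observable && pred[1] < 1) {
    pred_sc <- pred
    pred_sc[1] <- 0
    pred_sc <- pred_sc / sum(pred[-1])
  } else pred_sc <- pred
  structure(
    list(K = as.integer(K), m = m, k = k, pred = pred_sc,
         V = score_V(dist, pred_sc, n_score_max),
         O = score_O(dist, pred_sc, n_score_max),
         n_score_max = as.integer(n_score_max), m_residual = m_res),
    class = "dual_poisson_fit")
}

#' @export
print.dual_poisson_fit <- function(x, ...) {
  cat(sprintf("Dual Poisson fit: K = %d, m = %.3f, k = %.3f | V = %.4g, O = %.4g\n",
              x$K, x$m, x$k, x$V, x$O))
  invisible(x)
}

#' Select the oligomeric state by scanning candidate K
#'
#' Fits the monomer + K-mer mixture for every K in `K_range`, scores each
#' with V and O (N = 1..`n_score_max`) and reports the maximizers. Ties —
#' including several K reaching the perfect-fit `Inf` sentinel — break toward
#' the smallest K (parsimony).
#'
#' @inheritParams fit_dual_poisson
#' @param K_range integer vector of candidate oligomer sizes (default 1:10).
#' @return a `model_selection`: list with `scan` (data frame K, m, k, V, O),
#'   `fits` (per-K `dual_poisson_fit`), `best_K_by_V`, `best_K_by_O`,
#'   `best_fit` (the fit at `best_K_by_O`).
#' @examples
#' cl <- simulate_cluster_compositions(synthetic_config(seed = 5))
#' sel <- select_oligomer_size(build_distribution(cl))
#' sel$best_K_by_O
#' @export
select_oligomer_size <- function(dist, K_range = 1:10, n_score_max = 10L,
                                 condition_observable = FALSE) {
  fits <- lapply(K_range, function(K)
    fit_dual_poisson(dist, K, n_score_max, condition_observable))
  scan <- data.frame(
    K = vapply(fits, `[[`, integer(1), "K"),
    m = vapply(fits, `[[`, numeric(1), "m"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    V = vapply(fits, `[[`, numeric(1), "V"),
    O = vapply(fits, `[[`, numeric(1), "O"))
  best_v <- scan$K[which.max(scan$V)]   # which.max takes the first maximum:
  best_o <- scan$K[which.max(scan$O)]   # ties already break to smaller K
  structure(
    list(scan = scan, fits = setNames(fits, paste0("K", scan$K)),
         best_K_by_V = best_v, best_K_by_O = best_o,
         best_fit = fits[[which.max(scan$O)]]),
    class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Oligomer-size scan:\n")
  print(transform(x$scan, m = round(m, 3), k = round(k, 3),
                  V = signif(V, 4), O = signif(O, 4)), row.names = FALSE)
  cat(sprintf("Best K: %d (by V), %d (by O)\n", x$best_K_by_V, x$best_K_by_O))
  invisible(x)
}

#' Local maxima of a predicted copy-number distribution
#'
#' Interior peaks of `P_Total(N)` over an N window — e.g. the twin peaks at
#' N = 4 and N = 7 that a monomer + trimer mixture with m = 2.2, k = 1.5
#' places in the observable range.
#'
#' @param pred prediction vector from [predict_dual_poisson()] (from N = 0).
#' @param n_window integer range of N to search (default 2:10).
#' @return integer vector of N at which `P_Total` is a strict local maximum
#'   against its left neighbor and >= its right neighbor.
#' @export
prediction_peaks <- function(pred, n_window = 2:10) {
  check_that(max(n_window) + 2 <= length(pred),
             "prediction vector too short for the requested window")
  n_window[vapply(n_window, function(N)
    pred[N + 1] > pred[N] && pred[N + 1] >= pred[N + 2], logical(1))]
}
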
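# Latent oligomer posterior and cooperative vesicle-capture model.
#
# Under the fitted monomer + K-mer mixture, a cluster of N copies contains an
# unknown number n of K-mers. Bayes gives
#   P_n(N) = Poisson(n; k) Poisson(N - K n; m) / normalizer,  n = 0..floor(N/K)
# and, if n oligomers capture a vesicle with probability p_n (p_0 = 0),
#   P_bind(N) = sum_{n>=1} p_n P_n(N).

#' Posterior distribution of the oligomer count in a cluster of size N
#'
#' @param N observed copy number (>= 1).
#' @param fit a `dual_poisson_fit` (fields `K`, `m`, `k`), e.g. from
#'   [fit_dual_poisson()] or [select_oligomer_size()]`$best_fit`.
#' @return an `oligomer_posterior`: list with `N`, `K`, `n` (support
#'   0..floor(N/K)) and `prob` (posterior over `n`, summing to 1).
#' @examples
#' fit <- list(K = 3, m = 2.2, k = 1.5)
#' oligomer_posterior(3, fit)$prob[2]  # P(one trimer | N = 3) ~ 0.458
#' @export
oligomer_posterior <- function(N, fit) {
  check_that(N >= 1 && N == floor(N), "N must be a positive integer")
  K <- fit$K; m <- fit$m; k <- fit$k
  n <- 0:(N %/% K)
  w <- dpois(n, k) * dpois(N - K * n, m)
  if (sum(w) <= 0)
    stop("degenerate posterior: no (monomer, oligomer) split of N = ", N,
         " has positive probability under the fit (m = ", m, ", k = ", k, ")",
         call. = FALSE)
  structure(list(N = as.integer(N), K = as.integer(K), n = n,
                 prob = w / sum(w)),
            class = "oligomer_posterior")
}

#' Construct a vesicle-capture model
#'
#' @param capture_probs numeric vector of per-oligomer-count capture
#'   probabilities indexed from n = 0; the first entry (p0) must be 0.
#'   Oligomer counts beyond the last entry saturate at the last entry.
#' @param K oligomer size the probabilities refer to.
#' @return a `capture_model`.
#' @examples
#' wt <- capture_model(c(0, 0.17, 0.55, 1), K = 3)
#' @export
capture_model <- function(capture_probs, K) {
  check_that(all(is.finite(capture_probs)) &&
               all(capture_probs >= 0 & capture_probs <= 1),
             "capture probabilities must lie in [0, 1]")
  check_that(capture_probs[1] == 0, "p0 must be 0")
  structure(list(K = as.integer(K), capture_probs = as.numeric(capture_probs),
                 n_max = length(capture_probs) - 1L),
            class = "capture_model")
}

#' @export
print.capture_model <- function(x, ...) {
  cat(sprintf("Capture model (K = %d): p_n = %s for n = 0..%d (saturating)\n",
              x$K, paste(signif(x$capture_probs, 3), collapse = ", "), x$n_max))
  if (!is.null(x$log_lik)) cat(sprintf("  log-likelihood %.2f\n", x$log_lik))
  invisible(x)
}

#' Predicted vesicle-capture probability for a cluster of size N
#'
#' `P_bind(N) = sum_{n >= 1} p_n P_n(N)`, marginalizing the capture
#' probabilities over the oligomer-count posterior. Clusters with N < K
#' cannot hold an oligomer and have `P_bind = 0`.
#'
#' @inheritParams oligomer_posterior
#' @param model a `capture_model` with the same K as `fit`.
#' @return capture probability in `[0, 1]`; vectorized over `N`.
#' @export
predict_bind_probability <- function(N, fit, model) {
  check_that(model$K == fit$K,
             "capture model and mixture fit use different oligomer sizes")
  vapply(N, function(Ni) {
    post <- oligomer_posterior(Ni, fit)
    sum(capture_prob_at(model$capture_probs, post$n) * post$prob)
  }, numeric(1))
}

#' Empirical vesicle-capture curve
#'
#' Per-copy-number fraction of clusters that captured a vesicle, with
#' binomial counts.
#'
#' @param clusters a cluster table whose `vesicle_bound` flags are all known.
#' @return a `capture_curve` data frame: `N`, `n_clusters`, `n_bound`,
#'   `fraction_bound`.
#' @export
empirical_bind_curve <- function(clusters) {
  if (anyNA(clusters$vesicle_bound))
    stop("vesicle_bound unknown for cluster(s): ",
         paste(head(clusters$cluster_id[is.na(clusters$vesicle_bound)], 10),
               collapse = ", "), call. = FALSE)
  obs <- clusters[clusters$copy_number >= 1, ]
  Ns <- sort(unique(obs$copy_number))
  key <- factor(obs$copy_number, levels = Ns)
  out <- data.frame(N = Ns,
                    n_clusters = as.integer(table(key)),
                    n_bound = as.integer(tapply(obs$vesicle_bound, key, sum)))
  out$fraction_bound <- out$n_bound / out$n_clusters
  class(out) <- c("capture_curve", "data.frame")
  out
}

#' Fit per-oligomer-count capture probabilities by maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood
#' `sum_i b_i log P_bind(N_i) + (1 - b_i) log(1 - P_bind(N_i))`
#' over `(p_1, ..., p_n_max)` in the unit box, with p0 = 0 fixed and
#' saturation (`p_n = p_n_max` for n > n_max). Box-constrained L-BFGS-B from
#' several starts; since `P_bind` depends on the data only through N, the
#' likelihood is aggregated per copy number and the fit costs O(max N) per
#' evaluation regardless of sample size. A least-squares-on-curve criterion
#' (weighted by cluster counts) is available for procedural mimicry of
#' visual curve matching.
#'
#' @param clusters a cluster table with known `vesicle_bound`.
#' @param fit a `dual_poisson_fit` describing the oligomer mixture.
#' @param n_max number of free probabilities (counts beyond saturate).
#' @param criterion `"likelihood"` (default) or `"curve"` (least squares on
#'   the empirical capture curve).
#' @param monotone constrain p to be nondecreasing in n (default `FALSE`).
#' @return a `capture_model` with extra fields `log_lik` and `criterion`.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(seed = 11, n_clusters = 5000)
#' cl <- simulate_capture_outcomes(simulate_cluster_compositions(cfg),
#'                                 c(0, 0.17, 0.55, 1), seed = 11)
#' dist <- build_distribution(cl)
#' fit <- fit_dual_poisson(dist, K = 3)
#' fit_capture_probabilities(cl, fit, n_max = 3)
#' }
#' @export
fit_capture_probabilities <- function(clusters, fit, n_max = 3L,
                                      criterion = c("likelihood", "curve"),
                                      monotone = FALSE) {
  criterion <- match.arg(criterion)
  check_that(n_max >= 1, "n_max must be >= 1")
  curve <- empirical_bind_curve(clusters)
  if (!any(curve$N >= fit$K))
    stop("no clusters large enough to contain an oligomer (all N < K); ",
         "capture probabilities are not identifiable", call. = FALSE)

  # posterior-weighted design: w[N, n] = P(n oligomers | N), n = 1..n_max
  # with saturation classes collapsed into n = n_max.
  Ns <- curve$N
  W <- t(vapply(Ns, function(N) {
    post <- oligomer_posterior(N, fit)
    idx <- pmin(post$n, n_max)
    w <- vapply(seq_len(n_max), function(n) sum(post$prob[idx == n]),
                numeric(1))
    w
  }, numeric(n_max)))
  if (n_max == 1) W <- matrix(W, ncol = 1)

  eps <- 1e-9
  pbind <- function(p) pmin(1 - eps, pmax(eps, as.numeric(W %*% p)))
  theta_to_p <- function(theta) if (monotone) pmin(1, cumsum(theta)) else theta
  objective <- function(theta) {
    p <- theta_to_p(theta)
    pb <- pbind(p)
    if (criterion == "likelihood") {
      -sum(curve$n_bound * log(pb) +
             (curve$n_clusters - curve$n_bound) * log(1 - pb))
    } else {
      sum(curve$n_clusters * (curve$fraction_bound - pb)^2)
    }
  }
  starts <- list(rep(0.5, n_max),
                 seq(0.2, 0.9, length.out = n_max),
                 rep(0.1, n_max),
                 rep(0.9, n_max))
  if (monotone) starts <- lapply(starts, function(s) pmax(diff(c(0, sort(s))), 0.01))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, objective, method = "L-BFGS-B",
            lower = rep(0, n_max), upper = rep(1, n_max),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  check_that(!is.null(best), "capture-probability optimization failed")
  p_hat <- theta_to_p(best$par)
  model <- capture_model(c(0, p_hat), K = fit$K)
  model$criterion <- criterion
  pb <- pbind(p_hat)
  model$log_lik <- sum(curve$n_bound * log(pb) +
                         (curve$n_clusters - curve$n_bound) * log(1 - pb))
  model$curve <- transform(curve, predicted = pb)
  model
}
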
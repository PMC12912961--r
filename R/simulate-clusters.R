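# Cluster-composition and vesicle-capture generators.

#' Simulate cluster compositions from the monomer + K-mer mixture
#'
#' Each cluster independently draws `true_monomers ~ Poisson(monomer_mean)`
#' and `true_oligomers ~ Poisson(oligomer_mean)`; its copy number is
#' `true_monomers + K * true_oligomers`. Zero-copy draws are retained (column
#' `observable` is `FALSE` for them): empty clusters are not optically
#' detectable, but keeping them lets the truncation bias of observed-mean
#' statistics be measured. Use [filter_observable()] for the detectable subset.
#'
#' @param config a [synthetic_config()].
#' @return a `data.frame` of class `cluster_table` with columns `cluster_id`,
#'   `condition`, `copy_number`, `vesicle_bound` (all `NA` until a capture
#'   simulation is attached), `true_monomers`, `true_oligomers`, `observable`.
#' @examples
#' cl <- simulate_cluster_compositions(synthetic_config(seed = 1, n_clusters = 100))
#' all(cl$copy_number == cl$true_monomers + 3 * cl$true_oligomers)
#' @export
simulate_cluster_compositions <- function(config) {
  check_that(inherits(config, "synthetic_config"),
             "`config` must be a synthetic_config")
  withr::with_seed(substream_seed(config$seed, "compositions"), {
    mono  <- rpois(config$n_clusters, config$monomer_mean)
    oligo <- rpois(config$n_clusters, config$oligomer_mean)
  })
  n <- mono + config$K * oligo
  out <- data.frame(
    cluster_id    = seq_len(config$n_clusters),
    condition     = config$condition,
    copy_number   = n,
    vesicle_bound = NA,
    true_monomers = mono,
    true_oligomers = oligo,
    observable    = n >= 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Keep only optically detectable clusters
#'
#' Drops clusters with `copy_number == 0` (no fluorophore, hence invisible in
#' TIRF). The number removed is reported with a message; an input with no
#' detectable cluster returns an empty table with a warning.
#'
#' @param clusters a cluster table (from [simulate_cluster_compositions()] or
#'   [read_cluster_table()]).
#' @return the filtered cluster table.
#' @export
filter_observable <- function(clusters) {
  keep <- clusters$copy_number >= 1L
  removed <- sum(!keep)
  if (removed > 0)
    message(sprintf("filter_observable: removed %d zero-copy cluster(s)", removed))
  out <- clusters[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no observable clusters remain")
  out
}

# p_n lookup with saturation: indices beyond the vector reuse its last entry.
capture_prob_at <- function(capture_probs, n) {
  idx <- pmin(n + 1L, length(capture_probs))
  capture_probs[idx]
}

#' Simulate vesicle-capture outcomes
#'
#' Given the latent oligomer count of each cluster, a vesicle is captured with
#' probability `capture_probs[n + 1]` (Bernoulli), where `n` is the number of
#' oligomers. `capture_probs[1]` is `p0 = 0`: clusters without an oligomer
#' never bind. Counts beyond the last supplied entry saturate at the last
#' entry, mirroring the "3 or more oligomers" grouping of capture data.
#'
#' @param clusters a cluster table carrying `true_oligomers`.
#' @param capture_probs numeric vector in `[0, 1]`, indexed from n = 0, first
#'   entry 0.
#' @param seed integer seed.
#' @return the cluster table with `vesicle_bound` filled in (logical).
#' @examples
#' cfg <- synthetic_config(seed = 2, n_clusters = 500)
#' cl <- simulate_cluster_compositions(cfg)
#' cl <- simulate_capture_outcomes(cl, c(0, 0.17, 0.55, 1), seed = 2)
#' @export
simulate_capture_outcomes <- function(clusters, capture_probs, seed) {
  check_that(!is.null(clusters$true_oligomers) &&
               !anyNA(clusters$true_oligomers),
             "clusters must carry latent `true_oligomers` to simulate capture")
  check_that(all(is.finite(capture_probs)) &&
               all(capture_probs >= 0 & capture_probs <= 1),
             "capture probabilities must lie in [0, 1]")
  check_that(capture_probs[1] == 0, "p0 must be 0")
  p <- capture_prob_at(capture_probs, clusters$true_oligomers)
  withr::with_seed(substream_seed(seed, "capture"), {
    bound <- rbinom(nrow(clusters), 1L, p) == 1L
  })
  clusters$vesicle_bound <- bound
  clusters
}

#' Read / write cluster observation tables
#'
#' CSV with header `cluster_id,condition,copy_number,vesicle_bound,
#' true_monomers,true_oligomers` (the latter three optional;
#' `vesicle_bound` coded 0/1/NA).
#'
#' @param path CSV file path.
#' @return `read_cluster_table()` returns a `cluster_table` data frame.
#' @export
read_cluster_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("cluster_id", "copy_number") %in% names(df)),
             "cluster table needs at least cluster_id and copy_number columns")
  if (is.null(df$condition)) df$condition <- "unknown"
  df$vesicle_bound <- if (is.null(df$vesicle_bound)) NA else df$vesicle_bound == 1
  if (is.null(df$true_monomers)) df$true_monomers <- NA_integer_
  if (is.null(df$true_oligomers)) df$true_oligomers <- NA_integer_
  df$observable <- df$copy_number >= 1L
  class(df) <- c("cluster_table", "data.frame")
  df
}

#' @rdname read_cluster_table
#' @param clusters a cluster table.
#' @export
write_cluster_table <- function(clusters, path) {
  out <- clusters[, c("cluster_id", "condition", "copy_number",
                      "vesicle_bound", "true_monomers", "true_oligomers")]
  out$vesicle_bound <- ifelse(is.na(out$vesicle_bound), NA_integer_,
                              as.integer(out$vesicle_bound))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
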
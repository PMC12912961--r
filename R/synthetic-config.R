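#' Configuration for the synthetic TIRF experiment generator
#'
#' Bundles and validates every parameter the generators consume. The default
#' values reproduce the wild-type study conditions: clusters are a
#' superposition of Poisson-distributed monomers (mean `monomer_mean`) and
#' Poisson-distributed fixed-size K-mers (mean `oligomer_mean`), with the
#' trimer model `K = 3`, `monomer_mean = 2.2` and `oligomer_mean = 1.4667`
#' giving the observed average of 6.6 copies per cluster.
#'
#' @param seed integer; root seed, mandatory.
#' @param K integer >= 1; oligomer size (3 for trimers, 6 for hexamers).
#' @param monomer_mean Poisson mean of free monomers per cluster (copies).
#' @param oligomer_mean Poisson mean of K-mers per cluster.
#' @param n_clusters number of clusters to draw.
#' @param condition free-text label stored with each cluster.
#' @param capture_probs optional numeric vector of per-oligomer-count capture
#'   probabilities, indexed from n = 0 (first entry must be 0); counts beyond
#'   the last entry saturate at the last entry.
#' @param trace_params list with `unit_step` (single-fluorophore intensity, camera
#'   units), `bleach_prob` (per-frame bleaching probability), `noise_sd`
#'   (Gaussian camera noise, camera units), `n_frames`, `baseline`.
#' @param image_params list with `size_px` (square field edge, pixels),
#'   `pixel_size_um` (micron per pixel), `n_domains`, `mean_domain_area_um2`,
#'   `sd_domain_area_um2`, `density` (bulk fluorophores per pixel),
#'   `enrichment` (fold E >= 1), `quench` (per-molecule brightness factor
#'   inside domains, in (0, 1]), `noise_sd`, `background`.
#' @return an object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(seed = 1, K = 3, monomer_mean = 2.2,
#'                         oligomer_mean = 1.4667, n_clusters = 878)
#' @export
synthetic_config <- function(seed,
                             K = 3L,
                             monomer_mean = 2.2,
                             oligomer_mean = 1.4667,
                             n_clusters = 878L,
                             condition = "synthetic",
                             capture_probs = NULL,
                             trace_params = list(),
                             image_params = list()) {
  check_that(!missing(seed) && length(seed) == 1 && is.finite(seed),
             "`seed` is mandatory and must be a single finite number")
  check_that(length(K) == 1 && K >= 1 && K == floor(K),
             "`K` must be a single integer >= 1")
  check_that(is.finite(monomer_mean) && monomer_mean >= 0,
             "`monomer_mean` must be >= 0")
  check_that(is.finite(oligomer_mean) && oligomer_mean >= 0,
             "`oligomer_mean` must be >= 0")
  check_that(n_clusters >= 1, "`n_clusters` must be >= 1")
  if (!is.null(capture_probs)) {
    check_that(all(is.finite(capture_probs)) &&
                 all(capture_probs >= 0 & capture_probs <= 1),
               "`capture_probs` must all lie in [0, 1]")
    check_that(capture_probs[1] == 0,
               "`capture_probs[1]` is p0 and must be 0 (a cluster without oligomers cannot capture)")
  }

  trace_defaults <- list(unit_step = 100, bleach_prob = 0.05,
                         noise_sd = 20, n_frames = 200L, baseline = 0)
  image_defaults <- list(size_px = 256L, pixel_size_um = 0.16,
                         n_domains = 25L, mean_domain_area_um2 = 1.7,
                         sd_domain_area_um2 = 0.2, density = 50,
                         enrichment = 3, quench = 0.75,
                         noise_sd = 0, background = 0)
  trace_params <- modifyList(trace_defaults, trace_params)
  image_params <- modifyList(image_defaults, image_params)
  check_that(trace_params$unit_step > 0, "trace unit step must be > 0")
  check_that(trace_params$bleach_prob > 0 && trace_params$bleach_prob < 1,
             "per-frame bleach probability must lie in (0, 1)")
  check_that(image_params$enrichment >= 1, "enrichment fold must be >= 1")
  check_that(image_params$quench > 0 && image_params$quench <= 1,
             "quench factor must lie in (0, 1]")

  structure(
    list(seed = as.integer(seed), K = as.integer(K),
         monomer_mean = monomer_mean, oligomer_mean = oligomer_mean,
         n_clusters = as.integer(n_clusters), condition = condition,
         capture_probs = capture_probs,
         trace_params = trace_params, image_params = image_params),
    class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic experiment configuration\n")
  cat(sprintf("  seed %d | K = %d | monomer mean %.4g | %d-mer mean %.4g | %d clusters\n",
              x$seed, x$K, x$monomer_mean, x$K, x$oligomer_mean, x$n_clusters))
  if (!is.null(x$capture_probs))
    cat("  capture probabilities:", paste(x$capture_probs, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a generator configuration
#'
#' The on-disk format is a single YAML (or JSON) document mirroring the
#' `synthetic_config` fields; `seed` is mandatory.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `read_synthetic_config()` returns a `synthetic_config`;
#'   `write_synthetic_config()` returns `path` invisibly.
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(synthetic_config, raw)
}

#' @rdname read_synthetic_config
#' @param config a `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
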
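# Stepwise photobleaching trace generator.

#' Simulate a photobleaching trace for a cluster of N fluorophores
#'
#' Each of the `copy_number` fluorophores independently survives each frame
#' with probability `1 - bleach_prob` (geometric lifetime, discrete time).
#' The recorded intensity at frame t is
#' `unit_step * survivors(t) + baseline + N(0, noise_sd)`, so the ensemble
#' expectation decays as `unit_step * N * (1 - bleach_prob)^t` — the
#' exponential profile seen for large clusters, while individual small-N
#' traces show discrete bleaching steps of height `unit_step`. Photoblinking
#' and dark states are not modeled.
#'
#' @param copy_number integer >= 1; number of fluorophores N.
#' @param trace_params list as in [synthetic_config()] (`unit_step`,
#'   `bleach_prob`, `noise_sd`, `n_frames`, `baseline`).
#' @param seed integer seed.
#' @param trace_id identifier stored on the result.
#' @return a `bleach_trace`: list with `trace_id`, `intensity` (length
#'   `n_frames`, frame 0 first), `frame_interval`, `baseline`, and the latent
#'   `survivors` series (synthetic ground truth).
#' @examples
#' tr <- simulate_bleach_trace(4, list(noise_sd = 0), seed = 1)
#' tr$intensity[1]  # = 4 * unit_step at frame 0
#' @export
simulate_bleach_trace <- function(copy_number, trace_params = list(), seed,
                                  trace_id = "trace") {
  check_that(copy_number >= 1, "`copy_number` must be >= 1")
  p <- modifyList(list(unit_step = 100, bleach_prob = 0.05, noise_sd = 20,
                       n_frames = 200L, baseline = 0), trace_params)
  check_that(p$unit_step > 0, "unit step must be > 0")
  check_that(p$n_frames >= 1, "frame count must be >= 1")
  withr::with_seed(substream_seed(seed, "bleach"), {
    # frames survived after frame 0 (alive at frame 0 by construction)
    lifetime <- rgeom(copy_number, p$bleach_prob)
    noise <- if (p$noise_sd > 0) rnorm(p$n_frames, 0, p$noise_sd) else numeric(p$n_frames)
  })
  frames <- 0:(p$n_frames - 1L)
  survivors <- vapply(frames, function(t) sum(lifetime >= t), integer(1))
  structure(
    list(trace_id = trace_id,
         intensity = p$unit_step * survivors + p$baseline + noise,
         frame_interval = 1,
         baseline = p$baseline,
         survivors = survivors),
    class = "bleach_trace")
}

#' Construct a bleaching trace from an intensity vector
#'
#' @param intensity numeric vector of per-frame intensities (>= 10 frames).
#' @param trace_id identifier.
#' @param frame_interval seconds per frame.
#' @param baseline known camera baseline, or `NULL` to estimate downstream.
#' @return a `bleach_trace`.
#' @export
bleach_trace <- function(intensity, trace_id = "trace", frame_interval = 1,
                         baseline = NULL) {
  check_that(length(intensity) >= 10, "a trace needs at least 10 frames")
  check_that(all(is.finite(intensity)), "intensities must be finite")
  structure(list(trace_id = trace_id, intensity = as.numeric(intensity),
                 frame_interval = frame_interval, baseline = baseline),
            class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("Bleaching trace '%s': %d frames, intensity %.4g..%.4g\n",
              x$trace_id, length(x$intensity),
              max(x$intensity), min(x$intensity)))
  invisible(x)
}

#' Read / write bleaching traces (long CSV)
#'
#' Long format with header `trace_id,frame,intensity`; one file can hold many
#' traces.
#'
#' @param path CSV path.
#' @return `read_bleach_traces()` returns a named list of `bleach_trace`.
#' @export
read_bleach_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("frame", "intensity") %in% names(df)),
             "trace CSV needs frame and intensity columns")
  if (is.null(df$trace_id)) df$trace_id <- "trace"
  out <- lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$frame), ]
    bleach_trace(d$intensity, trace_id = d$trace_id[1])
  })
  out[order(names(out))]
}

#' @rdname read_bleach_traces
#' @param traces a list of `bleach_trace`.
#' @export
write_bleach_traces <- function(traces, path) {
  if (inherits(traces, "bleach_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id,
               frame = seq_along(tr$intensity) - 1L,
               intensity = tr$intensity)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
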
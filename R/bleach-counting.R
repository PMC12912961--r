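# Copy-number estimation from photobleaching traces.
#
# Small clusters bleach in resolvable discrete steps: the copy number is the
# number of unit steps (a simultaneous double bleach counts as two). Large
# clusters bleach smoothly; there the copy number is N = I0 / a, with I0 the
# initial intensity above baseline and a the single-fluorophore unit step
# calibrated from the small clusters of the same experiment.

# --- piecewise-constant change-point fit (binary segmentation) -------------

# Best single split of y[l..r] by residual sum of squares.
best_split <- function(y, l, r) {
  n <- r - l + 1L
  if (n < 2L) return(NULL)
  seg <- y[l:r]
  cs <- cumsum(seg); cs2 <- cumsum(seg^2)
  i <- seq_len(n - 1L)                       # split after position i
  rss_left  <- cs2[i] - cs[i]^2 / i
  rss_right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  rss_all   <- cs2[n] - cs[n]^2 / n
  gain <- rss_all - (rss_left + rss_right)
  j <- which.max(gain)
  list(pos = l + j - 1L, gain = gain[j])     # last index of the left segment
}

# Recursive binary segmentation with an RSS-reduction penalty.
segment_trace <- function(y, penalty) {
  cps <- integer(0)
  recurse <- function(l, r) {
    sp <- best_split(y, l, r)
    if (is.null(sp) || sp$gain <= penalty) return(invisible())
    cps <<- c(cps, sp$pos)
    recurse(l, sp$pos)
    recurse(sp$pos + 1L, r)
  }
  recurse(1L, length(y))
  sort(cps)
}

# Robust noise scale from first differences (steps are sparse outliers).
noise_scale <- function(y) {
  d <- diff(y)
  s <- stats::mad(d) / sqrt(2)
  if (!is.finite(s)) s <- 0
  s
}

# Baseline: supplied, or median of the final 10% of frames.
trace_baseline <- function(trace) {
  if (!is.null(trace$baseline)) return(trace$baseline)
  n <- length(trace$intensity)
  median(trace$intensity[max(1L, floor(0.9 * n)):n])
}

#' Count bleaching steps in a trace
#'
#' Locates change points on the intensity series with a penalized
#' piecewise-constant fit (binary segmentation; the penalty scales with the
#' robust noise variance of the trace, so a noise-free trace accepts every
#' true step). The fitted levels are then snapped to the unit-step lattice —
#' every plateau is an integer number of surviving fluorophores above the
#' final level — and the copy number is the sum of level decreases on that
#' lattice. A downward change of height h therefore contributes
#' `round(h / a)`: simultaneous double bleaches count twice, and dips below
#' `min_step_fraction * a` quantize to zero and are rejected. Upward level
#' changes (blinking back, drift) are never counted.
#'
#' @param trace a `bleach_trace`.
#' @param unit_step single-fluorophore intensity a, or `NULL` to estimate it
#'   from the trace's own smallest detected downward step.
#' @param min_step_fraction downward changes smaller than
#'   `min_step_fraction * a` are rejected as noise (default 0.5).
#' @return a `step_count` result: `trace_id`, `method = "stepwise"`,
#'   `copy_number_estimate`, `unit_step`, `initial_intensity`,
#'   `step_positions` (frame index after which each level drop occurs),
#'   `step_heights`, `fit_residual` (mean squared residual of the piecewise
#'   fit).
#' @examples
#' tr <- simulate_bleach_trace(4, list(noise_sd = 0), seed = 7)
#' detect_steps(tr, unit_step = 100)$copy_number_estimate
#' @export
detect_steps <- function(trace, unit_step = NULL, min_step_fraction = 0.5) {
  y <- trace$intensity
  sigma <- noise_scale(y)
  # Penalty on the RSS reduction of a split. It is kept permissive (the
  # spurious splits it lets through produce level changes well below
  # min_step_fraction * a and are rejected by the height filter below),
  # because a single-frame plateau between two bleaching events must still
  # be resolvable; the floor keeps noise-free traces from splitting on
  # numerical dust.
  penalty <- max(1.5 * sigma^2 * log(length(y)), 1e-9 * mean(y^2), 1e-12)
  cps <- segment_trace(y, penalty)
  bounds <- c(0L, cps, length(y))
  seg_len <- diff(bounds)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(y[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  fitted <- rep(levels, seg_len)
  residual <- mean((y - fitted)^2)

  if (levels[length(levels)] > levels[1])
    stop("trace '", trace$trace_id, "' has an upward net trend; malformed trace",
         call. = FALSE)
  dlev <- diff(levels)
  # standard error of each level change; splits explainable by noise alone
  # are discarded before any height thresholding
  se <- sigma * sqrt(1 / head(seg_len, -1) + 1 / tail(seg_len, -1))
  is_down <- dlev < 0 & -dlev > 3 * se
  down <- -dlev[is_down]
  if (length(down) == 0)
    stop("no downward bleaching steps found in trace '", trace$trace_id, "'",
         call. = FALSE)

  a <- if (is.null(unit_step)) min(down) else unit_step
  check_that(a > 0, "unit step must be > 0")
  # snap levels to the survivor lattice anchored at the final plateau; a
  # one-frame plateau contaminating a neighboring segment mean then costs
  # less than half a unit step instead of a whole miscount
  lattice <- round_half_up((levels - levels[length(levels)]) / a)
  dm <- -diff(lattice)
  counted <- dm >= 1 & !(dm == 1 & -dlev < min_step_fraction * a)
  counts <- dm[counted]
  if (sum(counts) < 1)
    stop("no steps of at least ", min_step_fraction, " x unit step found",
         call. = FALSE)
  pos <- cps[counted]
  down <- -dlev[counted]

  structure(
    list(trace_id = trace$trace_id, method = "stepwise",
         copy_number_estimate = as.integer(sum(counts)),
         unit_step = a,
         initial_intensity = y[1] - trace_baseline(trace),
         step_positions = pos, step_heights = down,
         fit_residual = residual),
    class = "step_count")
}

#' Fit an exponential decay to a bleaching trace
#'
#' Least-squares fit of `intensity = I0 * exp(-rate * t) + baseline` using
#' Levenberg-Marquardt, with starting values from a log-linear regression.
#' For large clusters the ensemble of surviving fluorophores decays
#' geometrically per frame, so the smooth profile is exponential.
#'
#' @param trace a `bleach_trace` with at least 20 frames.
#' @return list with `I0` (fitted amplitude above baseline at frame 0),
#'   `decay_rate` (per frame), `baseline`, `fit_residual` (mean squared
#'   residual).
#' @export
fit_exponential_decay <- function(trace) {
  y <- trace$intensity
  check_that(length(y) >= 20, "exponential fit needs at least 20 frames")
  t <- seq_along(y) - 1
  b0 <- trace_baseline(trace)
  amp <- y[1] - b0
  if (!is.finite(amp) || abs(amp) <= 1e-12 * max(abs(y), 1) ||
      sd(y) <= 1e-12 * max(abs(y), 1)) {
    warning("degenerate exponential fit: trace is constant")
    return(list(I0 = max(amp, 0), decay_rate = 0, baseline = b0,
                fit_residual = var(y) * (length(y) - 1) / length(y)))
  }
  # log-linear start on the positive part of the baseline-subtracted trace
  pos <- which((y - b0) > 0.05 * amp)
  r0 <- if (length(pos) >= 2) {
    max(1e-4, -coef(stats::lm(log(y[pos] - b0) ~ t[pos]))[[2]])
  } else 0.05
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-r * t) + b,
                      start = list(I0 = amp, r = r0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    return(list(I0 = unname(cf["I0"]), decay_rate = unname(cf["r"]),
                baseline = unname(cf["b"]), fit_residual = mean(resid(fit)^2)))
  }
  # Levenberg-Marquardt fails on exactly-exponential data (singular gradient
  # at the solution); a direct simplex minimization of the same SSR then
  # finishes the job.
  ssr <- function(p) sum((y - (p[1] * exp(-abs(p[2]) * t) + p[3]))^2)
  o <- optim(c(amp, r0, b0), ssr, control = list(maxit = 2000, reltol = 1e-14))
  if (!is.finite(o$value))
    stop("exponential decay fit failed to converge", call. = FALSE)
  list(I0 = o$par[1], decay_rate = abs(o$par[2]), baseline = o$par[3],
       fit_residual = o$value / length(y))
}

#' Estimate the copy number of a cluster from its bleaching trace
#'
#' Dispatches between the two counting regimes: traces whose detected step
#' count is at most `stepwise_max` and whose piecewise-constant fit is at
#' least as good as the smooth exponential fit are counted step by step;
#' all other traces use the large-N rule `N = round(I0 / a)`, where `I0`
#' is the initial intensity above baseline.
#'
#' @inheritParams detect_steps
#' @param unit_step single-fluorophore intensity a (> 0), e.g. from
#'   [calibrate_unit_step()].
#' @param stepwise_max largest copy number trusted to step counting
#'   (default 6).
#' @return a `step_count` result; `method` records the branch taken.
#' @examples
#' tr <- simulate_bleach_trace(3, list(noise_sd = 0), seed = 3)
#' estimate_copy_number(tr, unit_step = 100)$method  # "stepwise"
#' @export
estimate_copy_number <- function(trace, unit_step, stepwise_max = 6L,
                                 min_step_fraction = 0.5) {
  check_that(unit_step > 0, "unit step must be > 0")
  steps <- tryCatch(
    detect_steps(trace, unit_step, min_step_fraction),
    error = function(e) NULL)
  if (!is.null(steps) && steps$copy_number_estimate <= stepwise_max) {
    expfit <- if (length(trace$intensity) >= 20)
      tryCatch(suppressWarnings(fit_exponential_decay(trace)),
               error = function(e) NULL) else NULL
    if (is.null(expfit) || steps$fit_residual <= expfit$fit_residual)
      return(steps)
  }
  expfit <- fit_exponential_decay(trace)
  i0 <- trace$intensity[1] - expfit$baseline
  n <- round_half_up(i0 / unit_step)
  if (n < 1)
    stop("exponential branch estimated a copy number below 1", call. = FALSE)
  structure(
    list(trace_id = trace$trace_id, method = "exponential",
         copy_number_estimate = n, unit_step = unit_step,
         initial_intensity = i0, step_positions = integer(0),
         step_heights = numeric(0), decay_rate = expfit$decay_rate,
         fit_residual = expfit$fit_residual),
    class = "step_count")
}

#' @export
print.step_count <- function(x, ...) {
  cat(sprintf("Trace '%s': N = %d (%s; unit step %.4g, I0 %.4g)\n",
              x$trace_id, x$copy_number_estimate, x$method,
              x$unit_step, x$initial_intensity))
  invisible(x)
}

#' Calibrate the single-fluorophore unit step from stepwise traces
#'
#' The unit intensity a is the median of all single bleaching steps. Singles
#' are separated from simultaneous multiples by windowing: an initial
#' estimate a0 is seeded from the mode of all step heights, heights within
#' `[0.5 a0, 1.5 a0)` are kept as singles, and the window is re-centered once
#' on their median before the final median is taken.
#'
#' @param results list of `step_count` results (stepwise traces, typically
#'   from small clusters of the same experiment; 5 or more recommended).
#' @return calibrated unit step a.
#' @export
calibrate_unit_step <- function(results) {
  if (inherits(results, "step_count")) results <- list(results)
  heights <- unlist(lapply(results, function(r) r$step_heights))
  if (length(heights) < 3)
    stop("too few bleaching steps to calibrate the unit step", call. = FALSE)
  a0 <- if (length(heights) >= 5) {
    d <- density(heights)
    d$x[which.max(d$y)]
  } else median(heights)
  for (i in 1:2) {
    singles <- heights[heights >= 0.5 * a0 & heights < 1.5 * a0]
    if (length(singles) == 0)
      stop("no single-step heights near the running estimate", call. = FALSE)
    a0 <- median(singles)
  }
  a0
}

#' Count copy numbers for a set of traces
#'
#' Convenience wrapper: optionally auto-calibrates the unit step from the
#' stepwise traces, then applies [estimate_copy_number()] to every trace.
#'
#' @param traces list of `bleach_trace`.
#' @param unit_step a number, or `"auto"` to calibrate with
#'   [calibrate_unit_step()] from per-trace step detection.
#' @param stepwise_max passed to [estimate_copy_number()].
#' @return a `data.frame` with columns `trace_id`, `method`, `copy_number`,
#'   `unit_step`, `I0`, `residual`.
#' @export
count_copy_numbers <- function(traces, unit_step = "auto", stepwise_max = 6L) {
  if (identical(unit_step, "auto")) {
    pre <- lapply(traces, function(tr)
      tryCatch(detect_steps(tr), error = function(e) NULL))
    pre <- Filter(function(r) !is.null(r) &&
                    r$copy_number_estimate <= stepwise_max, pre)
    unit_step <- calibrate_unit_step(pre)
  }
  rows <- lapply(traces, function(tr) {
    r <- estimate_copy_number(tr, unit_step, stepwise_max)
    data.frame(trace_id = r$trace_id, method = r$method,
               copy_number = r$copy_number_estimate,
               unit_step = r$unit_step, I0 = r$initial_intensity,
               residual = r$fit_residual, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
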
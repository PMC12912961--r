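# Shared small helpers.

#' Round half away from zero
#'
#' Commercial rounding used for step multiplicities and for N = I0/a: 0.5
#' always rounds up in magnitude (unlike base `round()`, which rounds half to
#' even). Keeping one documented rule avoids platform-dependent tie behavior.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Stop unless condition holds, with a sprintf-style message.
check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# Deterministic substream seed: root seed offset by a stage-name hash, so
# adding a stage never perturbs the draws of another. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100000L
  (as.integer(seed) %% 21000000L) * 100L + h %% 100L + h
}
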
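#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"); reported
#' percentages here follow the convention of rounding .5 upward, so that
#' 100 * 516 / 1752 = 29.45205... prints as 29.5 at one decimal.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return `x` rounded half-up to `digits` decimals
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Empirical percentile with linear interpolation
#'
#' Thin, explicitly documented wrapper around the default (type 7) sample
#' quantile: linear interpolation between order statistics. Kept as its own
#' function so the QC filter's interval rule points at a single definition
#' that tests can check against an explicit-sort oracle.
#'
#' @param x numeric vector (NAs not allowed)
#' @param probs probabilities in \[0, 1\]
#' @return numeric vector of percentiles
#' @keywords internal
percentile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

# Derive a 31-bit sub-seed from the current RNG stream. All simulator
# sub-streams (per cluster, per replicate) are spawned this way from one
# master seed, so one integer reproduces the whole run.
derive_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("coexpair_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("coexpair_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
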
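#' Round half away from zero
#'
#' Standard "schoolbook" rounding used for all reported percentages, so that
#' e.g. 2.55 prints as 2.6 rather than R's banker's rounding to 2.5 (for
#' positive values this is round-half-up).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded half-up to one decimal
#' @param n count
#' @param total denominator
#' @param digits decimal places (default 1)
#' @return percentage on the 0-100 scale
#' @export
pct <- function(n, total, digits = 1) {
  round_half_up(100 * n / total, digits)
}

# internal: stopifnot-style validation with a clear message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
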
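#' Round half away from zero
#'
#' Deterministic half-up rounding (3.5 -> 4, 32.08 -> 32), unlike base
#' [round()] which rounds half to even. Used for all reported integer
#' counts and percentages so that printed summaries do not depend on the
#' IEEE round-to-even rule at .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Integer percentage of a count
#'
#' `round_percent(k, n)` is `100 * k / n` rounded half-up to the nearest
#' integer, the convention used throughout the class summaries and
#' overlap reports (e.g. 5,230 of 5,532 genes -> 95).
#'
#' @param k numerator count (non-negative).
#' @param n denominator count (positive).
#' @return integer percentage.
#' @examples
#' round_percent(1655, 5532)  # 30
#' @export
round_percent <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0), all(k >= 0))
  as.integer(round_half_up(100 * k / n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a header line followed by bullet-style sub-messages
.stop_many <- function(header, msgs) {
  stop(paste(c(header, paste0("  - ", msgs)), collapse = "\n"), call. = FALSE)
}
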
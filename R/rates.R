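#' Annual rate of change (ARC) between two values
#'
#' The ARC is the constant exponential rate linking two positive values
#' observed `n_years` apart, expressed in percent per year:
#' \deqn{ARC = 100 \cdot \ln(y_{end}/y_{start}) / n}
#' It is the workhorse of every projection in the package: the
#' business-as-usual (BAU) trend continues each county's historical ARC,
#' and the scale-up scenarios are defined by alternative ARCs.
#'
#' @param y_start Positive rate or proportion at the start of the period.
#' @param y_end Positive rate or proportion at the end of the period.
#' @param n_years Number of annual steps between the two values
#'   (year difference, e.g. 2014 - 2003 = 11). Must be >= 1.
#'
#' @return Signed rate of change in percent per year; negative iff
#'   `y_end < y_start`.
#'
#' @examples
#' arc(69.8, 59.5, 12)   # national U5M decline, ~ -1.33 %/yr
#' arc(50, 100, 10)      # doubling in a decade, 100*ln(2)/10
#' @export
arc <- function(y_start, y_end, n_years) {
  if (!all(is.finite(y_start)) || any(y_start <= 0)) {
    stop("`y_start` must be positive and finite", call. = FALSE)
  }
  if (!all(is.finite(y_end)) || any(y_end <= 0)) {
    stop("`y_end` must be positive and finite", call. = FALSE)
  }
  if (!all(is.finite(n_years)) || any(n_years < 1)) {
    stop("`n_years` must be >= 1", call. = FALSE)
  }
  100 * log(y_end / y_start) / n_years
}

#' Project a value forward at a constant annual rate of change
#'
#' Applies `arc_value` (percent per year) for `k_years` annual steps:
#' `y0 * exp(arc_value/100 * k_years)`. Inverse of [arc()]:
#' `project(y0, arc(y0, y1, n), n)` recovers `y1` exactly (to floating
#' point).
#'
#' @param y0 Positive baseline value.
#' @param arc_value Rate in percent per year (signed), as returned by
#'   [arc()].
#' @param k_years Number of annual steps to project (>= 0).
#'
#' @return Projected value, same scale as `y0`.
#' @export
project <- function(y0, arc_value, k_years) {
  if (!all(is.finite(y0)) || any(y0 <= 0)) {
    stop("`y0` must be positive and finite", call. = FALSE)
  }
  if (any(k_years < 0)) stop("`k_years` must be >= 0", call. = FALSE)
  y0 * exp(arc_value / 100 * k_years)
}

#' Clamp a projected coverage proportion to its admissible band
#'
#' Projected coverage is restricted to `[0.001, 0.99]` on the proportion
#' scale: the ceiling is the universal-coverage cap of 99% used by the
#' scale-up scenarios, and the floor keeps log-linear arithmetic away
#' from zero.
#'
#' @param value Numeric vector of proportions (finite).
#' @return `value` clamped into `[0.001, 0.99]`.
#' @export
clamp_coverage <- function(value) {
  pmin(pmax(value, 0.001), 0.99)
}
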
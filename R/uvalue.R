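#' Measured value with a standard deviation
#'
#' Lightweight vectorised container for quantities carried through the
#' pipeline as value +/- sd (e.g. slopes, yields, G-values). Uncertainties
#' are combined by first-order (quadrature) propagation throughout: the
#' replicate measurements entering each quantity are independent, so
#' correlations between combined terms are ignored.
#'
#' @param value numeric vector of central values.
#' @param sd numeric vector of standard deviations, recycled against
#'   `value`; must be non-negative.
#' @return An object of class `"uvalue"`: a list with numeric components
#'   `value` and `sd` of equal length.
#' @examples
#' uvalue(16.7, 1.7)
#' udiff(uvalue(16.7, 1.7), uvalue(3.9, 0.1))
#' @export
uvalue <- function(value, sd = 0) {
  value <- as.numeric(value)
  sd <- rep_len(as.numeric(sd), length(value))
  if (any(!is.finite(sd) | sd < 0))
    stop("'sd' must be finite and non-negative")
  structure(list(value = value, sd = sd), class = "uvalue")
}

#' @export
is_uvalue <- function(x) inherits(x, "uvalue")

as_uvalue <- function(x) {
  if (is_uvalue(x)) x else uvalue(x)
}

#' @export
format.uvalue <- function(x, ..., digits = 4) {
  paste0(signif(x$value, digits), " ± ", signif(x$sd, digits))
}

#' @export
print.uvalue <- function(x, ...) {
  cat(format(x, ...), sep = "\n")
  invisible(x)
}

#' @export
length.uvalue <- function(x) length(x$value)

#' @export
`[.uvalue` <- function(x, i) uvalue(x$value[i], x$sd[i])

#' Difference of two uncertain values
#'
#' `value = a - b`, with standard deviations combined in quadrature
#' (`sd = sqrt(sd_a^2 + sd_b^2)`). This is the operation behind the
#' substrate subtraction Y_LEE = Y_Ta - Y_glass and behind every
#' enzyme-minus-baseline yield difference.
#'
#' @param a,b `uvalue` objects (or plain numerics, taken as exact).
#' @return A `uvalue`.
#' @export
udiff <- function(a, b) {
  a <- as_uvalue(a); b <- as_uvalue(b)
  uvalue(a$value - b$value, sqrt(a$sd^2 + b$sd^2))
}

#' Sum of two uncertain values
#'
#' Quadrature companion of [udiff()]; used for summing the two enzymes'
#' additional yields and for total damage (loss of supercoiled + total BD).
#'
#' @inheritParams udiff
#' @return A `uvalue`.
#' @export
usum <- function(a, b) {
  a <- as_uvalue(a); b <- as_uvalue(b)
  uvalue(a$value + b$value, sqrt(a$sd^2 + b$sd^2))
}

#' Ratio of two uncertain values
#'
#' `value = a/b`, with the relative standard deviations of numerator and
#' denominator combined in quadrature:
#' `sd = |a/b| * sqrt((sd_a/a)^2 + (sd_b/b)^2)`.
#' When the numerator is exactly zero the relative-error rule degenerates;
#' only the numerator's absolute error is then carried (`sd = sd_a/|b|`).
#' This is the estimator used for enhancement ratios, OER and G_LEE/G_X.
#'
#' @inheritParams udiff
#' @return A `uvalue`.
#' @export
uratio <- function(a, b) {
  a <- as_uvalue(a); b <- as_uvalue(b)
  if (any(b$value == 0)) stop("uratio: zero denominator")
  v <- a$value / b$value
  sd <- ifelse(
    a$value == 0,
    a$sd / abs(b$value),
    abs(v) * sqrt((a$sd / a$value)^2 + (b$sd / b$value)^2)
  )
  uvalue(v, sd)
}

#' Scale an uncertain value by an exact constant
#'
#' @param a a `uvalue`.
#' @param k numeric scale factor (exact).
#' @return A `uvalue` with both value and sd scaled by `|k|`-preserving rules
#'   (`value = k*a`, `sd = |k|*sd_a`).
#' @export
uscale <- function(a, k) {
  a <- as_uvalue(a)
  uvalue(k * a$value, abs(k) * a$sd)
}
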
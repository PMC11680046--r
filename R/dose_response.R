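#' Fit a linear exposure-response curve for one conformation
#'
#' Ordinary least squares of band fraction against photon fluence, with all
#' replicate lanes entering as separate points. In the single-event regime
#' the response is linear and the slope carries all the information; the
#' intercept only reflects the initial composition plus manipulation damage
#' and never enters the yields.
#'
#' @param lanes a `"lane_fractions"` data frame for one condition and
#'   series (at least 3 distinct fluence levels).
#' @param form band to fit: one of `SC, circular, linear, crosslinked,
#'   concatemer`.
#' @return An object of class `"slope_fit"`: list with `form`, `slope` and
#'   `intercept` ([uvalue()]s, sd from residual variance), `n_points`,
#'   `r_squared`.
#' @export
fit_exposure_response <- function(lanes, form) {
  form <- match.arg(form, BAND_LEVELS)
  lanes <- as.data.frame(lanes)
  if (!all(c("fluence", form) %in% names(lanes)))
    stop("lanes must contain 'fluence' and the '", form, "' fraction")
  fluence <- lanes$fluence
  y <- lanes[[form]]
  if (length(unique(fluence)) < 3)
    stop("need at least 3 distinct fluence levels")
  fit <- stats::lm(y ~ fluence)
  cf <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  # standard errors straight from the residual variance (an exact line has
  # sd 0, and summary.lm's perfect-fit warning is irrelevant here)
  n <- length(y)
  sxx <- sum((fluence - mean(fluence))^2)
  s2 <- ssr / (n - 2)
  se <- c(sqrt(s2 * (1 / n + mean(fluence)^2 / sxx)), sqrt(s2 / sxx))
  names(se) <- c("(Intercept)", "fluence")
  structure(list(form = form,
                 slope = uvalue(cf[["fluence"]], se[["fluence"]]),
                 intercept = uvalue(cf[["(Intercept)"]], se[["(Intercept)"]]),
                 n_points = length(y),
                 r_squared = if (sst > 0) 1 - ssr / sst else NA_real_),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Exposure-response fit, %s band: slope %s, intercept %s (n = %d, R^2 = %s)\n",
              x$form, format(x$slope, digits = 3),
              format(x$intercept, digits = 3), x$n_points,
              format(x$r_squared, digits = 3)))
  invisible(x)
}

#' Convert a fitted slope into an effective damage yield
#'
#' The effective yield (lesions per plasmid per photon cm^-2) is the fitted
#' slope divided by the initial supercoiled fraction of the unirradiated
#' sample. For the supercoiled band itself the slope is negative (loss of
#' supercoiled) and the yield is reported as a positive magnitude; product
#' bands keep the slope's sign, so pure-noise negative estimates are
#' retained unclipped and downstream subtractions stay unbiased.
#'
#' @param fit a `"slope_fit"`.
#' @param f_sc0 initial supercoiled fraction, in (0, 1].
#' @return A [uvalue()] yield.
#' @export
effective_yield <- function(fit, f_sc0) {
  if (!inherits(fit, "slope_fit")) stop("fit must be a 'slope_fit'")
  if (f_sc0 <= 0 || f_sc0 > 1)
    stop("f_sc0 must lie in (0, 1]")
  if (fit$form == "SC") {
    uvalue(abs(fit$slope$value) / f_sc0, fit$slope$sd / f_sc0)
  } else {
    uscale(fit$slope, 1 / f_sc0)
  }
}

#' Mean and replicate scatter of repeated yield measurements
#'
#' The reported uncertainty of every yield is the sample standard deviation
#' across independent slope replicates (the "six identical measurements"
#' convention), not the propagated per-fit residual error, which is kept
#' only as a diagnostic.
#'
#' @param yields a list of [uvalue()]s (or a numeric vector) of replicate
#'   yield estimates; at least 2.
#' @return A [uvalue()]: mean of the values, sd = sample standard deviation.
#' @export
replicate_mean <- function(yields) {
  v <- if (is.numeric(yields)) yields
       else vapply(yields, function(u) as_uvalue(u)$value, numeric(1))
  if (length(v) < 2) stop("need at least 2 replicates")
  uvalue(mean(v), stats::sd(v))
}
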
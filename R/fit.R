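#' Fit the full damage model to a gel band table
#'
#' Central estimator of the package. From quantified gel-lane band
#' intensities of irradiated plasmid films it
#' \enumerate{
#'   \item normalises every lane to conformation fractions (undoing the
#'     supercoiled staining bias),
#'   \item fits a linear exposure-response curve per conformation,
#'     condition and slope-replicate series, and divides slopes by the
#'     initial supercoiled fraction to obtain effective yields,
#'   \item averages yields over replicate series (reported sd = replicate
#'     scatter),
#'   \item decomposes the four treatments (untreated, heated, Nth, Fpg)
#'     into the nine-lesion taxonomy, including heat-labile and
#'     enzyme-revealed base-damage classes,
#'   \item subtracts glass from Ta yields to isolate the low-energy
#'     photoelectron (LEE) contribution, and
#'   \item converts glass and LEE yields to G-values (damages/100 eV).
#' }
#'
#' @param bands a band table (long data frame as read by
#'   [read_band_table()] or produced by [simulate_experiment()]), covering
#'   all four treatments; both substrates are needed for LEE results.
#' @param config a [pipeline_config()].
#' @param enzyme_baseline baseline for the enzyme differences: `"heated"`
#'   (default; enzyme incubation includes the same 37 degC hour) or
#'   `"untreated"`.
#' @param f_sc0 optional fixed initial supercoiled fraction; by default it
#'   is estimated per (gas, gamma, substrate) as the mean supercoiled
#'   fraction of the unirradiated (zero-fluence) lanes.
#' @return An object of class `"damage_fit"` with components `fractions`
#'   (per-lane conformation fractions), `slopes` (per-series linear fits),
#'   `yields` (replicate-averaged effective yields), `lesions` (lesion
#'   yields for glass, Ta and LEE), `gvalues` (a [g_table()]), `f0`
#'   (estimated initial composition per condition), `config` and `call`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' truth <- reference_gvalues()
#' bands <- simulate_experiment(truth, experiment_design(slope_replicates = 2),
#'                              noise_sd = 0, seed = 1)
#' fit <- plasmid_damage_fit(bands)
#' coef(fit)[1:5, ]
#' @export
plasmid_damage_fit <- function(bands, config = pipeline_config(),
                               enzyme_baseline = c("heated", "untreated"),
                               f_sc0 = NULL) {
  enzyme_baseline <- match.arg(enzyme_baseline)
  fractions <- if (inherits(bands, "lane_fractions")) bands
               else normalize_band_table(bands, config$sc_stain_factor)

  condcols <- c("gas", "gamma", "substrate")
  conds <- unique(as.data.frame(fractions)[condcols])
  rownames(conds) <- NULL

  # initial composition per condition from the unirradiated lanes
  f0 <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    sel <- fractions$gas == conds$gas[i] & fractions$gamma == conds$gamma[i] &
      fractions$substrate == conds$substrate[i] & fractions$fluence == 0
    if (!any(sel))
      stop("no zero-fluence lanes for ", paste(conds[i, ], collapse = "/"),
           "; supply 'f_sc0'")
    cbind(conds[i, , drop = FALSE],
          as.data.frame(as.list(colMeans(fractions[sel, BAND_LEVELS]))))
  }))
  names(f0) <- c(condcols, BAND_LEVELS)
  rownames(f0) <- NULL

  forms <- c("SC", "circular", "linear", "crosslinked")
  fitcols <- c(condcols, "treatment", "series")
  groups <- split(as.data.frame(fractions),
                  interaction(as.data.frame(fractions)[fitcols], drop = TRUE))
  slopes <- do.call(rbind, lapply(groups, function(d) {
    do.call(rbind, lapply(forms, function(fm) {
      ft <- fit_exposure_response(d, fm)
      cbind(d[1, fitcols, drop = FALSE],
            data.frame(form = fm, slope = ft$slope$value,
                       slope_sd = ft$slope$sd,
                       intercept = ft$intercept$value,
                       intercept_sd = ft$intercept$sd,
                       n_points = ft$n_points, r_squared = ft$r_squared))
    }))
  }))
  rownames(slopes) <- NULL

  # effective yields per series, then replicate mean across series
  fsc <- function(i) {
    if (!is.null(f_sc0)) return(f_sc0)
    f0$SC[f0$gas == slopes$gas[i] & f0$gamma == slopes$gamma[i] &
            f0$substrate == slopes$substrate[i]]
  }
  yvals <- vapply(seq_len(nrow(slopes)), function(i) {
    s <- slopes$slope[i]
    (if (slopes$form[i] == "SC") abs(s) else s) / fsc(i)
  }, numeric(1))
  ysd <- slopes$slope_sd / vapply(seq_len(nrow(slopes)), fsc, numeric(1))

  ykey <- interaction(slopes[c(condcols, "treatment", "form")], drop = TRUE)
  yields <- do.call(rbind, lapply(split(seq_len(nrow(slopes)), ykey),
    function(idx) {
      u <- if (length(idx) >= 2) replicate_mean(yvals[idx])
           else uvalue(yvals[idx], ysd[idx])
      cbind(slopes[idx[1], c(condcols, "treatment", "form"), drop = FALSE],
            data.frame(yield = u$value, sd = u$sd))
    }))
  rownames(yields) <- NULL

  # lesion taxonomy per substrate condition, then Ta - glass
  lesions <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    sel <- yields$gas == conds$gas[i] & yields$gamma == conds$gamma[i] &
      yields$substrate == conds$substrate[i]
    ys <- lapply(TREATMENT_LEVELS, function(tr) {
      d <- yields[sel & yields$treatment == tr, ]
      if (nrow(d) != length(forms))
        stop("missing '", tr, "' treatment for condition ",
             paste(conds[i, ], collapse = "/"))
      yield_set(conds$substrate[i], conds$gas[i], conds$gamma[i], tr,
                stats::setNames(lapply(seq_len(nrow(d)), function(j)
                  uvalue(d$yield[j], d$sd[j])), d$form),
                if (is.null(f_sc0)) f0$SC[i] else f_sc0)
    })
    names(ys) <- TREATMENT_LEVELS
    condition_lesions(ys$untreated, ys$heated, ys$Nth, ys$Fpg,
                      enzyme_baseline)
  }))
  pairs <- unique(lesions[c("gas", "gamma")])
  lee <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sel <- lesions$gas == pairs$gas[i] & lesions$gamma == pairs$gamma[i]
    subs <- unique(lesions$substrate[sel])
    if (!all(c("Ta", "glass") %in% subs)) return(NULL)
    lee_yields(lesions[sel & lesions$substrate == "Ta", ],
               lesions[sel & lesions$substrate == "glass", ])
  }))
  lesions <- rbind(lesions, lee)
  rownames(lesions) <- NULL
  class(lesions) <- c("lesion_yields", "data.frame")

  structure(list(fractions = fractions, slopes = slopes, yields = yields,
                 lesions = lesions,
                 gvalues = yields_to_gvalues(lesions, config),
                 f0 = f0, config = config,
                 enzyme_baseline = enzyme_baseline,
                 call = match.call()),
            class = "damage_fit")
}

#' @export
print.damage_fit <- function(x, ...) {
  cat("Plasmid film damage fit\n")
  cat(sprintf("  %d lanes, %d conditions (gas x gamma x substrate), %d slope fits\n",
              nrow(x$fractions), nrow(x$f0), nrow(x$slopes)))
  cat(sprintf("  gases: %s; gamma: %s; substrates: %s\n",
              paste(unique(x$f0$gas), collapse = ", "),
              paste(sort(unique(x$f0$gamma)), collapse = ", "),
              paste(unique(x$f0$substrate), collapse = ", ")))
  cat(sprintf("  enzyme baseline: %s\n", x$enzyme_baseline))
  cat("  G-values: use coef(), summary() or render_report()\n")
  invisible(x)
}

#' @export
summary.damage_fit <- function(object, decimals = 1, ...) {
  structure(list(fit = object,
                 report = render_report(object$gvalues, decimals = decimals)),
            class = "summary.damage_fit")
}

#' @export
print.summary.damage_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  cat(x$report, sep = "\n")
  invisible(x)
}

#' Extract estimates from a damage fit
#'
#' @param object a `"damage_fit"`.
#' @param type `"gvalues"` (default; the G-value table), `"lesions"`
#'   (per-substrate lesion yields) or `"yields"` (per-form effective
#'   yields).
#' @param ... unused.
#' @return A data frame.
#' @export
coef.damage_fit <- function(object, type = c("gvalues", "lesions", "yields"),
                            ...) {
  switch(match.arg(type),
         gvalues = object$gvalues,
         lesions = object$lesions,
         yields = object$yields)
}

# recovered primitive damage rates for one physical substrate
recovered_rates <- function(object, gas, gamma, substrate) {
  l <- object$lesions
  sel <- l$gas == gas & l$gamma == gamma & l$substrate == substrate
  if (!any(sel)) stop("no fitted condition ", gas, "/", gamma, "/", substrate)
  r <- stats::setNames(numeric(length(PRIMITIVE_LESIONS)), PRIMITIVE_LESIONS)
  hit <- l$lesion[sel] %in% PRIMITIVE_LESIONS
  r[l$lesion[sel][hit]] <- l$yield[sel][hit]
  pmax(r, 0)
}

#' Predicted band fractions from a fitted model
#'
#' Evaluates the single-event model at the recovered damage rates and the
#' estimated initial composition of the requested condition.
#'
#' @param object a `"damage_fit"`.
#' @param gas,gamma,substrate condition (substrate `"Ta"` or `"glass"`).
#' @param treatment treatment arm.
#' @param fluence numeric vector of photon fluences.
#' @param ... unused.
#' @return Matrix of fractions, one row per fluence, columns the five
#'   bands.
#' @export
predict.damage_fit <- function(object, gas, gamma, substrate,
                               treatment = "untreated", fluence, ...) {
  rates <- recovered_rates(object, gas, gamma, substrate)
  f0row <- object$f0[object$f0$gas == gas & object$f0$gamma == gamma &
                       object$f0$substrate == substrate, ]
  f0 <- unlist(f0row[BAND_LEVELS])
  f0 <- f0 / sum(f0)
  t(vapply(fluence, function(ph)
    expected_fractions(rates, treatment, ph, f0),
    numeric(length(BAND_LEVELS))))
}

#' @export
fitted.damage_fit <- function(object, ...) {
  fr <- as.data.frame(object$fractions)
  sl <- object$slopes
  key_f <- interaction(fr$gas, fr$gamma, fr$substrate, fr$treatment,
                       fr$series)
  out <- fr[c("gas", "gamma", "substrate", "treatment", "series",
              "fluence", "replicate")]
  for (fm in unique(sl$form)) {
    s <- sl[sl$form == fm, ]
    key_s <- interaction(s$gas, s$gamma, s$substrate, s$treatment, s$series)
    m <- match(key_f, key_s)
    out[[fm]] <- s$intercept[m] + s$slope[m] * fr$fluence
  }
  out
}

#' @export
residuals.damage_fit <- function(object, ...) {
  ft <- fitted(object)
  fr <- as.data.frame(object$fractions)
  forms <- setdiff(names(ft), c("gas", "gamma", "substrate", "treatment",
                                "series", "fluence", "replicate"))
  for (fm in forms) ft[[fm]] <- fr[[fm]] - ft[[fm]]
  ft
}

#' Exposure-response plot of a damage fit
#'
#' Base-graphics panels of band fraction versus fluence for one condition,
#' with the per-series linear fits overlaid.
#'
#' @param x a `"damage_fit"`.
#' @param gas,gamma,substrate condition to display.
#' @param treatment treatment arm.
#' @param forms bands to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.damage_fit <- function(x, gas, gamma, substrate,
                            treatment = "untreated",
                            forms = c("SC", "circular", "linear",
                                      "crosslinked"), ...) {
  fr <- as.data.frame(x$fractions)
  sel <- fr$gas == gas & fr$gamma == gamma & fr$substrate == substrate &
    fr$treatment == treatment
  if (!any(sel)) stop("no lanes for the requested condition")
  d <- fr[sel, ]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(forms)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  sl <- x$slopes
  for (fm in forms) {
    graphics::plot(d$fluence, d[[fm]], xlab = "fluence (photons/cm^2)",
                   ylab = "fraction", main = fm,
                   col = as.integer(factor(d$series)), ...)
    ss <- sl[sl$gas == gas & sl$gamma == gamma & sl$substrate == substrate &
               sl$treatment == treatment & sl$form == fm, ]
    for (j in seq_len(nrow(ss)))
      graphics::abline(ss$intercept[j], ss$slope[j],
                       col = as.integer(factor(ss$series))[j], lty = 2)
  }
  invisible(x)
}

#' Simulate new band tables from a fitted model
#'
#' Parametric-bootstrap style forward simulation: the fitted G-value table
#' is used as generating truth for [simulate_experiment()]. Negative
#' recovered G-values (pure-noise estimates) are clipped to zero for
#' generation.
#'
#' @param object a `"damage_fit"`.
#' @param nsim number of simulated campaigns.
#' @param seed integer seed for the first campaign; campaign `i` uses
#'   `seed + i - 1`.
#' @param design an [experiment_design()].
#' @param noise_sd Gaussian band noise sd.
#' @param ... unused.
#' @return A band table (`nsim = 1`) or a list of band tables.
#' @export
simulate.damage_fit <- function(object, nsim = 1, seed,
                                design = experiment_design(),
                                noise_sd = 0.003, ...) {
  if (missing(seed)) stop("an integer 'seed' is required")
  g <- as.data.frame(object$gvalues)
  g <- g[g$lesion %in% PRIMITIVE_LESIONS, ]
  g$G <- pmax(g$G, 0)
  sims <- lapply(seq_len(nsim), function(i)
    simulate_experiment(g, design, object$config, noise_sd,
                        seed = seed + i - 1))
  if (nsim == 1) sims[[1]] else sims
}
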
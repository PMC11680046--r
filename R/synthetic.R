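#' Design of a simulated irradiation experiment
#'
#' Describes the exposure schedule and replication structure of one
#' irradiation campaign: films exposed for 0, 5, 10, 20, 30 and 40 minutes
#' at a constant photon flux, three lanes per exposure entering each
#' linear fit, and six independent slope replicates per condition from
#' which the reported standard deviations are taken.
#'
#' The absolute photon flux is a free constant of the apparatus. The
#' default (2.5e8 photons cm^-2 min^-1) keeps the largest per-plasmid Poisson
#' mean near 0.01 for realistic G-value inputs, i.e. safely inside the
#' single-event regime where the exposure-response curves are linear.
#'
#' @param exposure_min exposure times in minutes (must include 0).
#' @param flux photon flux, photons cm^-2 min^-1.
#' @param fluences photon fluences, photons cm^-2; default
#'   `exposure_min * flux`. Must be non-negative and strictly increasing.
#' @param lane_replicates lanes per fluence level entering one fit.
#' @param slope_replicates independent repeats of the whole
#'   exposure-response series per condition.
#' @param f0 initial composition of the unirradiated sample over the five
#'   gel bands (named fractions; renormalised to sum to 1). Default: 96.0%
#'   supercoiled, 0.73% crosslinked, 0.72% circular, 2.54% concatemeric.
#' @param p_pyrimidine share of each base-damage class residing on
#'   pyrimidine sites (revealed by Nth); the purine share `1 - p` is
#'   revealed by Fpg. Downstream recovery is insensitive to this split
#'   because the two enzymes' additional yields are summed.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(exposure_min = c(0, 5, 10, 20, 30, 40),
                              flux = 2.5e8,
                              fluences = exposure_min * flux,
                              lane_replicates = 3,
                              slope_replicates = 6,
                              f0 = c(SC = 0.9600, circular = 0.0072,
                                     crosslinked = 0.0073, concatemer = 0.0254),
                              p_pyrimidine = 0.5) {
  if (any(fluences < 0) || is.unsorted(fluences, strictly = TRUE))
    stop("fluences must be non-negative and strictly increasing")
  f0 <- f0[f0 != 0]
  if (!all(names(f0) %in% BAND_LEVELS))
    stop("unknown band in f0: ",
         paste(setdiff(names(f0), BAND_LEVELS), collapse = ", "))
  full <- stats::setNames(numeric(length(BAND_LEVELS)), BAND_LEVELS)
  full[names(f0)] <- f0
  if (abs(sum(full) - 1) > 0.01)
    stop("f0 must sum to 1 (within 1%)")
  full <- full / sum(full)
  if (p_pyrimidine < 0 || p_pyrimidine > 1)
    stop("p_pyrimidine must lie in [0, 1]")
  structure(list(fluences = fluences, lane_replicates = lane_replicates,
                 slope_replicates = slope_replicates, f0 = full,
                 p_pyrimidine = p_pyrimidine),
            class = "experiment_design")
}

#' Convert a table of G-values into per-plasmid damage rates
#'
#' Inverts the G-value definitions to obtain the "true" damage rates
#' (lesions per plasmid per unit photon fluence) that drive the forward
#' simulator: for each lesion,
#' `glass = G_X * photon_energy * x_abs_area / (100 * cf_x * n_dna)`,
#' `LEE   = G_LEE * eta_e * x_trans_area * mean_lee_energy / (100 * cf_lee * n_dna)`,
#' and `Ta = glass + LEE` (the substrate-subtraction premise: damage on Ta
#' is photon damage plus photoelectron damage).
#'
#' @param g_truth a [g_table()] (or plain data frame with columns
#'   `gas, gamma, source, lesion, G`) holding sources `"X"` and `"LEE"` for
#'   the primitive lesions (`SSB, DSB, CL, isolatedBD, NDCD, BD-CL` and
#'   optionally `heatLabileSSB`); derived lesions (`LossSC`, `totalBD`,
#'   `total`) are ignored here. Missing primitive lesions count as rate 0.
#' @param config a [pipeline_config()].
#' @return A data frame of class `"damage_rates"` with columns
#'   `gas, gamma, substrate` (glass/Ta/LEE) and one rate column per
#'   primitive lesion.
#' @export
gvalues_to_rates <- function(g_truth, config = pipeline_config()) {
  g_truth <- as.data.frame(g_truth)
  need <- c("gas", "gamma", "source", "lesion", "G")
  if (!all(need %in% names(g_truth)))
    stop("g_truth must have columns ", paste(need, collapse = ", "))
  g_truth <- g_truth[g_truth$lesion %in% PRIMITIVE_LESIONS, ]
  if (any(g_truth$G < 0)) stop("negative G-values are not allowed")
  if (!all(g_truth$source %in% c("X", "LEE")))
    stop("g_truth sources must be 'X' and 'LEE'")

  kx <- config$photon_energy * config$x_abs_area /
    (100 * config$cf_x * config$n_dna)
  kl <- config$eta_e * config$x_trans_area * config$mean_lee_energy /
    (100 * config$cf_lee * config$n_dna)

  conds <- unique(g_truth[c("gas", "gamma")])
  out <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    sel <- g_truth$gas == conds$gas[i] & g_truth$gamma == conds$gamma[i]
    rate <- function(src, k) {
      r <- stats::setNames(numeric(length(PRIMITIVE_LESIONS)), PRIMITIVE_LESIONS)
      rows <- g_truth[sel & g_truth$source == src, ]
      r[rows$lesion] <- rows$G * k
      r
    }
    glass <- rate("X", kx)
    lee <- rate("LEE", kl)
    rates <- rbind(glass = glass, Ta = glass + lee, LEE = lee)
    data.frame(gas = conds$gas[i], gamma = conds$gamma[i],
               substrate = rownames(rates), rates,
               check.names = FALSE, row.names = NULL)
  }))
  class(out) <- c("damage_rates", "data.frame")
  out
}

# Effective Poisson means per conformation class for one treatment.
# Enzyme digestion converts base lesions into strand breaks: Nth reveals the
# pyrimidine share p of each BD class, Fpg the purine share 1-p; every
# 37 C-incubated portion (heated, Nth, Fpg) also converts heat-labile sites
# into SSBs.
effective_means <- function(rates, treatment, fluence, p_pyrimidine = 0.5) {
  share <- switch(treatment,
                  untreated = 0, heated = 0,
                  Nth = p_pyrimidine, Fpg = 1 - p_pyrimidine)
  heat <- if (treatment == "untreated") 0 else rates[["heatLabileSSB"]]
  c(SSB = (rates[["SSB"]] + heat + share * rates[["isolatedBD"]]) * fluence,
    DSB = (rates[["DSB"]] + share * rates[["NDCD"]]) * fluence,
    CL = (rates[["CL"]] + share * rates[["BD-CL"]]) * fluence)
}

#' Expected band fractions under the single-event (Poisson) model
#'
#' Exposure-response linearity with fluence means every lesion is induced
#' by a single event, so lesion counts per plasmid are Poisson with mean
#' `rate * fluence`. An initially supercoiled molecule is classified by the
#' highest-priority damage it carries (a DSB dominates electrophoretic
#' mobility, then a crosslink, then a nick):
#' `P(linear) = 1 - exp(-m_DSB)`, `P(crosslinked | not linear) =
#' 1 - exp(-m_CL)`, `P(circular | neither) = 1 - exp(-m_SSB)`, remainder
#' supercoiled. Pre-existing circular/crosslinked/concatemer material is
#' carried through unchanged.
#'
#' @param rates named numeric vector of per-plasmid damage rates for the
#'   primitive lesions (one substrate/condition), as one row of
#'   [gvalues_to_rates()].
#' @param treatment one of `"untreated"`, `"heated"`, `"Nth"`, `"Fpg"`;
#'   governs which latent lesion classes are expressed as strand breaks.
#' @param fluence photon fluence, photons cm^-2 (scalar, >= 0).
#' @param f0 named initial composition over the five bands (sums to 1).
#' @param p_pyrimidine pyrimidine share of BD classes (see
#'   [experiment_design()]).
#' @return Named fractions over `SC, circular, linear, crosslinked,
#'   concatemer`, summing to 1.
#' @export
expected_fractions <- function(rates, treatment, fluence,
                               f0 = experiment_design()$f0,
                               p_pyrimidine = 0.5) {
  stopifnot(fluence >= 0)
  m <- effective_means(rates, treatment, fluence, p_pyrimidine)
  sc0 <- f0[["SC"]]
  p_lin <- 1 - exp(-m[["DSB"]])
  p_cl <- exp(-m[["DSB"]]) * (1 - exp(-m[["CL"]]))
  p_circ <- exp(-m[["DSB"]] - m[["CL"]]) * (1 - exp(-m[["SSB"]]))
  c(SC = sc0 * exp(-sum(m)),
    circular = f0[["circular"]] + sc0 * p_circ,
    linear = sc0 * p_lin,
    crosslinked = f0[["crosslinked"]] + sc0 * p_cl,
    concatemer = f0[["concatemer"]])
}

#' Simulate gel band tables for a full irradiation campaign
#'
#' Forward model of the experiment: for every condition (gas, hydration
#' level, substrate, treatment), slope replicate, fluence and lane, takes
#' the expected band fractions, divides the supercoiled band by the stain
#' factor (emulating the weaker SYBR Green I binding that the analysis must
#' undo), adds independent Gaussian band noise, and clips at zero.
#' Deterministic for a fixed seed.
#'
#' @param g_truth generating G-value table (see [gvalues_to_rates()]).
#' @param design an [experiment_design()].
#' @param config a [pipeline_config()].
#' @param noise_sd absolute standard deviation of the Gaussian band noise,
#'   on the intensity (~fraction) scale.
#' @param seed integer seed; required, so simulated campaigns are
#'   reproducible.
#' @param treatments treatments to simulate (default all four).
#' @return A long-format band table (data frame) with columns
#'   `substrate, gas, gamma, treatment, series, fluence, replicate, band,
#'   intensity` — the schema read back by [read_band_table()].
#' @export
simulate_experiment <- function(g_truth, design = experiment_design(),
                                config = pipeline_config(),
                                noise_sd = 0.003, seed,
                                treatments = TREATMENT_LEVELS) {
  if (missing(seed)) stop("an integer 'seed' is required")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  rates <- gvalues_to_rates(g_truth, config)
  rates <- rates[rates$substrate %in% c("glass", "Ta"), ]
  check_condition(rates$substrate, rates$gas, rates$gamma, treatments)

  grid <- expand.grid(i = seq_len(nrow(rates)), treatment = treatments,
                      fluence = design$fluences,
                      stringsAsFactors = FALSE)
  frac <- t(vapply(seq_len(nrow(grid)), function(j) {
    r <- unlist(rates[grid$i[j], PRIMITIVE_LESIONS])
    expected_fractions(r, grid$treatment[j], grid$fluence[j],
                       design$f0, design$p_pyrimidine)
  }, numeric(length(BAND_LEVELS))))
  colnames(frac) <- BAND_LEVELS
  frac[, "SC"] <- frac[, "SC"] / config$sc_stain_factor

  nlane <- design$lane_replicates * design$slope_replicates
  lanes <- expand.grid(replicate = seq_len(design$lane_replicates),
                       series = seq_len(design$slope_replicates),
                       j = seq_len(nrow(grid)))
  out <- data.frame(
    substrate = rates$substrate[grid$i[lanes$j]],
    gas = rates$gas[grid$i[lanes$j]],
    gamma = rates$gamma[grid$i[lanes$j]],
    treatment = grid$treatment[lanes$j],
    series = lanes$series,
    fluence = grid$fluence[lanes$j],
    replicate = lanes$replicate
  )
  intens <- frac[lanes$j, , drop = FALSE]
  set.seed(as.integer(seed))
  if (noise_sd > 0)
    intens <- intens + stats::rnorm(length(intens), 0, noise_sd)
  intens <- pmax(intens, 0)

  long <- data.frame(out[rep(seq_len(nrow(out)), times = length(BAND_LEVELS)), ],
                     band = rep(BAND_LEVELS, each = nrow(out)),
                     intensity = as.vector(intens),
                     row.names = NULL)
  ord <- order(long$gas, long$gamma, long$substrate, long$treatment,
               long$series, long$fluence, long$replicate,
               match(long$band, BAND_LEVELS))
  long <- long[ord, ]
  rownames(long) <- NULL
  long
}
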
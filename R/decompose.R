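#' Per-treatment effective yields for one condition
#'
#' Container for the four per-form effective yields measured on one
#' (substrate, gas, hydration) condition under one treatment.
#'
#' @param substrate,gas,gamma,treatment condition keys.
#' @param yields named list of [uvalue()]s over the fitted forms
#'   (`SC, circular, linear, crosslinked`). The `SC` entry is the
#'   loss-of-supercoiled yield (positive magnitude).
#' @param f_sc0 initial supercoiled fraction used to form the yields.
#' @return An object of class `"yield_set"`.
#' @export
yield_set <- function(substrate, gas, gamma, treatment, yields, f_sc0) {
  check_condition(substrate, gas, gamma, treatment)
  need <- c("SC", "circular", "linear", "crosslinked")
  if (!all(need %in% names(yields)))
    stop("yields must contain entries for ", paste(need, collapse = ", "))
  structure(list(substrate = substrate, gas = gas, gamma = gamma,
                 treatment = treatment,
                 yields = lapply(yields[need], as_uvalue), f_sc0 = f_sc0),
            class = "yield_set")
}

same_condition <- function(a, b) {
  identical(a$substrate, b$substrate) && identical(a$gas, b$gas) &&
    identical(a$gamma, b$gamma)
}

check_treatment <- function(ys, expected) {
  if (!inherits(ys, "yield_set")) stop("expected a 'yield_set'")
  if (ys$treatment != expected)
    stop("expected the '", expected, "' treatment, got '", ys$treatment, "'")
  invisible(ys)
}

lesion_df <- function(gas, gamma, substrate, lesions) {
  data.frame(gas = gas, gamma = gamma, substrate = substrate,
             lesion = names(lesions),
             yield = vapply(lesions, function(u) u$value, numeric(1)),
             sd = vapply(lesions, function(u) u$sd, numeric(1)),
             row.names = NULL)
}

#' Lesions read directly from the untreated sample
#'
#' The prompt lesions need no enzymatic treatment: a nicked (circular)
#' plasmid marks an SSB, a linearised one a DSB, the crosslinked band an
#' inter-duplex CL, and the disappearance of the supercoiled band the loss
#' of supercoiled.
#'
#' @param untreated a `"yield_set"` with treatment `"untreated"`.
#' @return Named list of [uvalue()]s: `SSB`, `DSB`, `CL`, `LossSC`.
#' @export
prompt_lesions <- function(untreated) {
  check_treatment(untreated, "untreated")
  with(untreated$yields,
       list(SSB = circular, DSB = linear, CL = crosslinked, LossSC = SC))
}

#' Heat-labile SSB yield
#'
#' Incubation at 37 degC for 1 h converts heat-labile sites into strand
#' breaks; the heat-labile SSB yield is the heated-minus-untreated
#' difference of SSB (circular-band) yields. The analogous differences for
#' the other forms are returned as diagnostics.
#'
#' @param heated,untreated `"yield_set"`s for the same condition.
#' @return Named list of [uvalue()]s: `heatLabileSSB` plus diagnostic
#'   differences `dDSB`, `dCL`, `dLossSC`.
#' @export
heat_labile <- function(heated, untreated) {
  check_treatment(heated, "heated")
  check_treatment(untreated, "untreated")
  if (!same_condition(heated, untreated))
    stop("heated and untreated yield sets are for different conditions")
  list(heatLabileSSB = udiff(heated$yields$circular, untreated$yields$circular),
       dDSB = udiff(heated$yields$linear, untreated$yields$linear),
       dCL = udiff(heated$yields$crosslinked, untreated$yields$crosslinked),
       dLossSC = udiff(heated$yields$SC, untreated$yields$SC))
}

#' Enzyme-revealed base-damage lesions
#'
#' Nth excises damaged pyrimidines and Fpg damaged purines, converting base
#' lesions into strand breaks. The additional SSB, DSB, CL and
#' loss-of-supercoiled yields of the two enzyme digests over the baseline
#' are summed (the two base classes are disjoint) to give, respectively,
#' isolated BDs, non-DSB clustered damages (NDCDs), BD-related crosslinks
#' and total BDs. Negative differences (noise) are carried, not clipped.
#'
#' @param nth,fpg `"yield_set"`s for the Nth and Fpg digests.
#' @param baseline `"yield_set"` the differences are taken against; the
#'   heated portion by default (enzyme incubation includes the same 37 degC
#'   hour, so heat-labile breaks are present in both and cancel).
#' @return Named list of [uvalue()]s: `isolatedBD`, `NDCD`, `BD-CL`,
#'   `totalBD`.
#' @export
enzyme_lesions <- function(nth, fpg, baseline) {
  check_treatment(nth, "Nth")
  check_treatment(fpg, "Fpg")
  if (!same_condition(nth, baseline) || !same_condition(fpg, baseline))
    stop("enzyme and baseline yield sets are for different conditions")
  extra <- function(form)
    usum(udiff(nth$yields[[form]], baseline$yields[[form]]),
         udiff(fpg$yields[[form]], baseline$yields[[form]]))
  list(isolatedBD = extra("circular"), NDCD = extra("linear"),
       `BD-CL` = extra("crosslinked"), totalBD = extra("SC"))
}

#' Total damage yield
#'
#' Total damage is the loss of supercoiled (every plasmid that left the
#' supercoiled band) plus the total base damage revealed by the enzymes.
#' Note that total BD is measured on the supercoiled band and need not
#' equal the sum isolatedBD + NDCD + BD-CL; no such identity is enforced.
#'
#' @param lesions named list of [uvalue()]s containing `LossSC` and
#'   `totalBD`, or a `"lesion_yields"` data frame row set for one condition.
#' @return A [uvalue()].
#' @export
total_damage <- function(lesions) {
  if (is.data.frame(lesions)) {
    pick <- function(l) {
      r <- lesions[lesions$lesion == l, ]
      if (nrow(r) != 1) stop("need exactly one '", l, "' row")
      uvalue(r$yield, r$sd)
    }
    lesions <- list(LossSC = pick("LossSC"), totalBD = pick("totalBD"))
  }
  if (!all(c("LossSC", "totalBD") %in% names(lesions)))
    stop("need LossSC and totalBD entries")
  usum(lesions$LossSC, lesions$totalBD)
}

#' Assemble the full lesion table for one substrate condition
#'
#' Combines [prompt_lesions()], [heat_labile()], [enzyme_lesions()] and
#' [total_damage()] for the four treatments of one (substrate, gas,
#' hydration) condition.
#'
#' @param untreated,heated,nth,fpg `"yield_set"`s for the four treatments
#'   of the same condition.
#' @param enzyme_baseline `"heated"` (default) or `"untreated"`: which
#'   portion the enzyme differences are taken against.
#' @return A `"lesion_yields"` data frame with columns
#'   `gas, gamma, substrate, lesion, yield, sd` covering the nine-lesion
#'   taxonomy plus `heatLabileSSB`.
#' @export
condition_lesions <- function(untreated, heated, nth, fpg,
                              enzyme_baseline = c("heated", "untreated")) {
  enzyme_baseline <- match.arg(enzyme_baseline)
  for (ys in list(heated, nth, fpg))
    if (!same_condition(untreated, ys))
      stop("yield sets are for different conditions")
  prompt <- prompt_lesions(untreated)
  hl <- heat_labile(heated, untreated)
  base <- if (enzyme_baseline == "heated") heated else untreated
  enz <- enzyme_lesions(nth, fpg, base)
  lesions <- c(prompt, enz)
  lesions$total <- total_damage(lesions)
  lesions$heatLabileSSB <- hl$heatLabileSSB
  out <- lesion_df(untreated$gas, untreated$gamma, untreated$substrate,
                   lesions[c(LESION_LEVELS, "heatLabileSSB")])
  class(out) <- c("lesion_yields", "data.frame")
  out
}

#' Isolate the low-energy-electron contribution by substrate subtraction
#'
#' Damage on tantalum is photon damage plus photoelectron (LEE) damage,
#' while glass emits a negligible photoelectron current; the LEE yield of
#' every lesion is therefore the Ta-minus-glass difference, with
#' uncertainties combined in quadrature.
#'
#' @param ta,glass `"lesion_yields"` data frames for the same (gas,
#'   hydration) condition on the Ta and glass substrates.
#' @return A `"lesion_yields"` data frame with `substrate = "LEE"`.
#' @export
lee_yields <- function(ta, glass) {
  for (x in list(ta, glass)) if (!inherits(x, "lesion_yields"))
    stop("expected 'lesion_yields' inputs")
  if (unique(ta$substrate) != "Ta" || unique(glass$substrate) != "glass")
    stop("inputs must be the Ta and glass lesion tables, in that order")
  if (!identical(unique(ta$gas), unique(glass$gas)) ||
      !identical(unique(ta$gamma), unique(glass$gamma)))
    stop("Ta and glass tables are for different conditions")
  m <- match(ta$lesion, glass$lesion)
  if (anyNA(m) || nrow(ta) != nrow(glass))
    stop("Ta and glass tables cover different lesions")
  d <- udiff(uvalue(ta$yield, ta$sd), uvalue(glass$yield[m], glass$sd[m]))
  out <- data.frame(gas = ta$gas, gamma = ta$gamma, substrate = "LEE",
                    lesion = ta$lesion, yield = d$value, sd = d$sd,
                    row.names = NULL)
  class(out) <- c("lesion_yields", "data.frame")
  out
}

#' Write lesion yields to CSV
#'
#' @param lesions a `"lesion_yields"` data frame (one row per
#'   gas/gamma/substrate/lesion).
#' @param path CSV path.
#' @export
write_lesion_yields <- function(lesions, path) {
  utils::write.csv(as.data.frame(lesions), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
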
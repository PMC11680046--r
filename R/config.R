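#' Closed vocabularies of the assay
#'
#' Levels shared by every stage of the pipeline: the five electrophoresis
#' bands, the two substrates, the two gas atmospheres, the four hydration
#' levels (water molecules per nucleotide), the four treatment arms, the
#' nine-lesion taxonomy resolved by the assay, and the primitive lesion
#' classes the forward simulator is parameterised by.
#'
#' @name vocabularies
#' @aliases BAND_LEVELS SUBSTRATE_LEVELS GAS_LEVELS GAMMA_LEVELS
#'   TREATMENT_LEVELS LESION_LEVELS PRIMITIVE_LESIONS
NULL

#' @rdname vocabularies
#' @export
BAND_LEVELS <- c("SC", "circular", "linear", "crosslinked", "concatemer")
#' @rdname vocabularies
#' @export
SUBSTRATE_LEVELS <- c("Ta", "glass")
#' @rdname vocabularies
#' @export
GAS_LEVELS <- c("O2", "N2")
#' @rdname vocabularies
#' @export
GAMMA_LEVELS <- c(2.5, 10, 20, 33)
#' @rdname vocabularies
#' @export
TREATMENT_LEVELS <- c("untreated", "heated", "Nth", "Fpg")
#' @rdname vocabularies
#' @export
LESION_LEVELS <- c("CL", "SSB", "DSB", "LossSC", "BD-CL", "isolatedBD",
                   "NDCD", "totalBD", "total")
#' @rdname vocabularies
#' @export
PRIMITIVE_LESIONS <- c("SSB", "DSB", "CL", "isolatedBD", "NDCD", "BD-CL",
                       "heatLabileSSB")

# grams per base pair of duplex DNA (650 Da/bp average)
.DA_PER_BP <- 650
.G_PER_DA <- 1.6605e-24

#' Physical constants and geometry of the irradiation experiment
#'
#' Bundles every constant entering the yield -> G-value conversion for
#' 1.5 keV X-ray irradiation of five-monolayer (15 nm) plasmid films on
#' tantalum and glass substrates, where photons traversing the film eject
#' low-energy photoelectrons (0-30 eV) from the Ta surface.
#'
#' @param photon_energy energy per incident photon, eV.
#' @param eta_e electrons emitted from the Ta-DNA interface per incident
#'   photon (dimensionless).
#' @param eta_e_sd standard deviation of `eta_e`, propagated into every
#'   LEE G-value.
#' @param mean_lee_energy mean energy of the emitted photoelectron
#'   distribution, eV.
#' @param cf_x,cf_lee multiplicative corrections (>= 1) for the finite film
#'   thickness, applied to X-ray and LEE G-values respectively.
#' @param sc_stain_factor correction applied to the supercoiled band
#'   intensity for the weaker binding of SYBR Green I to that conformation.
#' @param plasmid_bp plasmid length, base pairs.
#' @param dna_mass_per_film DNA mass deposited per film, ng.
#' @param film_radius film radius, mm.
#' @param film_radius_sd standard deviation of the film radius, mm
#'   (diagnostic; not propagated by default).
#' @param x_abs_frac fraction of incident photons absorbed within the film
#'   (sets the default effective absorbing area).
#' @param x_abs_area effective absorbing area, cm^2: film area times the
#'   fraction of photons absorbed in the film. Fluence (photons/cm^2) times
#'   this area is the number of photons absorbed, making the G-value
#'   formulas dimensionally pure counts.
#' @param x_trans_area effective transmitting area, cm^2: film area times
#'   the fraction of photons reaching the Ta substrate.
#' @param n_dna plasmid molecules per film; derived from
#'   `dna_mass_per_film` and `plasmid_bp` at 650 Da per base pair unless
#'   overridden.
#' @return An object of class `"pipeline_config"` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$n_dna       # ~9.3e10 plasmids per 320 ng film
#' @export
pipeline_config <- function(photon_energy = 1486,
                            eta_e = 0.057,
                            eta_e_sd = 0.005,
                            mean_lee_energy = 5.33,
                            cf_x = 1.094,
                            cf_lee = 1.05,
                            sc_stain_factor = 1.12,
                            plasmid_bp = 3197,
                            dna_mass_per_film = 320,
                            film_radius = 2.0,
                            film_radius_sd = 0.1,
                            x_abs_frac = 0.003,
                            x_abs_area = NULL,
                            x_trans_area = NULL,
                            n_dna = NULL) {
  film_area <- pi * (film_radius / 10)^2  # mm -> cm
  if (is.null(x_abs_area)) x_abs_area <- film_area * x_abs_frac
  if (is.null(x_trans_area)) x_trans_area <- film_area * (1 - x_abs_frac)
  if (is.null(n_dna)) {
    n_dna <- dna_mass_per_film * 1e-9 / (plasmid_bp * .DA_PER_BP * .G_PER_DA)
  }
  cfg <- list(
    photon_energy = photon_energy, eta_e = eta_e, eta_e_sd = eta_e_sd,
    mean_lee_energy = mean_lee_energy, cf_x = cf_x, cf_lee = cf_lee,
    sc_stain_factor = sc_stain_factor, plasmid_bp = plasmid_bp,
    dna_mass_per_film = dna_mass_per_film, film_radius = film_radius,
    film_radius_sd = film_radius_sd, x_abs_area = x_abs_area,
    x_trans_area = x_trans_area, n_dna = n_dna
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("all configuration fields must be numeric")
  pos <- setdiff(names(cfg), c("eta_e_sd", "film_radius_sd"))
  bad <- pos[vapply(cfg[pos], function(x) !is.finite(x) || x <= 0, logical(1))]
  if (length(bad))
    stop("configuration fields must be positive: ", paste(bad, collapse = ", "))
  if (cfg$cf_x < 1 || cfg$cf_lee < 1)
    stop("finite-thickness corrections cf_x and cf_lee must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  cat(sprintf("  photon energy     %g eV\n", x$photon_energy))
  cat(sprintf("  eta_e             %g ± %g electrons/photon\n",
              x$eta_e, x$eta_e_sd))
  cat(sprintf("  mean LEE energy   %g eV\n", x$mean_lee_energy))
  cat(sprintf("  CF_X / CF_LEE     %g / %g\n", x$cf_x, x$cf_lee))
  cat(sprintf("  SC stain factor   %g\n", x$sc_stain_factor))
  cat(sprintf("  plasmid           %d bp, %g ng/film, N_DNA = %.3g\n",
              x$plasmid_bp, x$dna_mass_per_film, x$n_dna))
  cat(sprintf("  X_abs / X_trans   %.4g / %.4g cm^2\n",
              x$x_abs_area, x$x_trans_area))
  invisible(x)
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Every field of [pipeline_config()] may appear as a key; missing keys take
#' the defaults. Unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# Validate one condition key; used by readers and the simulator.
check_condition <- function(substrate, gas, gamma, treatment) {
  if (!all(substrate %in% SUBSTRATE_LEVELS))
    stop("unknown substrate: ",
         paste(setdiff(substrate, SUBSTRATE_LEVELS), collapse = ", "))
  if (!all(gas %in% GAS_LEVELS))
    stop("unknown gas: ", paste(setdiff(gas, GAS_LEVELS), collapse = ", "))
  if (!all(gamma %in% GAMMA_LEVELS))
    stop("hydration level gamma must be one of ",
         paste(GAMMA_LEVELS, collapse = ", "), "; got ",
         paste(setdiff(gamma, GAMMA_LEVELS), collapse = ", "))
  if (!all(treatment %in% TREATMENT_LEVELS))
    stop("unknown treatment: ",
         paste(setdiff(treatment, TREATMENT_LEVELS), collapse = ", "))
  invisible(TRUE)
}
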
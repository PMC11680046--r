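#' Tabulated electron energy spectrum
#'
#' A 0-30 eV electron energy distribution Z(E), e.g. the photoelectron
#' spectrum emitted from the Ta-DNA interface or a secondary-electron
#' distribution produced by high-energy radiation in water. Weights need
#' not be normalised; every use is invariant to their overall scale.
#'
#' @param energy strictly increasing energy grid, eV.
#' @param weight non-negative weights per energy, with a positive integral.
#' @param label character label for the spectrum.
#' @param allow_outside permit energies outside the 0-30 eV contract.
#' @return An object of class `"electron_spectrum"`.
#' @export
electron_spectrum <- function(energy, weight, label = "spectrum",
                              allow_outside = FALSE) {
  if (length(energy) != length(weight) || length(energy) < 1)
    stop("energy and weight must be equal-length, non-empty")
  if (is.unsorted(energy, strictly = TRUE))
    stop("energies must be strictly increasing")
  if (!allow_outside && (min(energy) < 0 || max(energy) > 30))
    stop("energies outside 0-30 eV (set allow_outside = TRUE to permit)")
  if (any(weight < 0)) stop("weights must be non-negative")
  if (sum(weight) <= 0) stop("spectrum weights must have a positive sum")
  structure(list(energy = energy, weight = weight, label = label),
            class = "electron_spectrum")
}

#' Tabulated damage-yield function Y(E)
#'
#' Electron-energy dependence of a lesion's damage yield on 0-30 eV, in
#' arbitrary units (every use is scale-invariant).
#'
#' @param energy strictly increasing energy grid, eV.
#' @param value non-negative yields per energy.
#' @param lesion lesion label.
#' @inheritParams electron_spectrum
#' @return An object of class `"yield_function"`.
#' @export
yield_function <- function(energy, value, lesion = "lesion",
                           allow_outside = FALSE) {
  if (length(energy) != length(value) || length(energy) < 1)
    stop("energy and value must be equal-length, non-empty")
  if (is.unsorted(energy, strictly = TRUE))
    stop("energies must be strictly increasing")
  if (!allow_outside && (min(energy) < 0 || max(energy) > 30))
    stop("energies outside 0-30 eV (set allow_outside = TRUE to permit)")
  if (any(value < 0)) stop("yields must be non-negative")
  structure(list(energy = energy, value = value, lesion = lesion),
            class = "yield_function")
}

read_two_col <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected a two-column CSV (energy, value)")
  if (!all(vapply(tab[1:2], is.numeric, logical(1))))
    stop("both columns must be numeric")
  tab
}

#' Load a spectrum or yield function from a two-column CSV
#'
#' @param path CSV with columns (energy_eV, value); the label is taken
#'   from the file name.
#' @param allow_outside permit energies outside the 0-30 eV contract.
#' @return An `"electron_spectrum"` / `"yield_function"`.
#' @export
load_spectrum <- function(path, allow_outside = FALSE) {
  tab <- read_two_col(path)
  electron_spectrum(tab[[1]], tab[[2]],
                    label = sub("\\.[^.]*$", "", basename(path)),
                    allow_outside = allow_outside)
}

#' @rdname load_spectrum
#' @export
load_yield_function <- function(path, allow_outside = FALSE) {
  tab <- read_two_col(path)
  yield_function(tab[[1]], tab[[2]],
                 lesion = sub("\\.[^.]*$", "", basename(path)),
                 allow_outside = allow_outside)
}

#' Write a spectrum or yield function to CSV
#'
#' @param x an `"electron_spectrum"` or `"yield_function"`.
#' @param path CSV path.
#' @export
write_spectrum <- function(x, path) {
  if (inherits(x, "electron_spectrum")) {
    utils::write.csv(data.frame(energy_eV = x$energy, weight = x$weight),
                     path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "yield_function")) {
    utils::write.csv(data.frame(energy_eV = x$energy, value = x$value),
                     path, row.names = FALSE, quote = FALSE)
  } else stop("x must be an electron_spectrum or yield_function")
  invisible(path)
}

# Energy-normalised damage efficiency of a spectrum:
#   W(Z) = integral(Z(E) Y(E) dE) / integral(Z(E) E dE),
# i.e. damages per unit energy carried by electrons drawn from Z.
# Trapezoidal on the common (union, interpolated) grid; a single-point
# (delta-like) spectrum degenerates to Y(E0)/E0.
spectral_weight <- function(yf, spectrum) {
  if (length(spectrum$energy) == 1) {
    e0 <- spectrum$energy
    if (e0 < min(yf$energy) || e0 > max(yf$energy))
      stop("spectrum energy outside the yield function's grid")
    y0 <- stats::approx(yf$energy, yf$value, xout = e0)$y
    if (e0 <= 0) stop("zero spectrum energy: W undefined")
    return(y0 / e0)
  }
  lo <- max(min(yf$energy), min(spectrum$energy))
  hi <- min(max(yf$energy), max(spectrum$energy))
  if (lo >= hi) stop("yield function and spectrum grids do not overlap")
  grid <- sort(unique(c(yf$energy, spectrum$energy)))
  grid <- grid[grid >= lo & grid <= hi]
  z <- stats::approx(spectrum$energy, spectrum$weight, xout = grid)$y
  y <- stats::approx(yf$energy, yf$value, xout = grid)$y
  denom <- pracma::trapz(grid, z * grid)
  if (denom <= 0) stop("spectrum deposits no energy on the common grid")
  pracma::trapz(grid, z * y) / denom
}

#' Re-express a G-value under a different electron energy distribution
#'
#' A measured G-value is tied to the energy distribution of the electrons
#' that produced it. Given the lesion's yield function Y(E), the G-value
#' under another 0-30 eV distribution is generated by rescaling with the
#' energy-deposition-weighted yield ratio:
#' `G(Z_target) = G_ref * W(Z_target) / W(Z_ref)` with
#' `W(Z) = integral(Z Y dE) / integral(Z E dE)` (trapezoidal, linear
#' interpolation onto the union grid). A delta-like single-point spectrum
#' at E0 gives `W = Y(E0)/E0`. The transform is invariant to rescaling
#' Y or either spectrum's weights by positive constants, and the identity
#' `Z_target = Z_ref` returns `G_ref` unchanged.
#'
#' This weighting is this package's realisation of the spectrum-transfer
#' procedure; it is anchored only to the requirement that the target's
#' energy-dependent yield function be known.
#'
#' @param yf a [yield_function()] for the lesion.
#' @param target an [electron_spectrum()] to re-express the G-value under.
#' @param reference the [electron_spectrum()] the reference G-value was
#'   measured with.
#' @param g_ref reference G-value ([uvalue()] or numeric).
#' @return A [uvalue()] G-value under the target distribution.
#' @export
spectral_g <- function(yf, target, reference, g_ref) {
  if (!inherits(yf, "yield_function")) stop("yf must be a 'yield_function'")
  for (s in list(target, reference)) if (!inherits(s, "electron_spectrum"))
    stop("spectra must be 'electron_spectrum' objects")
  w_t <- spectral_weight(yf, target)
  w_r <- spectral_weight(yf, reference)
  if (w_r <= 0) stop("reference spectrum yields zero damage efficiency")
  uscale(as_uvalue(g_ref), w_t / w_r)
}
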
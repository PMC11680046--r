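#' G-value table
#'
#' A `"g_table"` holds G-values (damages per 100 eV of energy deposited)
#' per (gas, hydration level, source, lesion), where `source` is `"X"`
#' (photon damage, glass substrate), `"LEE"` (Ta-minus-glass photoelectron
#' damage) or a spectrum label for re-weighted values.
#'
#' @param df data frame with columns `gas, gamma, source, lesion, G, sd`.
#' @return The validated data frame with class `"g_table"`.
#' @export
g_table <- function(df) {
  need <- c("gas", "gamma", "source", "lesion", "G", "sd")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("g_table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(df$G))) stop("G-values must be finite")
  if (any(df$sd < 0)) stop("G-value sds must be non-negative")
  bad <- setdiff(df$lesion, c(LESION_LEVELS, "heatLabileSSB"))
  if (length(bad))
    stop("unknown lesion: ", paste(bad, collapse = ", "))
  df <- as.data.frame(df)
  class(df) <- c("g_table", "data.frame")
  df
}

#' Look up one cell of a G-value table
#'
#' @param g a `"g_table"`.
#' @param source,lesion,gamma cell keys.
#' @param gas gas atmosphere; defaults to the table's single gas.
#' @return A [uvalue()].
#' @export
g_cell <- function(g, source, lesion, gamma, gas = unique(g$gas)) {
  if (length(gas) != 1) stop("specify 'gas': table holds several")
  r <- g[g$gas == gas & g$gamma == gamma & g$source == source &
           g$lesion == lesion, ]
  if (nrow(r) != 1)
    stop(sprintf("missing cell: %s %s gamma=%s %s", gas, source, gamma, lesion))
  uvalue(r$G, r$sd)
}

#' G-value of photon-induced damage (glass substrate)
#'
#' Converts an effective yield measured on glass into a G-value: the
#' number of damages per fluence, `D = yield * n_dna`, divided by the
#' energy absorbed in the film per fluence, `photon_energy * x_abs_area`,
#' times the finite-thickness correction and 100:
#' `G_X = yield * n_dna * 100 * cf_x / (photon_energy * x_abs_area)`.
#'
#' @param lesion_yield a [uvalue()] yield, damages per plasmid per
#'   photon cm^-2.
#' @param config a [pipeline_config()].
#' @return A [uvalue()] G-value (damages / 100 eV).
#' @export
g_x <- function(lesion_yield, config = pipeline_config()) {
  if (config$x_abs_area <= 0) stop("x_abs_area must be positive")
  k <- config$n_dna * 100 * config$cf_x /
    (config$photon_energy * config$x_abs_area)
  uscale(as_uvalue(lesion_yield), k)
}

#' G-value of LEE-induced damage (Ta minus glass)
#'
#' Converts a substrate-subtracted LEE yield into a G-value. The energy
#' delivered by photoelectrons per unit fluence is `eta_e * x_trans_area *
#' mean_lee_energy` (electrons per transmitted photon times their mean
#' energy), so
#' `G_LEE = yield * n_dna * 100 * cf_lee / (eta_e * x_trans_area * Ebar)`.
#' The uncertainty of `eta_e` (relative, default 0.005/0.057) is folded
#' into the G-value sd in quadrature.
#'
#' @inheritParams g_x
#' @return A [uvalue()] G-value (damages / 100 eV).
#' @export
g_lee <- function(lesion_yield, config = pipeline_config()) {
  if (config$eta_e <= 0 || config$mean_lee_energy <= 0)
    stop("eta_e and mean_lee_energy must be positive")
  k <- config$n_dna * 100 * config$cf_lee /
    (config$eta_e * config$x_trans_area * config$mean_lee_energy)
  y <- as_uvalue(lesion_yield)
  g <- k * y$value
  rel_eta <- config$eta_e_sd / config$eta_e
  uvalue(g, sqrt((k * y$sd)^2 + (g * rel_eta)^2))
}

#' Convert a lesion-yield table into a G-value table
#'
#' Applies [g_x()] to the glass rows and [g_lee()] to the LEE
#' (Ta-minus-glass) rows of a lesion table; Ta rows, which mix the two
#' energy-deposition channels, have no G-value of their own and are
#' dropped.
#'
#' @param lesions a `"lesion_yields"` data frame with substrates among
#'   `glass`, `Ta`, `LEE`.
#' @param config a [pipeline_config()].
#' @return A `"g_table"` with sources `"X"` (from glass) and `"LEE"`.
#' @export
yields_to_gvalues <- function(lesions, config = pipeline_config()) {
  lesions <- as.data.frame(lesions)
  keep <- lesions$substrate %in% c("glass", "LEE")
  lesions <- lesions[keep, ]
  if (!nrow(lesions)) stop("no glass or LEE rows to convert")
  rows <- lapply(seq_len(nrow(lesions)), function(i) {
    y <- uvalue(lesions$yield[i], lesions$sd[i])
    g <- if (lesions$substrate[i] == "glass") g_x(y, config)
         else g_lee(y, config)
    data.frame(gas = lesions$gas[i], gamma = lesions$gamma[i],
               source = if (lesions$substrate[i] == "glass") "X" else "LEE",
               lesion = lesions$lesion[i], G = g$value, sd = g$sd)
  })
  g_table(do.call(rbind, rows))
}

#' Write / read a G-value table
#'
#' @param g a `"g_table"`.
#' @param path CSV path (`gas, gamma, source, lesion, G, sd`).
#' @export
write_gtable <- function(g, path) {
  utils::write.csv(as.data.frame(g), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gtable
#' @export
read_gtable <- function(path) {
  g_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
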
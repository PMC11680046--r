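BAND_TABLE_COLS <- c("substrate", "gas", "gamma", "treatment", "fluence",
                     "replicate", "band", "intensity")

#' Read a gel-lane band table from CSV
#'
#' Entry point of the analysis: quantified band intensities (ImageQuant-style
#' output), one row per (condition, lane, band). An optional `series` column
#' distinguishes independent repeats of the exposure-response series; it
#' defaults to 1.
#'
#' @param path CSV file with columns
#'   `substrate, gas, gamma, treatment, fluence, replicate, band, intensity`
#'   (plus optional `series`).
#' @return A validated band table (data frame).
#' @export
read_band_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_band_table(tab)
}

#' @rdname read_band_table
#' @param tab a band table data frame to validate (e.g. from
#'   [simulate_experiment()]).
#' @export
validate_band_table <- function(tab) {
  missing_cols <- setdiff(BAND_TABLE_COLS, names(tab))
  if (length(missing_cols))
    stop("band table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"series" %in% names(tab)) tab$series <- 1L
  check_condition(tab$substrate, tab$gas, tab$gamma, tab$treatment)
  bad_band <- setdiff(unique(tab$band), BAND_LEVELS)
  if (length(bad_band))
    stop("unknown band label: ", paste(bad_band, collapse = ", "))
  neg <- which(tab$intensity < 0)
  if (length(neg))
    stop("negative intensity in row ", neg[1])
  key <- interaction(tab$substrate, tab$gas, tab$gamma, tab$treatment,
                     tab$series, tab$fluence, tab$replicate, tab$band,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate (condition, fluence, replicate, band) entry in row ", d)
  }
  tab
}

#' Write a band table (and optionally its generating truth) to CSV
#'
#' @param tab a band table.
#' @param path output CSV path.
#' @param truth optional generating G-value table, written alongside as
#'   `<path minus .csv>_truth.csv` for provenance.
#' @return `path`, invisibly.
#' @export
write_band_table <- function(tab, path, truth = NULL) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    tpath <- sub("\\.csv$", "", path)
    utils::write.csv(as.data.frame(truth), paste0(tpath, "_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Normalise one lane's band intensities to conformation fractions
#'
#' The supercoiled intensity is first multiplied by the stain factor to
#' undo the weaker SYBR Green I binding of that conformation, then all
#' bands are divided by the corrected lane total, so per-lane loading
#' differences cancel. Fractions, not intensities, are the analysis
#' currency.
#'
#' @param intensities named numeric vector over the five bands (any order;
#'   missing bands count as 0); at least one must be positive.
#' @param sc_stain_factor supercoiled staining correction (default 1.12).
#' @return Named fractions over `SC, circular, linear, crosslinked,
#'   concatemer`, summing to 1.
#' @export
normalize_lane <- function(intensities, sc_stain_factor = 1.12) {
  x <- stats::setNames(numeric(length(BAND_LEVELS)), BAND_LEVELS)
  bad <- setdiff(names(intensities), BAND_LEVELS)
  if (length(bad))
    stop("unknown band label: ", paste(bad, collapse = ", "))
  x[names(intensities)] <- intensities
  if (any(x < 0)) stop("negative band intensity")
  x[["SC"]] <- x[["SC"]] * sc_stain_factor
  tot <- sum(x)
  if (tot <= 0) stop("all-zero lane cannot be normalised")
  x / tot
}

#' Normalise a whole band table to lane fractions
#'
#' Applies [normalize_lane()] to every lane of a long-format band table.
#'
#' @param tab a band table (see [read_band_table()]).
#' @param sc_stain_factor supercoiled staining correction.
#' @return A wide data frame of class `"lane_fractions"`: one row per lane
#'   with columns `substrate, gas, gamma, treatment, series, fluence,
#'   replicate` and one fraction column per band.
#' @export
normalize_band_table <- function(tab, sc_stain_factor = 1.12) {
  tab <- validate_band_table(tab)
  keycols <- c("substrate", "gas", "gamma", "treatment", "series",
               "fluence", "replicate")
  key <- interaction(tab[keycols], drop = TRUE)
  idx <- split(seq_len(nrow(tab)), key)
  rows <- lapply(idx, function(i) {
    fr <- normalize_lane(stats::setNames(tab$intensity[i], tab$band[i]),
                         sc_stain_factor)
    cbind(tab[i[1], keycols, drop = FALSE], as.data.frame(as.list(fr)))
  })
  out <- do.call(rbind, rows)
  names(out) <- c(keycols, BAND_LEVELS)
  rownames(out) <- NULL
  class(out) <- c("lane_fractions", "data.frame")
  out
}

#' Write / read lane fractions
#'
#' CSV serialisation of the wide per-lane fraction table, with the same key
#' columns as the band table.
#'
#' @param fractions a `"lane_fractions"` data frame.
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the lane-fraction table (reader).
#' @export
write_lane_fractions <- function(fractions, path) {
  utils::write.csv(as.data.frame(fractions), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lane_fractions
#' @export
read_lane_fractions <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate", "gas", "gamma", "treatment", "series", "fluence",
            "replicate", BAND_LEVELS)
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols))
    stop("lane fractions file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  sums <- rowSums(out[BAND_LEVELS])
  if (any(abs(sums - 1) > 1e-6))
    stop("lane fractions must sum to 1")
  class(out) <- c("lane_fractions", "data.frame")
  out
}
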
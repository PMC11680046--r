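#' Half-up decimal rounding for display
#'
#' Rounds halves away from zero at a fixed number of decimals (the
#' convention that reproduces the published one-decimal ratio cells from
#' the published G-values), unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Hydration enhancement ratio of G-values
#'
#' Ratio of a lesion's G-value at high hydration to that at low hydration
#' (default gamma 33 over 2.5, i.e. bulk-like water over dry film), with
#' the sd from [uratio()].
#'
#' @param g a `"g_table"`.
#' @param source `"X"` or `"LEE"`.
#' @param lesion lesion name.
#' @param gamma_hi,gamma_lo hydration levels compared.
#' @param gas gas atmosphere (defaults to the table's single gas).
#' @return A [uvalue()].
#' @export
enhancement_ratio <- function(g, source, lesion, gamma_hi = 33,
                              gamma_lo = 2.5, gas = unique(g$gas)) {
  uratio(g_cell(g, source, lesion, gamma_hi, gas),
         g_cell(g, source, lesion, gamma_lo, gas))
}

#' Oxygen enhancement ratio table
#'
#' Cellwise ratio of G-values measured under O2 to those measured under N2
#' for every (gamma, source, lesion) cell present in both tables. Cells
#' whose N2 value sits near background (too small for a meaningful ratio)
#' are omitted by listing them explicitly in `omit` — the omission is an
#' input flag, not an automatic threshold.
#'
#' @param g_o2,g_n2 `"g_table"`s for the two atmospheres.
#' @param omit optional data frame with columns `source, lesion, gamma` of
#'   cells to leave out.
#' @return A data frame (class `"ratio_table"`) with columns
#'   `statistic = "OER"`, `source, lesion, gamma, value, sd`.
#' @export
oer <- function(g_o2, g_n2, omit = NULL) {
  keys <- c("gamma", "source", "lesion")
  m <- merge(as.data.frame(g_o2), as.data.frame(g_n2), by = keys,
             suffixes = c("_o2", "_n2"))
  if (!nrow(m)) stop("the two G tables have no overlapping cells")
  if (!is.null(omit)) {
    drop <- interaction(m$source, m$lesion, m$gamma) %in%
      interaction(omit$source, omit$lesion, omit$gamma)
    m <- m[!drop, ]
  }
  r <- uratio(uvalue(m$G_o2, m$sd_o2), uvalue(m$G_n2, m$sd_n2))
  out <- data.frame(statistic = "OER", source = m$source, lesion = m$lesion,
                    gamma = m$gamma, value = r$value, sd = r$sd)
  out <- out[order(out$source, match(out$lesion, LESION_LEVELS), out$gamma), ]
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Ratio of LEE to X-ray G-values
#'
#' Cellwise G_LEE/G_X per (gamma, lesion), plus each lesion's maximum over
#' hydration levels — the headline comparison of photoelectron versus
#' photon damage efficiency.
#'
#' @param g a `"g_table"` holding both `"X"` and `"LEE"` sources.
#' @param gas gas atmosphere (defaults to the table's single gas).
#' @return A `"ratio_table"` data frame with statistic `"LEE_over_X"`
#'   (per-gamma cells) and `"LEE_over_X_max"` (per-lesion maxima, with
#'   `gamma` the argmax).
#' @export
lee_over_x <- function(g, gas = unique(g$gas)) {
  if (length(gas) != 1) stop("specify 'gas': table holds several")
  g <- g[g$gas == gas & g$lesion %in% LESION_LEVELS, ]
  lees <- g[g$source == "LEE", ]
  m <- merge(as.data.frame(lees), as.data.frame(g[g$source == "X", ]),
             by = c("gamma", "lesion"), suffixes = c("_lee", "_x"))
  if (!nrow(m)) stop("need both LEE and X sources")
  m <- m[m$G_x != 0, ]  # a zero photon G-value admits no ratio
  if (!nrow(m)) stop("all X cells are zero; no ratios to form")
  r <- uratio(uvalue(m$G_lee, m$sd_lee), uvalue(m$G_x, m$sd_x))
  cells <- data.frame(statistic = "LEE_over_X", source = "LEE/X",
                      lesion = m$lesion, gamma = m$gamma,
                      value = r$value, sd = r$sd)
  maxima <- do.call(rbind, lapply(split(cells, cells$lesion), function(d) {
    i <- which.max(d$value)
    data.frame(statistic = "LEE_over_X_max", source = "LEE/X",
               lesion = d$lesion[i], gamma = d$gamma[i],
               value = d$value[i], sd = d$sd[i])
  }))
  out <- rbind(cells, maxima)
  out <- out[order(out$statistic, match(out$lesion, LESION_LEVELS), out$gamma), ]
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Direct / indirect decomposition of LEE damage
#'
#' Under the approximation that the water-mediated (indirect) contribution
#' adds linearly to the direct one, the direct share at hydration `gamma`
#' is the dry-film G-value over the hydrated one:
#' `direct_pct = 100 * G_LEE(2.5) / G_LEE(gamma)`, and
#' `indirect_pct = 100 - direct_pct` (exactly, by construction).
#'
#' @param g_lee a `"g_table"` with an `"LEE"` source (other sources are
#'   ignored).
#' @param lesion lesion name.
#' @param gamma hydration level of the hydrated cell; `2.5` returns
#'   `c(100, 0)` by definition.
#' @param gas gas atmosphere (defaults to the table's single gas).
#' @return Named numeric `c(direct_pct, indirect_pct)`.
#' @export
direct_indirect <- function(g_lee, lesion, gamma, gas = unique(g_lee$gas)) {
  if (gamma == 2.5) return(c(direct_pct = 100, indirect_pct = 0))
  dry <- g_cell(g_lee, "LEE", lesion, 2.5, gas)
  wet <- g_cell(g_lee, "LEE", lesion, gamma, gas)
  direct <- 100 * dry$value / wet$value
  c(direct_pct = direct, indirect_pct = 100 - direct)
}

#' Render a G-value report
#'
#' Deterministic plain-text table of G-values (one block per source, one
#' row per hydration level, one column per lesion, `G ± sd`), followed by
#' hydration enhancement-ratio rows and any supplied ratio table, all with
#' half-up rounding at the configured number of decimals. Negative
#' displayed G-values (pure-noise estimates carried unclipped through the
#' analysis) are shown as 0 with a footnote.
#'
#' @param g a `"g_table"`.
#' @param ratios optional `"ratio_table"` to append.
#' @param decimals decimals for display (G-values and ratios).
#' @param path optional: write the text report to `<path>.txt` and CSVs to
#'   `<path>_gvalues.csv` / `<path>_ratios.csv`.
#' @return Character vector of report lines, invisibly when `path` given.
#' @export
render_report <- function(g, ratios = NULL, decimals = 1, path = NULL) {
  fmt <- function(v, s) {
    v2 <- round_half_up(v, decimals)
    clip <- v2 < 0
    v2[clip] <- 0
    paste0(formatC(v2, format = "f", digits = decimals),
           " ± ", formatC(round_half_up(s, decimals), format = "f",
                          digits = decimals),
           ifelse(clip, " *", ""))
  }
  lines <- character()
  clipped <- FALSE
  lesions <- intersect(LESION_LEVELS, unique(g$lesion))
  for (gas in sort(unique(g$gas))) {
    for (src in sort(unique(g$source[g$gas == gas]))) {
      sub <- g[g$gas == gas & g$source == src, ]
      gammas <- sort(unique(sub$gamma))
      lines <- c(lines,
                 sprintf("G_%s (damages/100 eV), %s atmosphere", src, gas),
                 paste(c(sprintf("%-8s", "gamma"),
                         sprintf("%-14s", lesions)), collapse = ""))
      for (gm in gammas) {
        cells <- vapply(lesions, function(l) {
          r <- sub[sub$gamma == gm & sub$lesion == l, ]
          if (!nrow(r)) return("")
          if (r$G < 0) clipped <<- TRUE
          fmt(r$G, r$sd)
        }, character(1))
        lines <- c(lines, paste(c(sprintf("%-8s", gm),
                                  sprintf("%-14s", cells)), collapse = ""))
      }
      if (length(gammas) > 1) {
        er <- vapply(lesions, function(l) {
          ok <- all(c(min(gammas), max(gammas)) %in% sub$gamma[sub$lesion == l])
          if (!ok) return("")
          r <- enhancement_ratio(g, src, l, max(gammas), min(gammas), gas)
          formatC(round_half_up(r$value, decimals), format = "f",
                  digits = decimals)
        }, character(1))
        lines <- c(lines, paste(c(sprintf("%-8s", "ER"),
                                  sprintf("%-14s", er)), collapse = ""))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(ratios) && nrow(ratios)) {
    lines <- c(lines, "Ratio statistics")
    lines <- c(lines, sprintf("%-16s %-8s %-12s %-6s %s", "statistic",
                              "source", "lesion", "gamma", "value"))
    for (i in seq_len(nrow(ratios))) {
      lines <- c(lines, sprintf("%-16s %-8s %-12s %-6s %s",
                                ratios$statistic[i], ratios$source[i],
                                ratios$lesion[i], ratios$gamma[i],
                                formatC(round_half_up(ratios$value[i], decimals),
                                        format = "f", digits = decimals)))
    }
    lines <- c(lines, "")
  }
  if (clipped)
    lines <- c(lines, "* negative estimate (noise) displayed as 0")
  if (!is.null(path)) {
    writeLines(lines, paste0(path, ".txt"))
    gg <- as.data.frame(g)
    gg$G <- round_half_up(gg$G, decimals)
    gg$sd <- round_half_up(gg$sd, decimals)
    utils::write.csv(gg, paste0(path, "_gvalues.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(ratios)) {
      rr <- as.data.frame(ratios)
      rr$value <- round_half_up(rr$value, decimals)
      rr$sd <- round_half_up(rr$sd, decimals)
      utils::write.csv(rr, paste0(path, "_ratios.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    return(invisible(lines))
  }
  lines
}
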
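#' Reference G-values for plasmid films irradiated under oxygen
#'
#' Published reference measurement for this assay: G-values (damages per
#' 100 eV) for all nine gel-resolvable lesion classes induced in
#' five-monolayer pGEM-3Zf(-) plasmid films by 1.5 keV X-rays (`source =
#' "X"`, glass substrate) and by the 0-30 eV photoelectrons emitted from a
#' tantalum substrate (`source = "LEE"`, Ta-minus-glass), under a pure O2
#' atmosphere at hydration levels gamma = 2.5, 10, 20 and 33 water
#' molecules per nucleotide. Standard deviations are from six identical
#' measurements. Finite-thickness corrections (CF_X = 1.094,
#' CF_LEE = 1.05) are already applied.
#'
#' Used as the worked-example input for the ratio statistics and as the
#' generating truth for parameter-recovery simulations.
#'
#' @return A `"g_table"` (gas `"O2"`, sources `"X"` and `"LEE"`, 4 gamma
#'   levels x 9 lesions).
#' @export
reference_gvalues <- function() {
  lesions <- c("CL", "SSB", "DSB", "LossSC", "BD-CL", "isolatedBD",
               "NDCD", "totalBD", "total")
  cell <- function(gamma, source, G, sd)
    data.frame(gas = "O2", gamma = gamma, source = source,
               lesion = lesions, G = G, sd = sd)
  g_table(rbind(
    cell(2.5, "LEE", c(0.3, 7.8, 1.4, 8.3, 0.7, 12.5, 1.5, 13.1, 21.4),
         c(0.1, 2.1, 0.3, 2.3, 0.1, 1.5, 0.2, 1.7, 2.0)),
    cell(10, "LEE", c(0.5, 9.7, 1.4, 10.0, 0.9, 14.1, 1.7, 14.8, 24.9),
         c(0.1, 2.2, 0.1, 1.8, 0.1, 2.0, 0.1, 1.9, 2.0)),
    cell(20, "LEE", c(0.6, 11.8, 1.5, 12.7, 1.0, 17.4, 1.7, 19.2, 32.0),
         c(0.1, 1.9, 0.1, 2.3, 0.1, 2.0, 0.1, 1.9, 2.1)),
    cell(33, "LEE", c(0.7, 16.7, 2.0, 18.0, 1.2, 19.5, 2.4, 24.5, 42.5),
         c(0.1, 1.7, 0.1, 2.1, 0.1, 1.9, 0.1, 1.9, 2.2)),
    cell(2.5, "X", c(0.17, 3.3, 0.28, 3.5, 0.09, 0.7, 0.27, 0.8, 4.2),
         c(0.02, 0.2, 0.03, 0.3, 0.01, 0.2, 0.02, 0.2, 0.2)),
    cell(10, "X", c(0.16, 3.4, 0.28, 3.7, 0.09, 0.7, 0.12, 0.9, 4.6),
         c(0.01, 0.1, 0.01, 0.1, 0.01, 0.2, 0.01, 0.2, 0.2)),
    cell(20, "X", c(0.17, 4.0, 0.18, 4.0, 0.10, 1.1, 0.11, 1.4, 5.4),
         c(0.01, 0.2, 0.01, 0.2, 0.01, 0.2, 0.01, 0.2, 0.2)),
    cell(33, "X", c(0.16, 3.9, 0.20, 3.9, 0.09, 1.1, 0.22, 1.5, 5.5),
         c(0.01, 0.1, 0.01, 0.2, 0.01, 0.2, 0.01, 0.2, 0.2))
  ))
}
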
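# Monte-Carlo propagation oracle. The spread is measured as the half-width
# of the central 68.27% interval: for a ratio of Gaussians the sample sd is
# dominated by the heavy tail (its moments diverge as the denominator
# approaches zero), so the interval-based spread is the meaningful
# comparison with first-order propagation.
mc_spread <- function(f, a, b, n = 1e5) {
  xa <- rnorm(n, a$value, a$sd)
  xb <- rnorm(n, b$value, b$sd)
  r <- f(xa, xb)
  unname(diff(quantile(r, pnorm(c(-1, 1)))) / 2)
}

# Extend a primitive-lesion G table with the derived lesions implied by the
# single-event model (the G conversion is linear, so sums carry over):
# LossSC = SSB + DSB + CL, totalBD = isolatedBD + NDCD + BD-CL,
# total = LossSC + totalBD.
derived_truth <- function(g) {
  g <- as.data.frame(g)
  conds <- unique(g[c("gas", "gamma", "source")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- g$gas == conds$gas[i] & g$gamma == conds$gamma[i] &
      g$source == conds$source[i]
    pick <- function(l) {
      r <- g$G[sel & g$lesion == l]
      if (length(r)) r else 0
    }
    loss <- pick("SSB") + pick("DSB") + pick("CL")
    bd <- pick("isolatedBD") + pick("NDCD") + pick("BD-CL")
    data.frame(gas = conds$gas[i], gamma = conds$gamma[i],
               source = conds$source[i],
               lesion = c("LossSC", "totalBD", "total", "heatLabileSSB"),
               G = c(loss, bd, loss + bd, pick("heatLabileSSB")), sd = 0)
  })
  prim <- g[g$lesion %in% c("SSB", "DSB", "CL", "isolatedBD", "NDCD",
                            "BD-CL"), ]
  rbind(prim, do.call(rbind, rows))
}

# Small, fast campaign for unit tests: one gamma level, two series.
small_design <- function(...) {
  experiment_design(slope_replicates = 2, ...)
}

small_truth <- function(gamma = 33) {
  g <- as.data.frame(reference_gvalues())
  g_table(g[g$gamma == gamma, ])
}
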
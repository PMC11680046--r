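test_that("hydration enhancement ratios reproduce the published display cells", {
  g <- reference_gvalues()
  er <- function(src, lesion)
    round_half_up(enhancement_ratio(g, src, lesion)$value, 1)
  expect_equal(er("LEE", "SSB"), 2.1)
  expect_equal(er("LEE", "DSB"), 1.4)
  expect_equal(er("LEE", "LossSC"), 2.2)
  expect_equal(er("LEE", "total"), 2.0)
  expect_equal(er("LEE", "BD-CL"), 1.7)
  expect_equal(er("LEE", "isolatedBD"), 1.6)
  expect_equal(er("LEE", "NDCD"), 1.6)
  expect_equal(er("LEE", "totalBD"), 1.9)
  expect_equal(er("X", "SSB"), 1.2)
  expect_equal(er("X", "DSB"), 0.7)
  expect_equal(er("X", "LossSC"), 1.1)
  expect_equal(er("X", "NDCD"), 0.8)
  expect_equal(er("X", "total"), 1.3)
  # dry-over-hydrated decrease factor for X-ray DSBs
  dec <- enhancement_ratio(g, "X", "DSB", gamma_hi = 2.5, gamma_lo = 33)
  expect_equal(round_half_up(dec$value, 1), 1.4)
  expect_equal(enhancement_ratio(g, "LEE", "CL", 33, 33)$value, 1)
  expect_error(enhancement_ratio(g, "LEE", "SSB", gamma_hi = 5), "missing cell")
})

test_that("LEE-to-X ratios and their hydration maxima match the published figures", {
  r <- lee_over_x(reference_gvalues())
  mx <- r[r$statistic == "LEE_over_X_max", ]
  pick <- function(l) mx$value[mx$lesion == l]
  expect_equal(round_half_up(pick("DSB"), 0), 10)
  expect_equal(round_half_up(pick("NDCD"), 0), 15)
  expect_equal(round_half_up(pick("BD-CL"), 0), 13)
  cells <- r[r$statistic == "LEE_over_X" & r$gamma == 33, ]
  expect_equal(round_half_up(cells$value[cells$lesion == "CL"], 0), 4)
  expect_equal(round_half_up(cells$value[cells$lesion == "isolatedBD"], 0), 18)
  # NDCD peaks at gamma = 20, not at full hydration
  expect_equal(mx$gamma[mx$lesion == "NDCD"], 20)
})

test_that("direct/indirect split divides the dry G-value by the hydrated one", {
  g <- reference_gvalues()
  di <- function(gamma) direct_indirect(g, "total", gamma)
  expect_equal(round_half_up(di(10)[["direct_pct"]], 0), 86)
  expect_equal(round_half_up(di(20)[["direct_pct"]], 0), 67)
  expect_equal(round_half_up(di(33)[["direct_pct"]], 0), 50)
  expect_equal(di(2.5), c(direct_pct = 100, indirect_pct = 0))
  for (gamma in c(10, 20, 33))
    expect_equal(sum(di(gamma)), 100)
})

test_that("oxygen enhancement ratios are cellwise with explicit omissions", {
  g_o2 <- reference_gvalues()
  same <- oer(g_o2, g_o2)
  expect_true(all(abs(same$value - 1) < 1e-12))

  g_n2 <- as.data.frame(g_o2); g_n2$G <- g_n2$G / 2
  expect_true(all(abs(oer(g_o2, g_table(g_n2))$value - 2) < 1e-12))

  # synthetic N2 table giving cluster-lesion OERs {1.7, 1.8, 1.9} at gamma 33
  ratios <- c(DSB = 1.7, NDCD = 1.8, `BD-CL` = 1.9)
  g_n2 <- as.data.frame(g_o2)
  sel <- g_n2$source == "LEE" & g_n2$gamma == 33 &
    g_n2$lesion %in% names(ratios)
  g_n2$G[sel] <- g_n2$G[sel] / ratios[g_n2$lesion[sel]]
  r <- oer(g_o2, g_table(g_n2))
  cl <- r[r$source == "LEE" & r$gamma == 33 &
            r$lesion %in% names(ratios), ]
  expect_equal(mean(cl$value), 1.8, tolerance = 1e-12)

  # near-background cells are dropped only when explicitly flagged
  omit <- data.frame(source = "X", lesion = c("DSB", "BD-CL"), gamma = 33)
  r2 <- oer(g_o2, g_table(g_n2), omit = omit)
  expect_equal(nrow(r) - nrow(r2), 2)
  expect_false(any(r2$source == "X" & r2$gamma == 33 & r2$lesion == "DSB"))
})

test_that("every ratio statistic is invariant under global rescaling of G", {
  g <- reference_gvalues()
  g2 <- as.data.frame(g); g2$G <- g2$G * 3.7; g2$sd <- g2$sd * 3.7
  g2 <- g_table(g2)
  expect_equal(enhancement_ratio(g2, "LEE", "SSB")$value,
               enhancement_ratio(g, "LEE", "SSB")$value)
  expect_equal(lee_over_x(g2)$value, lee_over_x(g)$value)
  expect_equal(direct_indirect(g2, "total", 33),
               direct_indirect(g, "total", 33))
  expect_equal(oer(g2, g2)$value, oer(g, g)$value)
})

test_that("rendered reports are deterministic and honest about clipping", {
  g <- reference_gvalues()
  r <- lee_over_x(g)
  out1 <- render_report(g, r, decimals = 1)
  out2 <- render_report(g, r, decimals = 1)
  expect_identical(out1, out2)
  # the LEE enhancement-ratio row carries the published display values
  er_line <- out1[grep("^ER", out1)[1]]
  expect_match(er_line, "2.1")
  expect_true(any(grepl("Ratio statistics", out1)))
  expect_false(any(grepl("\\*", render_report(g))))

  neg <- as.data.frame(g)
  neg$G[neg$lesion == "CL" & neg$gamma == 2.5 & neg$source == "X"] <- -0.05
  outn <- render_report(g_table(neg))
  expect_true(any(grepl("negative estimate", outn)))

  path <- tempfile()
  render_report(g, r, path = path)
  expect_true(file.exists(paste0(path, ".txt")))
  expect_true(file.exists(paste0(path, "_gvalues.csv")))
  expect_true(file.exists(paste0(path, "_ratios.csv")))
})

test_that("display rounding is half-up at the configured decimals", {
  expect_equal(round_half_up(1.986, 1), 2.0)
  expect_equal(round_half_up(0.25, 1), 0.3)   # base round() would give 0.2
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(15.45, 0), 15)
  expect_equal(round_half_up(85.94, 0), 86)
})
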
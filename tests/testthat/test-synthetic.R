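test_that("G-values invert to per-plasmid damage rates", {
  cfg <- pipeline_config()
  g <- data.frame(gas = "O2", gamma = 33, source = c("X", "LEE"),
                  lesion = "SSB", G = c(3.3, 16.7), sd = 0)
  r <- gvalues_to_rates(g, cfg)
  glass <- r[r$substrate == "glass", "SSB"]
  lee <- r[r$substrate == "LEE", "SSB"]
  expect_equal(glass, 3.3 * 1486 * cfg$x_abs_area / (100 * 1.094 * cfg$n_dna))
  expect_equal(lee, 16.7 * 0.057 * cfg$x_trans_area * 5.33 /
                 (100 * 1.05 * cfg$n_dna))
  # substrate-subtraction premise: Ta = glass + LEE for every lesion
  expect_equal(unlist(r[r$substrate == "Ta", PRIMITIVE_LESIONS]),
               unlist(r[r$substrate == "glass", PRIMITIVE_LESIONS]) +
                 unlist(r[r$substrate == "LEE", PRIMITIVE_LESIONS]))
  # zero G gives zero rates; negative G rejected
  g0 <- g; g0$G <- 0
  expect_true(all(gvalues_to_rates(g0, cfg)[PRIMITIVE_LESIONS] == 0))
  gneg <- g; gneg$G[1] <- -1
  expect_error(gvalues_to_rates(gneg, cfg), "negative")
})

test_that("expected fractions follow the single-event Poisson partition", {
  f0 <- experiment_design()$f0
  rates <- setNames(rep(1e-13, length(PRIMITIVE_LESIONS)), PRIMITIVE_LESIONS)

  expect_equal(expected_fractions(rates, "untreated", 0, f0), f0)
  zero <- setNames(numeric(length(PRIMITIVE_LESIONS)), PRIMITIVE_LESIONS)
  expect_equal(expected_fractions(zero, "Fpg", 3e10, f0), f0)

  # output is a simplex for any treatment and fluence
  for (tr in c("untreated", "heated", "Nth", "Fpg")) {
    fr <- expected_fractions(rates, tr, 5e10, f0)
    expect_equal(sum(fr), 1)
    expect_true(all(fr >= 0))
  }

  # small-mean limit: circular gain ~ f0_SC * m_SSB within 1% up to m = 0.02
  for (m in c(0.001, 0.01, 0.02)) {
    r <- zero; r[["SSB"]] <- m / 1e10
    fr <- expected_fractions(r, "untreated", 1e10, f0)
    gain <- fr[["circular"]] - f0[["circular"]]
    expect_equal(gain, f0[["SC"]] * m, tolerance = 0.01)
  }

  # enzyme treatments only add damage: non-SC fractions never decrease
  un <- expected_fractions(rates, "untreated", 5e10, f0)
  for (tr in c("Nth", "Fpg")) {
    en <- expected_fractions(rates, tr, 5e10, f0)
    expect_true(all(en[c("circular", "linear", "crosslinked")] >=
                      un[c("circular", "linear", "crosslinked")]))
    expect_lte(en[["SC"]], un[["SC"]])
  }
})

test_that("simulated campaigns are deterministic and unbiased at zero noise", {
  truth <- small_truth()
  d <- small_design()
  b1 <- simulate_experiment(truth, d, noise_sd = 0.003, seed = 7)
  b2 <- simulate_experiment(truth, d, noise_sd = 0.003, seed = 7)
  expect_identical(b1, b2)
  b3 <- simulate_experiment(truth, d, noise_sd = 0.003, seed = 8)
  expect_false(identical(b1, b3))

  # zero noise and no stain bias: intensities are exactly the model fractions
  cfg <- pipeline_config(sc_stain_factor = 1)
  b <- simulate_experiment(truth, d, cfg, noise_sd = 0, seed = 1)
  rates <- gvalues_to_rates(truth, cfg)
  one <- b[b$substrate == "Ta" & b$treatment == "untreated" &
             b$fluence == d$fluences[3] & b$series == 1 & b$replicate == 1, ]
  expt <- expected_fractions(
    unlist(rates[rates$substrate == "Ta", PRIMITIVE_LESIONS]),
    "untreated", d$fluences[3], d$f0)
  expect_equal(setNames(one$intensity, one$band), expt[one$band])
})

test_that("noise-free slopes match rate-implied slopes in the linear regime", {
  truth <- small_truth()
  cfg <- pipeline_config()
  rates <- gvalues_to_rates(truth, cfg)
  # scale exposures so the largest Poisson mean is ~0.01
  d <- experiment_design(flux = 2.5e8, slope_replicates = 1)
  b <- simulate_experiment(truth, d, cfg, noise_sd = 0, seed = 1)
  fr <- normalize_band_table(b, cfg$sc_stain_factor)
  for (sub in c("glass", "Ta")) {
    r <- unlist(rates[rates$substrate == sub, PRIMITIVE_LESIONS])
    lanes <- fr[fr$substrate == sub & fr$treatment == "untreated", ]
    slope <- fit_exposure_response(lanes, "circular")$slope$value
    expect_equal(slope, d$f0[["SC"]] * r[["SSB"]], tolerance = 0.005)
    slope_lin <- fit_exposure_response(lanes, "linear")$slope$value
    expect_equal(slope_lin, d$f0[["SC"]] * r[["DSB"]], tolerance = 0.005)
  }

  # Ta - glass slope difference equals the LEE-implied slope once curvature
  # is negligible (very low fluence)
  dlin <- experiment_design(flux = 1e6, slope_replicates = 1)
  blin <- simulate_experiment(truth, dlin, cfg, noise_sd = 0, seed = 1)
  frl <- normalize_band_table(blin, cfg$sc_stain_factor)
  s <- sapply(c("Ta", "glass"), function(sub)
    fit_exposure_response(frl[frl$substrate == sub &
                                frl$treatment == "untreated", ],
                          "circular")$slope$value)
  r_lee <- unlist(rates[rates$substrate == "LEE", "SSB"])
  expect_equal(unname(s["Ta"] - s["glass"]), dlin$f0[["SC"]] * unname(r_lee),
               tolerance = 1e-4)
})

test_that("experiment design validates its inputs", {
  expect_error(experiment_design(fluences = c(0, 2, 1)), "increasing")
  expect_error(experiment_design(p_pyrimidine = 1.2), "0, 1")
  expect_error(experiment_design(f0 = c(SC = 0.5, circular = 0.1)), "sum to 1")
  d <- experiment_design()
  expect_equal(sum(d$f0), 1)
  expect_equal(d$fluences[1], 0)
  expect_error(simulate_experiment(small_truth(), d, noise_sd = 0),
               "seed")
})
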
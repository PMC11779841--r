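test_that("scenario construction is deterministic and validates its schema", {
  s1 <- build_scenario(scenario_preset(), seed = 7)
  s2 <- build_scenario(scenario_preset(), seed = 7)
  expect_identical(s1, s2)
  expect_equal(s1$days, 1:5)
  # day-2 biomass maximum in the default trajectory
  expect_equal(which.max(s1$ground_truth$relative_total_biomass), 2L)
  # late residual biomass around 20 percent of the maximum
  expect_lt(s1$ground_truth$relative_total_biomass[5], 0.30)

  bad <- scenario_preset()
  bad$components$carbohydrate$mobile_fraction_by_day[2] <- 1.2
  expect_error(build_scenario(bad),
               "components.carbohydrate.mobile_fraction_by_day",
               fixed = TRUE)
  bad2 <- scenario_preset()
  bad2$days <- c(1, 1, 2)
  expect_error(build_scenario(bad2), "days")
  bad3 <- scenario_preset()
  bad3$sample_mass_per_day <- c(30, 30, -1, 30, 30)
  expect_error(build_scenario(bad3), "sample_mass_per_day")
})

test_that("noiseless qDP spectrum conserves configured component area", {
  sc <- build_scenario(single_peak_config())
  sp <- render_spectrum(sc, 1, "qDP")
  # unit biomass x 30 mg x 1 scan, unit-area Lorentzian; truncation < 0.5 %
  area <- integrate_region(sp, range(sp$ppm))
  expect_equal(area, 30, tolerance = 0.005)
  expect_true(all(diff(sp$ppm) < 0))  # descending storage convention
})

test_that("DP2s applies the mono-exponential saturation weight per phase", {
  # fully mobile component, T1 = 0.3 s: weight 1 - exp(-2/0.3)
  sc_m <- build_scenario(single_peak_config(mobile_fraction = 1,
                                            t1_mobile = 0.3))
  a_q <- integrate_region(render_spectrum(sc_m, 1, "qDP"), c(-10, 200))
  a_d <- integrate_region(render_spectrum(sc_m, 1, "DP2s"), c(-10, 200))
  expect_equal(a_d / a_q, 1 - exp(-2 / 0.3), tolerance = 1e-9)

  # rigid-only component, T1 = 10 s: weight 1 - exp(-0.2), strongly attenuated
  sc_r <- build_scenario(single_peak_config(mobile_fraction = 0,
                                            t1_rigid = 10))
  a_q <- integrate_region(render_spectrum(sc_r, 1, "qDP"), c(-10, 200))
  a_d <- integrate_region(render_spectrum(sc_r, 1, "DP2s"), c(-10, 200))
  expect_equal(a_d / a_q, 1 - exp(-0.2), tolerance = 1e-9)
  expect_lt(a_d / a_q, 0.2)
})

test_that("qDP area dominates DP2s area for every component and day", {
  sc <- build_scenario(noiseless_config(2048), seed = 11)
  for (day in sc$days) {
    a_q <- integrate_region(render_spectrum(sc, day, "qDP"), c(-10, 200)) /
      sc$scans_per_mode[["qDP"]]
    a_d <- integrate_region(render_spectrum(sc, day, "DP2s"), c(-10, 200)) /
      sc$scans_per_mode[["DP2s"]]
    expect_gte(a_q, a_d)
    expect_gte(a_d, 0)
  }
})

test_that("CP spectra are rigid-only and flagged non-quantitative", {
  sc_m <- build_scenario(single_peak_config(mobile_fraction = 1))
  cp <- render_spectrum(sc_m, 1, "CP")
  expect_true(cp$non_quantitative)
  expect_equal(max(abs(cp$intensity)), 0)
  sc_r <- build_scenario(single_peak_config(mobile_fraction = 0))
  a_cp <- integrate_region(render_spectrum(sc_r, 1, "CP"), c(-10, 200))
  a_q <- integrate_region(render_spectrum(sc_r, 1, "qDP"), c(-10, 200))
  expect_equal(a_cp / a_q, sc_r$cp_efficiency, tolerance = 1e-9)
  expect_error(render_spectrum(sc_r, 1, "DARR"))
})

test_that("rendered spectra are byte-identical under a fixed seed", {
  cfg <- scenario_preset()
  sc <- build_scenario(cfg, seed = 5)
  s1 <- render_spectrum(sc, 3, "qDP")
  s2 <- render_spectrum(build_scenario(cfg, seed = 5), 3, "qDP")
  expect_identical(s1, s2)
  s3 <- render_spectrum(build_scenario(cfg, seed = 6), 3, "qDP")
  expect_false(identical(s1$intensity, s3$intensity))
})

test_that("inversion-recovery emission follows the recovery model", {
  sc <- build_scenario(noiseless_config(64))
  ir <- emit_inversion_recovery(sc, "GlcA-C1", delays = c(0, 0.5, 1, 50),
                                noise_sigma = 0)
  expect_equal(ir$intensities[1], -1)            # full inversion at t = 0
  expect_equal(ir$intensities[4], 1, tolerance = 1e-6)  # plateau
  expect_error(emit_inversion_recovery(sc, "GlcA-C1", delays = numeric(0)),
               "empty")
  expect_error(emit_inversion_recovery(sc, "no-such-site"), "no true T1")
})

test_that("dipshift emission matches the simulator at the true coupling", {
  sc <- build_scenario(noiseless_config(64))
  cv <- emit_dipshift(sc, "PG-GlcNAc-C3", noise_sigma = 0)
  ref <- simulate_dipshift(0.70 * sc$delta_rigid, "CH",
                           mas_rate = sc$mas_rate,
                           scaling = sc$fslg_scaling)
  expect_equal(cv$intensity, ref$intensity, tolerance = 1e-12)
  expect_equal(cv$intensity[1], 1)
  expect_error(emit_dipshift(sc, "PG-GlcNAc-C3", multiplicity = "CH3"),
               "multiplicity")
})

test_that("sugar tables encode missing medium values as NA, never zero", {
  sc <- build_scenario(noiseless_config(64))
  tabs <- emit_sugar_tables(sc)
  glcn_medium <- tabs$medium$integral[tabs$medium$sugar == "GlcN"]
  expect_true(all(is.na(glcn_medium)))
  expect_false(any(!is.na(glcn_medium) & glcn_medium == 0))
  # GlcA day 1 gap present, later days populated
  glca <- tabs$medium[tabs$medium$sugar == "GlcA", ]
  expect_true(is.na(glca$integral[glca$day == 1]))
  expect_false(anyNA(glca$integral[glca$day %in% 2:5]))
  # truth labels drop unclusterable sugars
  expect_true(is.na(tabs$cluster[["GlcN"]]))
  expect_equal(sum(!is.na(tabs$cluster)), 7)
})

test_that("constant partition ratios give a constant feature matrix", {
  days <- 1:5
  tb <- data.frame(sugar = rep(c("X", "Y"), each = 5), day = rep(days, 2),
                   integral = rep(c(2, 3), each = 5))
  feats <- compute_ratio_features(tb, tb, days = 2:5)
  expect_true(all(feats == 1))
})
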
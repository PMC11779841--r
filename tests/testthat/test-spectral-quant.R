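make_spectrum <- function(ppm, intensity, mass = 30, scans = 64,
                          mode = "qDP", day = 1) {
  spectrum1d(ppm, intensity, sample_mass = mass, n_scans = scans,
             mode = mode, day = day)
}

test_that("region integration matches the closed-form Lorentzian integral", {
  ppm <- seq(200, -10, length.out = 16384)
  hwhm <- 0.5
  y <- (hwhm / pi) / ((ppm - 90)^2 + hwhm^2)
  sp <- make_spectrum(ppm, y)
  # closed form: (atan((105-90)/0.5) + atan((90-74)/0.5)) / pi
  expected <- (atan(30) + atan(32)) / pi
  expect_equal(integrate_region(sp, c(74, 105)), expected, tolerance = 0.005)
  # zero input
  expect_equal(integrate_region(make_spectrum(ppm, 0 * ppm), c(74, 105)), 0)
  # zero-overlap interval errors
  expect_error(integrate_region(sp, c(300, 400)), "does not overlap")
})

test_that("integrals over adjacent intervals add exactly", {
  set.seed(3)
  ppm <- seq(200, -10, length.out = 4097)
  sp <- make_spectrum(ppm, rnorm(length(ppm)))
  total <- integrate_region(sp, c(74, 105))
  parts <- integrate_region(sp, c(74, 90)) + integrate_region(sp, c(90, 105))
  expect_equal(parts, total, tolerance = 1e-12)
})

test_that("integration is independent of ppm storage direction", {
  set.seed(4)
  ppm <- seq(-10, 200, length.out = 2048)
  y <- abs(rnorm(length(ppm)))
  up <- make_spectrum(ppm, y)
  down <- make_spectrum(rev(ppm), rev(y))
  expect_equal(integrate_region(up, c(20, 150)),
               integrate_region(down, c(20, 150)), tolerance = 1e-12)
})

test_that("carbon biomass density normalizes by mass and scans", {
  # flat unit spectrum over a 96-ppm interval: integral 96
  ppm <- seq(100, 4, length.out = 1001)
  sp <- make_spectrum(ppm, rep(1, 1001), mass = 30, scans = 64)
  expect_equal(carbon_biomass_density(sp), 96 / (30 * 64), tolerance = 1e-12)
  # scale invariance: doubled intensities with doubled scan count
  sp2 <- make_spectrum(ppm, rep(2, 1001), mass = 30, scans = 128)
  expect_equal(carbon_biomass_density(sp2), carbon_biomass_density(sp),
               tolerance = 1e-12)
  # non-qDP spectra warn
  cp <- make_spectrum(ppm, rep(1, 1001), mode = "CP")
  expect_warning(carbon_biomass_density(cp), "quantitative")
})

test_that("mobile fraction is the density ratio, clamped with a warning", {
  ppm <- seq(150, 50, length.out = 501)
  qdp <- make_spectrum(ppm, rep(2, 501), mode = "qDP")
  same <- make_spectrum(ppm, rep(2, 501), mode = "DP2s")
  expect_equal(mobile_fraction(same, qdp), 1.0)
  noisy <- make_spectrum(ppm, rep(2.06, 501), mode = "DP2s")  # ratio 1.03
  expect_warning(f <- mobile_fraction(noisy, qdp), "clamped")
  expect_equal(f, 1.0)
  zero <- make_spectrum(ppm, rep(0, 501), mode = "qDP")
  expect_error(mobile_fraction(same, zero), "not positive")
})

test_that("two-phase scenario recovers the true mobile fraction", {
  cfg <- single_peak_config(mobile_fraction = 0.91, t1_mobile = 0.5,
                            t1_rigid = 20)
  sc <- build_scenario(cfg)
  qdp <- render_spectrum(sc, 1, "qDP")
  dp2s <- render_spectrum(sc, 1, "DP2s")
  expect_equal(mobile_fraction(dp2s, qdp), 0.91, tolerance = 0.01)
})

test_that("component quantification recovers the configured trajectories", {
  sc <- build_scenario(noiseless_config(2048), seed = 2)
  spectra <- list()
  for (day in sc$days) {
    for (m in c("qDP", "DP2s")) {
      spectra[[length(spectra) + 1]] <- render_spectrum(sc, day, m)
    }
  }
  cq <- component_quant(spectra)
  gt <- sc$ground_truth
  for (cl in c("carbohydrate", "protein")) {
    est <- cq$relative_density[cq$class == cl]
    tru <- gt$relative_biomass[, cl]
    expect_gt(cor(est, tru), 0.99)
    expect_equal(est[2], 1.0)   # reference-day normalization
    expect_equal(est, tru, tolerance = 0.02)
  }
  # missing day/mode pairing reported
  expect_error(component_quant(spectra[-1]), "missing day/mode")
  # empty region list rejected
  expect_error(component_quant(spectra, regions = list(carbohydrate = NULL),
                               classes = "carbohydrate"), "empty region")
})

test_that("peak tracking reports presence/absence and normalizes to the maximum", {
  ppm <- seq(100, 30, length.out = 2001)
  lor <- function(c0, a) a * (0.2 / pi) / ((ppm - c0)^2 + 0.2^2)
  days <- list(lor(65.187, 1), lor(65.187, 0.5), 0 * ppm)
  spectra <- lapply(seq_along(days), function(i) {
    make_spectrum(ppm, days[[i]], day = i)
  })
  tr <- track_peak_intensity(spectra, center = 65.187, window = 0.5)
  expect_equal(tr$normalized[1], 1.0)
  expect_lt(tr$normalized[3], 0.01)
  # constant peak: all ones
  const <- lapply(1:3, function(i) make_spectrum(ppm, lor(65.187, 1), day = i))
  expect_equal(track_peak_intensity(const, 65.187, 0.5)$normalized,
               rep(1, 3))
  # integral statistic available as an alternative
  tr2 <- track_peak_intensity(spectra, 65.187, 0.5, stat = "integral")
  expect_equal(tr2$normalized[2], 0.5, tolerance = 0.01)
  expect_error(track_peak_intensity(spectra, 65.187, window = -1), "window")
  expect_error(track_peak_intensity(spectra, center = 300, window = 0.5),
               "outside the axis")
})

test_that("component grouping normalizes to the reference and sums to 100 %", {
  vols <- expand.grid(peak = paste0("pk", 1:6), day = 1:3)
  set.seed(9)
  vols$volume <- runif(nrow(vols), 1, 10)
  cmap <- c(pk1 = "proteins", pk2 = "proteins", pk3 = "exopolysaccharides",
            pk4 = "nucleotides", pk5 = "lipids/biosurfactants")
  tab <- group_components(vols, cmap)
  sums <- as.numeric(tapply(tab$proportion, tab$day, sum))
  expect_equal(sums, rep(100, 3), tolerance = 1e-9)
  expect_equal(tab$quantity[tab$category == "proteins" & tab$day == 2], 100)
  expect_true("unknown" %in% tab$category)  # pk6 unmapped
  # one-category table: proportion 100 %
  one <- data.frame(peak = "pk1", day = 1, volume = 5)
  t1 <- group_components(one, c(pk1 = "proteins"),
                         reference = list(category = "proteins", day = 1))
  expect_equal(t1$proportion, 100)
  # duplicated peak identifiers rejected
  dup <- rbind(one, one)
  expect_error(group_components(dup, c(pk1 = "proteins")), "duplicated")
})

test_that("a lipid spike is recovered at its configured magnitude", {
  vols <- rbind(
    data.frame(peak = "prot", day = c(3, 4), volume = c(50, 30)),
    data.frame(peak = "lipid", day = c(3, 4), volume = c(0.2, 1.8))
  )
  cmap <- c(prot = "proteins", lipid = "lipids/biosurfactants")
  tab <- group_components(vols, cmap,
                          reference = list(category = "proteins", day = 3))
  lip <- tab$quantity[tab$category == "lipids/biosurfactants"]
  expect_equal(lip[2] / lip[1], 9, tolerance = 1e-9)
})
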
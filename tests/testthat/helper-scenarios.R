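# Shared fixture builders. Everything is generated in code at test time.

# Noiseless copy of the default five-day scenario config, with an optionally
# reduced ppm axis for speed.
noiseless_config <- function(n_points = 4096) {
  cfg <- scenario_preset()
  cfg$noise_sigma <- 0
  cfg$dynamics_noise <- 0
  cfg$sugar_noise <- 0
  cfg$ppm_axis["n"] <- n_points
  cfg
}

# Minimal single-component scenario: one unit-area peak, fully mobile,
# configurable T1s. Used for area-conservation and saturation checks.
single_peak_config <- function(center = 90, width = 0.5, biomass = 1,
                               mobile_fraction = 1, t1_mobile = 0.3,
                               t1_rigid = 10, n_points = 8192) {
  list(
    days = 1L,
    ppm_axis = c(min = -10, max = 200, n = n_points),
    noise_sigma = 0, dynamics_noise = 0, sugar_noise = 0,
    mas_rate = 13.5,
    sample_mass_per_day = 30,
    scans_per_mode = c(qDP = 1, DP2s = 1, CP = 1),
    cp_efficiency = 0.5,
    delta_rigid = 22.7,
    fslg_scaling = 1 / sqrt(3),
    components = list(
      peak = list(
        peaks = data.frame(center = center, width = width, area = 1),
        biomass_by_day = biomass,
        mobile_fraction_by_day = mobile_fraction,
        t1_mobile = t1_mobile, t1_rigid = t1_rigid,
        order_parameter_by_day = 0.5
      )
    ),
    seed = 1L
  )
}

# Two sugar families with well-separated biofilm/medium partition profiles.
two_family_tables <- function(noise = 0) {
  days <- 1:5
  sugars <- list(
    A1 = list(family = "A", ratio = c(5.0, 4.5, 4.0, 3.5, 3.0)),
    A2 = list(family = "A", ratio = c(5.2, 4.6, 4.1, 3.4, 3.1)),
    A3 = list(family = "A", ratio = c(4.9, 4.4, 3.9, 3.6, 2.9)),
    B1 = list(family = "B", ratio = c(0.30, 0.25, 0.20, 0.15, 0.10)),
    B2 = list(family = "B", ratio = c(0.32, 0.24, 0.21, 0.14, 0.11)),
    B3 = list(family = "B", ratio = c(0.29, 0.26, 0.19, 0.16, 0.10))
  )
  medium <- do.call(rbind, lapply(names(sugars), function(nm) {
    data.frame(sugar = nm, day = days, integral = rep(1, 5))
  }))
  biofilm <- do.call(rbind, lapply(names(sugars), function(nm) {
    v <- sugars[[nm]]$ratio
    if (noise > 0) v <- v * (1 + stats::rnorm(5, 0, noise))
    data.frame(sugar = nm, day = days, integral = v)
  }))
  list(biofilm = biofilm, medium = medium,
       family = vapply(sugars, `[[`, character(1), "family"))
}

# Four well-separated Gaussian blobs in the plane.
four_blobs <- function(n_per = 8, sep = 20, sigma = 0.3, seed = 42) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep), c(sep, sep))
  pts <- do.call(rbind, lapply(1:4, function(i) {
    cbind(rnorm(n_per, centers[i, 1], sigma),
          rnorm(n_per, centers[i, 2], sigma))
  }))
  rownames(pts) <- paste0("p", seq_len(nrow(pts)))
  list(points = pts, labels = rep(1:4, each = n_per))
}
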
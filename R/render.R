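# Unit-area Lorentzian in ppm: hwhm is the half width at half maximum.
lorentzian <- function(ppm, center, hwhm) {
  (hwhm / pi) / ((ppm - center)^2 + hwhm^2)
}

# Mono-exponential saturation factor for a recycle delay rd against T1.
saturation_factor <- function(rd, t1) 1 - exp(-rd / t1)

# Per-phase detection weights of the three polarization modes. qDP is fully
# quantitative by construction; DP2s weights each phase by its saturation
# factor at a 2 s recycle delay; CP sees only the rigid phase, scaled by a
# global non-quantitative efficiency.
mode_weights <- function(mode, t1_mobile, t1_rigid, cp_efficiency,
                         recycle_delay = 2) {
  switch(mode,
    qDP  = c(mobile = 1, rigid = 1),
    DP2s = c(mobile = saturation_factor(recycle_delay, t1_mobile),
             rigid  = saturation_factor(recycle_delay, t1_rigid)),
    CP   = c(mobile = 0, rigid = cp_efficiency),
    stop_input("unknown polarization mode '", mode, "'")
  )
}

#' Render a synthetic 1D spectrum for one day and polarization mode
#'
#' Each component contributes a sum of Lorentzian peaks whose total area is
#' `biomass x sample mass x number of scans` (unit-area calibration), split
#' between mobile and rigid phase by the component's mobile fraction and
#' weighted per phase by the polarization mode: quantitative DP detects both
#' phases fully, 2 s DP attenuates each phase by the mono-exponential
#' saturation factor `1 - exp(-2 / T1)`, and CP detects only the rigid phase
#' scaled by a non-quantitative efficiency. Additive Gaussian noise
#' (`scenario$noise_sigma`, intensity units) is drawn from a stream derived
#' deterministically from the scenario seed, the day and the mode.
#'
#' @param scenario a `scenario_spec` from [build_scenario()].
#' @param day one of `scenario$days`.
#' @param mode `"qDP"`, `"DP2s"` or `"CP"`.
#' @return a [spectrum1d()] (descending ppm axis).
#' @export
render_spectrum <- function(scenario, day, mode = c("qDP", "DP2s", "CP")) {
  stopifnot(inherits(scenario, "scenario_spec"))
  mode <- match.arg(mode)
  if (!day %in% scenario$days) {
    stop_input("day ", day, " is not in the scenario (",
               paste(scenario$days, collapse = ", "), ")")
  }
  di <- match(day, scenario$days)
  ax <- scenario$ppm_axis
  ppm <- seq(ax[[2]], ax[[1]], length.out = ax[[3]])  # descending
  mass <- scenario$sample_mass_per_day[[di]]
  scans <- scenario$scans_per_mode[[mode]]
  intensity <- numeric(length(ppm))
  for (comp in scenario$components) {
    w <- mode_weights(mode, comp$t1_mobile, comp$t1_rigid,
                      scenario$cp_efficiency)
    mf <- comp$mobile_fraction_by_day[di]
    phase_weight <- mf * w[["mobile"]] + (1 - mf) * w[["rigid"]]
    total_area <- comp$biomass_by_day[di] * mass * scans * phase_weight
    pk <- comp$peaks
    rel <- pk$area / sum(pk$area)
    for (j in seq_len(nrow(pk))) {
      intensity <- intensity +
        total_area * rel[j] * lorentzian(ppm, pk$center[j], pk$width[j])
    }
  }
  if (scenario$noise_sigma > 0) {
    intensity <- intensity + with_seed(
      derive_seed(scenario$seed, "spectrum", day, mode),
      stats::rnorm(length(ppm), 0, scenario$noise_sigma)
    )
  }
  spectrum1d(ppm, intensity, sample_mass = mass, n_scans = scans,
             mode = mode, day = day)
}

#' Emit a synthetic inversion-recovery series for one site
#'
#' Intensities follow the three-parameter recovery model
#' `I(t) = A + B exp(-t / T1)` with `A = 1`, `B = -2` (ideal inversion),
#' evaluated on a delay grid, plus optional additive Gaussian noise expressed
#' as a fraction of the dynamic range.
#'
#' @param scenario a `scenario_spec`.
#' @param site a site label present in `scenario$sites` with a true T1.
#' @param delays delay grid in seconds. The default targets slowly relaxing
#'   sites (T1 around 2.6 s): two baseline anchors, dense sampling near the
#'   expected T1 where the sensitivity of the recovery curve to T1 peaks,
#'   and plateau anchors.
#' @param noise_sigma noise, fraction of the dynamic range; defaults to
#'   `scenario$dynamics_noise`.
#' @return a list of class `inversion_recovery` with `site`, `delays`,
#'   `intensities`, `noise_sigma` and the true `t1`.
#' @export
emit_inversion_recovery <- function(scenario, site, delays = NULL,
                                    noise_sigma = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  t1 <- scenario$ground_truth$t1[site]
  if (is.na(t1)) stop_input("site '", site, "' has no true T1 in the scenario")
  if (is.null(delays)) {
    delays <- c(0.05, 0.1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 10, 12, 14)
  }
  if (length(delays) == 0) stop_input("delay grid must not be empty")
  if (any(delays < 0)) stop_input("delays must be >= 0")
  noise_sigma <- noise_sigma %||% scenario$dynamics_noise %||% 0
  intensities <- 1 - 2 * exp(-delays / t1)
  if (noise_sigma > 0) {
    rng <- diff(range(intensities))
    intensities <- intensities + with_seed(
      derive_seed(scenario$seed, "ir", site),
      stats::rnorm(length(delays), 0, noise_sigma * rng)
    )
  }
  structure(
    list(site = site, delays = delays, intensities = intensities,
         noise_sigma = noise_sigma, t1 = unname(t1)),
    class = "inversion_recovery"
  )
}

#' Emit a synthetic DIPSHIFT dephasing curve for one site
#'
#' The curve is produced by [simulate_dipshift()] at the site's true
#' effective coupling, `order parameter x rigid-limit coupling`, under the
#' scenario's MAS rate and FSLG scaling factor; optional additive Gaussian
#' noise is a fraction of the dynamic range.
#'
#' @param scenario a `scenario_spec`.
#' @param site a rigid-phase site label with a true order parameter.
#' @param multiplicity `"CH"` or `"CH2"`; defaults to the site's entry.
#' @param n_t1 number of dipolar evolution points across one rotor period.
#' @param noise_sigma noise, fraction of the dynamic range; defaults to
#'   `scenario$dynamics_noise`.
#' @return a `dipshift_curve` (see [simulate_dipshift()]) with the true
#'   order parameter attached as `$true_order_parameter`.
#' @export
emit_dipshift <- function(scenario, site, multiplicity = NULL, n_t1 = 16,
                          noise_sigma = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  s <- scenario$ground_truth$order_parameter[site]
  if (is.na(s)) {
    stop_input("site '", site, "' has no true order parameter in the scenario")
  }
  multiplicity <- multiplicity %||%
    unname(scenario$ground_truth$multiplicity[site])
  if (!multiplicity %in% c("CH", "CH2")) {
    stop_input("multiplicity must be 'CH' or 'CH2'")
  }
  noise_sigma <- noise_sigma %||% scenario$dynamics_noise %||% 0
  curve <- simulate_dipshift(
    delta_eff = unname(s) * scenario$delta_rigid,
    multiplicity = multiplicity,
    mas_rate = scenario$mas_rate,
    scaling = scenario$fslg_scaling,
    n_t1 = n_t1
  )
  if (noise_sigma > 0) {
    rng <- diff(range(curve$intensity))
    if (rng == 0) rng <- 1
    curve$intensity <- curve$intensity + with_seed(
      derive_seed(scenario$seed, "dipshift", site),
      stats::rnorm(length(curve$intensity), 0, noise_sigma * rng)
    )
  }
  curve$site <- site
  curve$true_order_parameter <- unname(s)
  curve
}

#' Emit synthetic biofilm and spent-medium sugar tables
#'
#' Per-sugar, per-day integrals for both compartments, with the clustered
#' temporal/partition structure of the scenario encoded in the ground truth.
#' Sugars absent from a compartment are emitted as missing (`NA`), never 0,
#' so downstream ratio features stay well defined. Relative Gaussian noise
#' (`scenario$sugar_noise`) is applied per cell from a seed-derived stream.
#'
#' @param scenario a `scenario_spec` defining at least two sugar families.
#' @return a list with tidy data frames `biofilm` and `medium`
#'   (columns `sugar`, `day`, `integral`) and the true `cluster` labels.
#' @export
emit_sugar_tables <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  sugars <- scenario$sugars
  if (is.null(sugars) || length(sugars) < 2) {
    stop_input("scenario must define at least 2 sugars")
  }
  fams <- unique(vapply(sugars, `[[`, character(1), "family"))
  if (length(fams) < 2) {
    stop_input("scenario must define at least 2 sugar families")
  }
  days <- scenario$days
  rel_noise <- scenario$sugar_noise %||% 0
  one <- function(compartment) {
    vals <- unlist(lapply(names(sugars), function(nm) {
      v <- sugars[[nm]][[compartment]]
      if (rel_noise > 0) {
        eps <- with_seed(
          derive_seed(scenario$seed, "sugar", compartment, nm),
          stats::rnorm(length(v), 0, rel_noise)
        )
        v <- v * (1 + eps)
        v[!is.na(v) & v < 0] <- 0
      }
      v
    }))
    data.frame(
      sugar = rep(names(sugars), each = length(days)),
      day = rep(days, times = length(sugars)),
      integral = vals,
      stringsAsFactors = FALSE
    )
  }
  list(
    biofilm = one("biofilm"),
    medium = one("medium"),
    cluster = scenario$ground_truth$sugar_cluster
  )
}
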
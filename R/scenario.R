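#' Default five-day biofilm scenario configuration
#'
#' Returns the configuration of the built-in `"bsubtilis-5day"` scenario: a
#' five-day static pellicle life cycle in which total carbon biomass peaks on
#' day 2 and decays to roughly 20 percent of its maximum by day 5, the mobile
#' phase dominates early (about 90 percent) and shrinks to the mid-70s late,
#' carbohydrate signals live in 74--105 ppm and protein signals in the
#' 10--29, 34--48, 106--124 and 132--160 ppm ranges, and eight monosaccharides
#' partition between biofilm and spent medium in four clustered families.
#'
#' All values are in the units used throughout the package: days (d), ppm,
#' seconds for relaxation times, kHz for couplings and spinning rates,
#' milligrams for sample masses.
#'
#' @param name preset name; only `"bsubtilis-5day"` is defined.
#' @return a nested list accepted by [build_scenario()].
#' @export
scenario_preset <- function(name = "bsubtilis-5day") {
  if (!identical(name, "bsubtilis-5day")) {
    stop_input("unknown scenario preset '", name, "'")
  }
  list(
    days = 1:5,
    ppm_axis = c(min = -10, max = 200, n = 4096),
    noise_sigma = 0.02,       # additive, spectrum intensity units per point
    dynamics_noise = 0.01,    # fraction of dynamic range, IR + DIPSHIFT series
    sugar_noise = 0.02,       # relative, sugar integral tables
    mas_rate = 13.5,          # kHz; assumption -- the acquisition rate is not fixed by the design
    sample_mass_per_day = c(30, 30, 30, 30, 30),
    scans_per_mode = c(qDP = 64, DP2s = 256, CP = 1024),
    cp_efficiency = 0.5,      # global, CP spectra are flagged non-quantitative
    delta_rigid = 22.7,       # kHz, rigid-limit one-bond C-H coupling
    fslg_scaling = 1 / sqrt(3),
    components = list(
      carbohydrate = list(
        peaks = data.frame(
          center = c(76.5, 82.0, 90.0, 98.8, 103.5),
          width  = c(1.2, 1.0, 1.5, 0.8, 0.9),
          area   = c(0.25, 0.30, 0.20, 0.15, 0.10)
        ),
        biomass_by_day = c(0.21, 0.30, 0.255, 0.150, 0.105),
        mobile_fraction_by_day = c(0.94, 0.94, 0.84, 0.78, 0.71),
        t1_mobile = 0.5,
        t1_rigid = 20,
        order_parameter_by_day = c(0.66, 0.72, 0.65, 0.60, 0.55)
      ),
      protein = list(
        peaks = data.frame(
          center = c(17.5, 24.0, 40.0, 44.5, 115.0, 136.0, 155.0),
          width  = c(1.0, 1.2, 1.5, 1.1, 1.3, 1.2, 1.0),
          area   = c(0.15, 0.15, 0.25, 0.15, 0.10, 0.12, 0.08)
        ),
        biomass_by_day = c(0.40, 0.50, 0.25, 0.15, 0.065),
        mobile_fraction_by_day = c(0.87, 0.87, 0.80, 0.75, 0.74),
        t1_mobile = 0.3,
        t1_rigid = 30,
        order_parameter_by_day = c(0.85, 0.90, 0.88, 0.85, 0.80)
      )
    ),
    sites = data.frame(
      site = c(
        "Glc-C1", "GlcA-C1", "Gal-C1", "GlcNAc-C1",
        "PG-GlcNAc-C3", "PG-MurNAc-C2", "TasA-Ala-CA", "TasA-Gly-CA",
        "Lipid-CH2"
      ),
      phase = c(rep("mobile", 4), rep("rigid", 5)),
      t1 = c(2.0, 2.6, 1.6, 0.9, NA, NA, NA, NA, NA),
      order_parameter = c(NA, NA, NA, NA, 0.70, 0.62, 0.95, 0.85, 0.45),
      multiplicity = c(
        "CH", "CH", "CH", "CH",
        "CH", "CH", "CH", "CH2", "CH2"
      ),
      stringsAsFactors = FALSE
    ),
    sugars = list(
      Glc    = list(family = "Glc",
                    biofilm = c(6.0, 10.0, 8.0, 5.0, 4.0),
                    medium  = c(1.0, 1.5, 2.0, 2.5, 3.0)),
      GlcA   = list(family = "GlcA",
                    biofilm = c(0.5, 0.9, 1.2, 1.1, 1.0),
                    medium  = c(NA, 0.20, 0.25, 0.30, 0.35)),
      GlcN   = list(family = "GlcN",
                    biofilm = c(0.8, 1.0, 0.4, 0.05, 0.02),
                    medium  = c(NA, NA, NA, NA, NA)),
      GlcNAc = list(family = "cellwall",
                    biofilm = c(0.60, 0.80, 1.00, 0.90, 0.85),
                    medium  = c(0.50, 0.60, 0.70, 0.80, 0.90)),
      MurNAc = list(family = "cellwall",
                    biofilm = c(0.55, 0.75, 0.95, 0.88, 0.80),
                    medium  = c(0.45, 0.55, 0.66, 0.77, 0.85)),
      Gal    = list(family = "Gal",
                    biofilm = c(0.90, 1.00, 0.60, 0.30, 0.15),
                    medium  = c(1.5, 2.5, 3.0, 2.6, 2.2)),
      GalN   = list(family = "Gal",
                    biofilm = c(0.85, 1.00, 0.65, 0.28, 0.12),
                    medium  = c(1.4, 2.3, 2.9, 2.5, 2.1)),
      GalNAc = list(family = "Gal",
                    biofilm = c(0.80, 0.95, 0.70, 0.30, 0.14),
                    medium  = c(1.3, 2.2, 2.8, 2.45, 2.0))
    ),
    seed = 7L
  )
}

check_key <- function(ok, key, msg) {
  if (!isTRUE(ok)) stop_config(key, msg)
}

validate_component <- function(comp, name, n_days) {
  key <- function(f) sprintf("components.%s.%s", name, f)
  check_key(is.data.frame(comp$peaks) &&
              all(c("center", "width", "area") %in% names(comp$peaks)),
            key("peaks"), "must be a data frame with center/width/area")
  check_key(all(comp$peaks$width > 0), key("peaks.width"), "widths must be > 0")
  check_key(all(comp$peaks$area >= 0), key("peaks.area"), "areas must be >= 0")
  check_key(length(comp$biomass_by_day) == n_days &&
              all(comp$biomass_by_day >= 0),
            key("biomass_by_day"),
            sprintf("must be %d non-negative values", n_days))
  mf <- comp$mobile_fraction_by_day
  check_key(length(mf) == n_days && all(mf >= 0 & mf <= 1),
            key("mobile_fraction_by_day"),
            sprintf("must be %d values in [0, 1]", n_days))
  check_key(is_scalar_number(comp$t1_mobile) && comp$t1_mobile > 0,
            key("t1_mobile"), "must be a positive number (s)")
  check_key(is_scalar_number(comp$t1_rigid) && comp$t1_rigid > 0,
            key("t1_rigid"), "must be a positive number (s)")
  s <- comp$order_parameter_by_day
  check_key(length(s) == n_days && all(s >= 0 & s <= 1),
            key("order_parameter_by_day"),
            sprintf("must be %d values in [0, 1]", n_days))
  invisible(comp)
}

#' Build a fully populated synthetic scenario
#'
#' Validates a scenario configuration (see [scenario_preset()] for the
#' structure) and assembles the `scenario_spec` object all generator
#' functions consume, including the ground-truth record against which
#' pipeline estimates are later compared. Identical `(config, seed)` pairs
#' produce identical scenarios and, downstream, byte-identical datasets.
#'
#' @param config a configuration list; defaults to [scenario_preset()].
#' @param seed integer seed overriding `config$seed`.
#' @return an object of class `scenario_spec`.
#' @export
build_scenario <- function(config = scenario_preset(), seed = NULL) {
  if (!is.list(config)) stop_config("config", "must be a list")
  days <- config$days
  check_key(is.numeric(days) && length(days) >= 1 &&
              all(days == as.integer(days)) && all(diff(days) > 0),
            "days", "must be strictly increasing integers")
  n_days <- length(days)
  ax <- config$ppm_axis
  check_key(is.numeric(ax) && length(ax) == 3 && ax[[2]] > ax[[1]] &&
              ax[[3]] >= 2,
            "ppm_axis", "must be (min, max, n) with max > min and n >= 2")
  check_key(is_scalar_number(config$noise_sigma) && config$noise_sigma >= 0,
            "noise_sigma", "must be >= 0")
  mass <- config$sample_mass_per_day
  if (length(mass) == 1) mass <- rep(mass, n_days)
  check_key(length(mass) == n_days && all(mass > 0),
            "sample_mass_per_day", "all sample masses must be > 0")
  scans <- config$scans_per_mode
  check_key(all(c("qDP", "DP2s", "CP") %in% names(scans)) && all(scans >= 1),
            "scans_per_mode", "must name qDP/DP2s/CP with counts >= 1")
  check_key(is_scalar_number(config$mas_rate) && config$mas_rate > 0,
            "mas_rate", "must be a positive spinning rate (kHz)")
  check_key(is_scalar_number(config$cp_efficiency) && config$cp_efficiency > 0,
            "cp_efficiency", "must be > 0")
  check_key(is_scalar_number(config$delta_rigid) && config$delta_rigid > 0,
            "delta_rigid", "must be > 0 (kHz)")
  check_key(length(config$components) >= 1 &&
              !is.null(names(config$components)),
            "components", "must be a named list of component specs")
  for (nm in names(config$components)) {
    validate_component(config$components[[nm]], nm, n_days)
  }
  if (!is.null(config$sugars)) {
    for (nm in names(config$sugars)) {
      sg <- config$sugars[[nm]]
      key <- function(f) sprintf("sugars.%s.%s", nm, f)
      check_key(length(sg$biofilm) == n_days &&
                  all(is.na(sg$biofilm) | sg$biofilm >= 0),
                key("biofilm"), "integrals must be >= 0 or NA")
      check_key(length(sg$medium) == n_days &&
                  all(is.na(sg$medium) | sg$medium >= 0),
                key("medium"), "integrals must be >= 0 or NA")
    }
  }
  if (!is.null(seed)) config$seed <- seed
  check_key(is_scalar_number(config$seed), "seed", "must be a single integer")
  config$seed <- as.integer(config$seed)
  config$sample_mass_per_day <- stats::setNames(mass, days)

  scenario <- config
  scenario$ground_truth <- scenario_ground_truth(config, days)
  class(scenario) <- "scenario_spec"
  scenario
}

# Assemble the ground-truth record: every quantity the pipeline later
# estimates has its true value here.
scenario_ground_truth <- function(config, days) {
  comps <- config$components
  biomass <- sapply(comps, function(c) c$biomass_by_day)     # days x comps
  mf <- sapply(comps, function(c) c$mobile_fraction_by_day)
  if (is.null(dim(biomass))) {
    biomass <- matrix(biomass, nrow = length(days))
    mf <- matrix(mf, nrow = length(days))
    colnames(biomass) <- colnames(mf) <- names(comps)
  }
  total <- rowSums(biomass)
  mobile_total <- rowSums(biomass * mf) / total
  ref_idx <- if (2 %in% days) match(2, days) else which.max(total)
  gt <- list(
    days = days,
    reference_day = days[ref_idx],
    biomass = biomass,
    relative_biomass = sweep(biomass, 2, biomass[ref_idx, ], "/"),
    relative_total_biomass = total / total[ref_idx],
    mobile_fraction = mf,
    mobile_fraction_total = mobile_total
  )
  sites <- config$sites
  if (!is.null(sites)) {
    gt$t1 <- stats::setNames(sites$t1, sites$site)
    gt$order_parameter <- stats::setNames(sites$order_parameter, sites$site)
    gt$multiplicity <- stats::setNames(sites$multiplicity, sites$site)
  }
  if (!is.null(config$sugars)) {
    fam <- vapply(config$sugars, function(s) s$family, character(1))
    gt$sugar_family <- fam
    # sugars with any missing medium value over days 2..5 are not clusterable
    cl_days <- intersect(days, 2:5)
    clusterable <- vapply(config$sugars, function(s) {
      idx <- match(cl_days, days)
      !anyNA(s$medium[idx]) && !anyNA(s$biofilm[idx])
    }, logical(1))
    lab <- ifelse(clusterable, fam, NA_character_)
    gt$sugar_cluster <- stats::setNames(lab, names(config$sugars))
    gt$sugar_biofilm <- sapply(config$sugars, function(s) s$biofilm)
    gt$sugar_medium <- sapply(config$sugars, function(s) s$medium)
  }
  gt
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Synthetic biofilm scenario\n")
  cat("  days:       ", paste(x$days, collapse = ", "), "\n")
  cat("  components: ", paste(names(x$components), collapse = ", "), "\n")
  cat("  sugars:     ", length(x$sugars), "\n")
  cat("  sites:      ", nrow(x$sites) %||% 0L, "\n")
  cat("  ppm axis:   ", sprintf("%g..%g ppm, %d points", x$ppm_axis[[1]],
                                x$ppm_axis[[2]], x$ppm_axis[[3]]), "\n")
  cat("  noise sigma:", x$noise_sigma, "  seed:", x$seed, "\n")
  invisible(x)
}
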
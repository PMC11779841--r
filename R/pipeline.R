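#' Default run configuration
#'
#' A single structured configuration drives simulation and analysis: the
#' scenario (see [scenario_preset()]), the integration region set, the
#' reference days, the dynamics settings and the clustering settings.
#'
#' @param scenario scenario configuration list.
#' @param seed integer seed applied to the scenario and all stochastic
#'   stages.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(scenario = scenario_preset(), seed = NULL) {
  cfg <- list(
    scenario = scenario,
    regions = default_regions(),
    reference_day = 2,
    component_reference = list(category = "proteins", day = 2),
    kinetics = list(classes = c("protein", "carbohydrate"),
                    interval_days = c(3, 4)),
    dynamics = list(delta_rigid = scenario$delta_rigid %||% 22.7,
                    scaling = scenario$fslg_scaling %||% (1 / sqrt(3)),
                    mas_rate = scenario$mas_rate %||% 13.5,
                    powder_step = 5, ch2_step = 10),
    clustering = list(days = 2:5, k_range = 2:6, seed = 0, k = 4)
  )
  if (!is.null(seed)) {
    cfg$scenario$seed <- as.integer(seed)
    cfg$clustering$seed <- as.integer(seed)
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Fields present in the file override the defaults of [default_config()];
#' the scenario section is validated by [build_scenario()] when used.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      utils::modifyList(cfg[[nm]], raw[[nm]])
    } else {
      raw[[nm]]
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Generate and write a complete synthetic dataset
#'
#' Builds the scenario, renders every day/mode spectrum, emits the
#' inversion-recovery series, DIPSHIFT curves and sugar tables, and writes
#' everything (plus the ground truth as JSON and the resolved configuration
#' as YAML) under `dir`. A fixed `(config, seed)` pair reproduces every file
#' byte for byte.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param dir output directory; created (with a notice) if missing.
#' @param seed optional integer overriding the scenario seed.
#' @return invisibly, a list with the `scenario` and the written `files`.
#' @export
run_simulate <- function(config = default_config(), dir, seed = NULL) {
  scenario <- build_scenario(config$scenario, seed = seed)
  if (!dir.exists(dir)) {
    message("creating output directory ", dir)
    dir.create(dir, recursive = TRUE)
  }
  spec_dir <- file.path(dir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE)
  files <- character(0)
  for (day in scenario$days) {
    for (mode in c("qDP", "DP2s", "CP")) {
      sp <- render_spectrum(scenario, day, mode)
      p <- file.path(spec_dir, sprintf("day%d_%s.txt", day, mode))
      write_spectrum(sp, p, seed = scenario$seed)
      files <- c(files, p, paste0(p, ".json"))
    }
  }
  sites <- scenario$sites
  ir <- do.call(rbind, lapply(sites$site[!is.na(sites$t1)], function(s) {
    sr <- emit_inversion_recovery(scenario, s)
    data.frame(site = s, delay_s = sr$delays, intensity = sr$intensities)
  }))
  p <- file.path(dir, "inversion_recovery.csv")
  utils::write.csv(ir, p, row.names = FALSE)
  files <- c(files, p)
  dc <- do.call(rbind, lapply(
    sites$site[!is.na(sites$order_parameter)],
    function(s) {
      cv <- emit_dipshift(scenario, s)
      data.frame(site = s, multiplicity = cv$multiplicity,
                 t_frac = cv$t_frac, intensity = cv$intensity)
    }
  ))
  p <- file.path(dir, "dipshift.csv")
  utils::write.csv(dc, p, row.names = FALSE)
  files <- c(files, p)
  sug <- emit_sugar_tables(scenario)
  for (nm in c("biofilm", "medium")) {
    p <- file.path(dir, sprintf("sugars_%s.csv", nm))
    utils::write.csv(sug[[nm]], p, row.names = FALSE)
    files <- c(files, p)
  }
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(scenario$ground_truth, p, auto_unbox = TRUE,
                       digits = NA, na = "null", matrix = "columnmajor")
  files <- c(files, p)
  p <- file.path(dir, "config_resolved.yaml")
  yaml::write_yaml(scenario_to_yaml(scenario), p)
  files <- c(files, p)
  invisible(list(scenario = scenario, files = files))
}

scenario_to_yaml <- function(scenario) {
  s <- unclass(scenario)
  s$ground_truth <- NULL
  s$components <- lapply(s$components, function(c) {
    c$peaks <- as.list(as.data.frame(c$peaks))
    c
  })
  s$sites <- as.list(as.data.frame(s$sites))
  s
}

read_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_computation("stage '", stage, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Executes, in order, spectral quantification (total and per-class
#' densities, mobile fractions), degradation kinetics (degraded quantities
#' and the proportion solver), relaxation and DIPSHIFT fits, and sugar
#' clustering. Every figure-analog table is written as CSV under
#' `out_dir` (default: `<dir>/analysis`). Warnings from all stages are
#' collected into the report.
#'
#' @param dir dataset directory as written by [run_simulate()] (or
#'   user-supplied data in the same layout).
#' @param config a `run_config`.
#' @param out_dir where to write the result tables.
#' @param reference_ratio_table optional externally supplied biofilm/medium
#'   ratio table for [reference_pca_variance()].
#' @return object of class `run_report` with a `tables` list, `warnings`,
#'   and the output `files`.
#' @export
run_analyze <- function(dir, config = default_config(),
                        out_dir = file.path(dir, "analysis"),
                        reference_ratio_table = NULL) {
  if (!dir.exists(dir)) stop_input("dataset directory not found: ", dir)
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  spec_files <- list.files(file.path(dir, "spectra"), pattern = "\\.txt$",
                           full.names = TRUE)
  if (!length(spec_files)) stop_input("no spectra found under ", dir)
  spectra <- read_stage("spectral_quant", lapply(spec_files, read_spectrum))
  idx <- index_spectra(spectra)
  days <- sort(unique(idx$day))
  ref_day <- config$reference_day %||% 2

  tables <- list()
  # total biomass density + overall mobile fraction
  tot <- collect(read_stage("spectral_quant", {
    dens <- mf <- numeric(length(days))
    for (k in seq_along(days)) {
      qdp <- spectra[[idx$i[idx$day == days[k] & idx$mode == "qDP"][1]]]
      dp2s <- spectra[[idx$i[idx$day == days[k] & idx$mode == "DP2s"][1]]]
      dens[k] <- carbon_biomass_density(qdp)
      mf[k] <- mobile_fraction(dp2s, qdp)
    }
    data.frame(day = days, density = dens,
               relative_density = dens / dens[match(ref_day, days)],
               mobile_fraction = mf)
  }))
  tables$biomass_density <- tot
  # per-class densities and mobile fractions
  comp <- collect(read_stage("spectral_quant", {
    component_quant(spectra, regions = config$regions,
                    reference_day = ref_day)
  }))
  tables$component_series <- as.data.frame(comp)
  # degradation kinetics
  kin <- collect(read_stage("degradation_kinetics", {
    obs <- degradation_observations(
      comp, classes = config$kinetics$classes,
      interval_days = config$kinetics$interval_days
    )
    tables$degradation_observations <- obs
    if (anyNA(obs$degraded)) {
      warning("degradation intervals with accumulation; proportions skipped",
              call. = FALSE)
      NULL
    } else {
      cls <- config$kinetics$classes
      d1 <- config$kinetics$interval_days[1]
      d2 <- config$kinetics$interval_days[2]
      g <- function(cl, dd) obs$degraded[obs$class == cl &
                                           obs$interval_end == dd]
      solve_proportions(g(cls[1], d1), g(cls[1], d2),
                        g(cls[2], d1), g(cls[2], d2))
    }
  }))
  if (!is.null(kin)) {
    tables$degradation_proportions <- data.frame(
      p1 = kin$p1, p2 = kin$p2, c1 = kin$c1, c2 = kin$c2
    )
  }
  # relaxation
  ir_path <- file.path(dir, "inversion_recovery.csv")
  if (file.exists(ir_path)) {
    tables$t1_fits <- collect(read_stage("relaxation_dynamics", {
      ir <- utils::read.csv(ir_path)
      do.call(rbind, lapply(split(ir, ir$site), function(d) {
        f <- fit_t1(list(delays = d$delay_s, intensities = d$intensity,
                         site = d$site[1]))
        data.frame(site = d$site[1], t1_s = f$t1,
                   residual_norm = f$residual_norm)
      }))
    }))
  }
  # DIPSHIFT order parameters
  dc_path <- file.path(dir, "dipshift.csv")
  if (file.exists(dc_path)) {
    tables$order_parameters <- collect(read_stage("relaxation_dynamics", {
      dc <- utils::read.csv(dc_path)
      dyn <- config$dynamics
      do.call(rbind, lapply(split(dc, dc$site), function(d) {
        curve <- structure(
          list(t_frac = d$t_frac, intensity = d$intensity,
               multiplicity = d$multiplicity[1], mas_rate = dyn$mas_rate,
               scaling = dyn$scaling, site = d$site[1]),
          class = "dipshift_curve"
        )
        f <- fit_order_parameter(curve, delta_rigid = dyn$delta_rigid,
                                 scaling = dyn$scaling,
                                 powder_step = dyn$powder_step,
                                 ch2_step = dyn$ch2_step)
        data.frame(site = d$site[1], multiplicity = d$multiplicity[1],
                   delta_eff_khz = f$delta_eff,
                   order_parameter = f$order_parameter)
      }))
    }))
  }
  # sugar clustering
  bf_path <- file.path(dir, "sugars_biofilm.csv")
  md_path <- file.path(dir, "sugars_medium.csv")
  clust <- NULL
  if (file.exists(bf_path) && file.exists(md_path)) {
    clust <- collect(read_stage("sugar_clustering", {
      suppressMessages(cluster_sugars(
        utils::read.csv(bf_path), utils::read.csv(md_path),
        days = config$clustering$days, k_range = config$clustering$k_range,
        seed = config$clustering$seed, k = config$clustering$k
      ))
    }))
    tables$sugar_clusters <- data.frame(
      sugar = names(clust$labels),
      pc1 = clust$scores[, 1], pc2 = clust$scores[, 2],
      cluster = unname(clust$labels)
    )
    tables$pca_explained_variance <- data.frame(
      component = seq_along(clust$pca$explained_variance),
      explained_variance = clust$pca$explained_variance
    )
    tables$silhouettes <- data.frame(
      k = as.integer(names(clust$silhouettes)),
      silhouette = unname(clust$silhouettes)
    )
  }
  ref_pca <- reference_pca_variance(reference_ratio_table)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    files <- c(files, p)
  }
  input_files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  input_files <- setdiff(input_files,
                         list.files(out_dir, recursive = TRUE,
                                    full.names = TRUE))
  structure(
    list(
      tables = tables, clustering = clust, proportions = kin,
      reference_pca = ref_pca,
      warnings = warnings_seen, files = files,
      input_checksums = tools::md5sum(input_files),
      version = as.character(utils::packageVersion("biofilmNMR"))
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Biofilm NMR analysis report (biofilmNMR", x$version, ")\n")
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  if (!is.null(x$proportions)) {
    cat(sprintf("  degraded matrix: p1 %.0f%% / c1 %.0f%%, p2 %.0f%% / c2 %.0f%%\n",
                x$proportions$p1, x$proportions$c1,
                x$proportions$p2, x$proportions$c2))
  }
  if (isTRUE(x$reference_pca$available)) {
    cat(sprintf("  reference PCA variance (2 comp): %.1f%%\n",
                x$reference_pca$explained_variance_2))
  } else {
    cat("  reference PCA check: unavailable (",
        x$reference_pca$reason, ")\n", sep = "")
  }
  if (length(x$warnings)) {
    cat("  warnings (", length(x$warnings), "):\n", sep = "")
    for (w in unique(x$warnings)) cat("    - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' Simulate, analyze, and compare every estimate with the ground truth
#'
#' End-to-end recovery harness: generates a synthetic dataset, runs the full
#' analysis, and checks each pipeline estimate against the scenario's
#' ground-truth record within the documented tolerances.
#'
#' @param config a `run_config`.
#' @param dir working directory for the run (a temporary directory by
#'   default).
#' @param seed optional integer seed.
#' @param tolerances named list overriding the default check tolerances:
#'   `relative_biomass` (0.02), `mobile_fraction` (0.02), `t1_rel` (0.05),
#'   `order_parameter` (0.03), `ari` (exact 1 required).
#' @return data frame of class `recovery_suite`: one row per check with
#'   `check`, `truth`, `estimate`, `tolerance`, `pass`.
#' @export
run_recovery_suite <- function(config = default_config(),
                               dir = tempfile("biofilm-run-"), seed = NULL,
                               tolerances = list()) {
  tol <- utils::modifyList(
    list(relative_biomass = 0.02, mobile_fraction = 0.02, t1_rel = 0.05,
         order_parameter = 0.03, ari = 1),
    tolerances
  )
  sim <- run_simulate(config, dir, seed = seed)
  gt <- sim$scenario$ground_truth
  rep <- run_analyze(dir, config)
  rows <- list()
  add <- function(check, truth, estimate, tolerance, pass) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, truth = truth, estimate = estimate,
      tolerance = tolerance, pass = pass
    )
  }
  cs <- rep$tables$component_series
  for (cl in colnames(gt$relative_biomass)) {
    for (k in seq_along(gt$days)) {
      d <- gt$days[k]
      est <- cs$relative_density[cs$class == cl & cs$day == d]
      tru <- gt$relative_biomass[k, cl]
      add(sprintf("relative_biomass.%s.day%d", cl, d), tru, est,
          tol$relative_biomass, abs(est - tru) <= tol$relative_biomass)
      est_mf <- cs$mobile_fraction[cs$class == cl & cs$day == d]
      tru_mf <- gt$mobile_fraction[k, cl]
      add(sprintf("mobile_fraction.%s.day%d", cl, d), tru_mf, est_mf,
          tol$mobile_fraction, abs(est_mf - tru_mf) <= tol$mobile_fraction)
    }
  }
  t1s <- rep$tables$t1_fits
  for (s in t1s$site) {
    tru <- unname(gt$t1[s])
    est <- t1s$t1_s[t1s$site == s]
    add(sprintf("t1.%s", s), tru, est, tol$t1_rel,
        abs(est - tru) / tru <= tol$t1_rel)
  }
  ops <- rep$tables$order_parameters
  for (s in ops$site) {
    tru <- unname(gt$order_parameter[s])
    est <- ops$order_parameter[ops$site == s]
    add(sprintf("order_parameter.%s", s), tru, est, tol$order_parameter,
        abs(est - tru) <= tol$order_parameter)
  }
  if (!is.null(rep$clustering)) {
    truth_lab <- gt$sugar_cluster[names(rep$clustering$labels)]
    ari <- mclust::adjustedRandIndex(truth_lab, rep$clustering$labels)
    add("sugar_cluster.ari", 1, ari, tol$ari, ari >= tol$ari)
  }
  out <- do.call(rbind, rows)
  attr(out, "report") <- rep
  class(out) <- c("recovery_suite", "data.frame")
  out
}

#' @export
print.recovery_suite <- function(x, ...) {
  n <- nrow(x)
  np <- sum(x$pass)
  cat(sprintf("Recovery suite: %d/%d checks passed\n", np, n))
  if (np < n) {
    bad <- x[!x$pass, ]
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  FAIL %s: truth %.4g, estimate %.4g (tol %.3g)\n",
                  bad$check[i], bad$truth[i], bad$estimate[i],
                  bad$tolerance[i]))
    }
  }
  invisible(x)
}
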
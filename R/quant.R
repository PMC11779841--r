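#' Default ppm integration regions per component class
#'
#' Carbohydrates are quantified over 74--105 ppm; proteins over the combined,
#' lipid-free ranges 10--29, 34--48, 106--124 and 132--160 ppm. Intervals are
#' half-open `[low, high)` so adjacent regions never overlap.
#'
#' @return a named list of two-column matrices (`low`, `high`), one per class.
#' @export
default_regions <- function() {
  list(
    carbohydrate = cbind(low = 74, high = 105),
    protein = cbind(low = c(10, 34, 106, 132), high = c(29, 48, 124, 160))
  )
}

#' Trapezoidal integral of a spectrum over a ppm interval
#'
#' Integrates on the native grid after clipping to the interval, with
#' interpolated boundary points so integrals over adjacent intervals add
#' exactly. The result is independent of the storage direction of the ppm
#' axis.
#'
#' @param spectrum a [spectrum1d()].
#' @param interval length-2 numeric `(low, high)` in ppm.
#' @return the integral in intensity x ppm units.
#' @export
integrate_region <- function(spectrum, interval) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  if (length(interval) != 2) stop_input("interval must be (low, high)")
  lo <- min(interval)
  hi <- max(interval)
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  if (ppm[1] > ppm[length(ppm)]) {  # ascending working order
    ppm <- rev(ppm)
    y <- rev(y)
  }
  lo_c <- max(lo, ppm[1])
  hi_c <- min(hi, ppm[length(ppm)])
  if (lo_c >= hi_c) {
    stop_input(sprintf("interval [%g, %g] does not overlap the axis [%g, %g]",
                       lo, hi, ppm[1], ppm[length(ppm)]))
  }
  inside <- ppm > lo_c & ppm < hi_c
  xx <- c(lo_c, ppm[inside], hi_c)
  yy <- c(stats::approx(ppm, y, xout = lo_c)$y, y[inside],
          stats::approx(ppm, y, xout = hi_c)$y)
  sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

# Sum of integrals over the rows of a (low, high) interval matrix.
integrate_regions <- function(spectrum, intervals) {
  intervals <- rbind(intervals)
  sum(vapply(seq_len(nrow(intervals)), function(i) {
    integrate_region(spectrum, intervals[i, ])
  }, numeric(1)))
}

#' Calibrated carbon biomass density of a spectrum
#'
#' The spectral integral normalized by sample mass and number of scans,
#' `integral / (mass x NS)`. This calibrated quantity is proportional to the
#' carbon weight fraction of the sample and is the basis of all day-to-day
#' comparisons; quantitative claims require a qDP spectrum (a warning is
#' issued otherwise).
#'
#' @param spectrum a [spectrum1d()].
#' @param interval optional `(low, high)` ppm interval, or a matrix of
#'   intervals; the full axis when omitted.
#' @return density in integral units per mg per scan.
#' @export
carbon_biomass_density <- function(spectrum, interval = NULL) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  if (spectrum$mode != "qDP") {
    warning("carbon biomass density is quantitative only for qDP spectra (",
            spectrum$mode, " supplied)", call. = FALSE)
  }
  area <- if (is.null(interval)) {
    integrate_region(spectrum, range(spectrum$ppm))
  } else {
    integrate_regions(spectrum, interval)
  }
  area / (spectrum$sample_mass * spectrum$n_scans)
}

#' Mobile-phase fraction from a 2 s DP / quantitative DP spectrum pair
#'
#' Ratio of the calibrated densities of the short-recycle-delay (mobile
#' selective) and quantitative DP spectra over the same region(s). Values
#' pushed outside `[0, 1]` by noise are clamped with a warning.
#'
#' @param dp2s,qdp [spectrum1d()] objects from the same sample and day.
#' @param interval optional ppm interval or interval matrix.
#' @return mobile fraction in `[0, 1]`.
#' @export
mobile_fraction <- function(dp2s, qdp, interval = NULL) {
  stopifnot(inherits(dp2s, "spectrum1d"), inherits(qdp, "spectrum1d"))
  if (!is.na(dp2s$day) && !is.na(qdp$day) && !identical(dp2s$day, qdp$day)) {
    warning("DP2s and qDP spectra are from different days", call. = FALSE)
  }
  d_num <- suppressWarnings(carbon_biomass_density(dp2s, interval))
  d_den <- carbon_biomass_density(qdp, interval)
  if (d_den <= 0) {
    stop_computation("quantitative DP density is not positive (", d_den, ")")
  }
  f <- d_num / d_den
  if (f > 1 || f < 0) {
    warning(sprintf("mobile fraction %.4f outside [0, 1]; clamped", f),
            call. = FALSE)
    f <- min(max(f, 0), 1)
  }
  f
}

index_spectra <- function(spectra) {
  days <- vapply(spectra, function(s) as.numeric(s$day), numeric(1))
  modes <- vapply(spectra, `[[`, character(1), "mode")
  data.frame(i = seq_along(spectra), day = days, mode = modes,
             stringsAsFactors = FALSE)
}

#' Per-class biomass density and mobile-fraction time series
#'
#' For every requested component class, integrates its region set in each
#' day's quantitative DP spectrum (density, then normalized to the reference
#' day) and forms the mobile fraction from the paired 2 s DP spectrum.
#'
#' @param spectra list of [spectrum1d()] covering every day in `qDP` and
#'   `DP2s` mode.
#' @param regions named list of interval matrices, as [default_regions()].
#' @param classes classes to quantify; defaults to `names(regions)`.
#' @param reference_day day whose density is set to 1.0 (default 2).
#' @return a `biomass_series` data frame with columns `class`, `day`,
#'   `density`, `relative_density`, `mobile_fraction`.
#' @export
component_quant <- function(spectra, regions = default_regions(),
                            classes = names(regions), reference_day = 2) {
  idx <- index_spectra(spectra)
  days <- sort(unique(idx$day))
  missing <- character(0)
  for (d in days) {
    for (m in c("qDP", "DP2s")) {
      if (!any(idx$day == d & idx$mode == m)) {
        missing <- c(missing, sprintf("day %g / %s", d, m))
      }
    }
  }
  if (length(missing)) {
    stop_input("missing day/mode spectra: ", paste(missing, collapse = "; "))
  }
  if (!reference_day %in% days) {
    stop_input("reference day ", reference_day, " has no spectra")
  }
  out <- list()
  for (cl in classes) {
    iv <- regions[[cl]]
    if (is.null(iv) || nrow(rbind(iv)) == 0) {
      stop_input("class '", cl, "' has an empty region list")
    }
    dens <- mf <- numeric(length(days))
    for (k in seq_along(days)) {
      d <- days[k]
      qdp <- spectra[[idx$i[idx$day == d & idx$mode == "qDP"][1]]]
      dp2s <- spectra[[idx$i[idx$day == d & idx$mode == "DP2s"][1]]]
      dens[k] <- carbon_biomass_density(qdp, iv)
      mf[k] <- mobile_fraction(dp2s, qdp, iv)
    }
    out[[cl]] <- data.frame(
      class = cl, day = days, density = dens,
      relative_density = dens / dens[match(reference_day, days)],
      mobile_fraction = mf, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "reference_day") <- reference_day
  class(res) <- c("biomass_series", "data.frame")
  res
}

#' Track a single peak's intensity across days
#'
#' Monitors one resolved resonance (by default the 65.2 ppm glycerol signal
#' used to follow carbon-source consumption in the medium) across a spectrum
#' series, reporting per-day values normalized to the day with the maximum.
#' Peak height within the window is the default statistic; the windowed
#' integral is available as an alternative.
#'
#' @param spectra list of [spectrum1d()] (one per day).
#' @param center peak position in ppm; glycerol reference positions are
#'   65.187 and 72.775 ppm.
#' @param window half-width of the search window in ppm (> 0).
#' @param stat `"height"` (default) or `"integral"`.
#' @return data frame with `day`, `value`, `normalized`.
#' @export
track_peak_intensity <- function(spectra, center = 65.187, window = 0.5,
                                 stat = c("height", "integral")) {
  stat <- match.arg(stat)
  if (!is_scalar_number(window) || window <= 0) {
    stop_input("window must be > 0")
  }
  days <- vapply(spectra, function(s) as.numeric(s$day), numeric(1))
  vals <- vapply(spectra, function(s) {
    sel <- s$ppm >= center - window & s$ppm <= center + window
    if (!any(sel)) {
      stop_input(sprintf("window %g +/- %g ppm is outside the axis",
                         center, window))
    }
    if (stat == "height") {
      max(s$intensity[sel])
    } else {
      integrate_region(s, c(center - window, center + window))
    }
  }, numeric(1))
  ord <- order(days)
  data.frame(day = days[ord], value = vals[ord],
             normalized = vals[ord] / max(vals))
}

#' The seven mobile-phase component categories
#' @return character vector of category names.
#' @export
component_categories <- function() {
  c("bacteria-related", "exopolysaccharides", "proteins", "nucleotides",
    "N-acetyl", "lipids/biosurfactants", "unknown")
}

#' Group 2D peak volumes into component categories
#'
#' Aggregates per-peak volumes from 2D mobile-phase spectra into the seven
#' source categories, reporting per-day relative proportions (summing to
#' 100 percent) and absolute quantities normalized so a reference
#' category/day pair (proteins on day 2 by default) equals 100.
#'
#' @param volumes data frame with columns `peak`, `day`, `volume`.
#' @param category_map named character vector mapping peak identifiers to
#'   categories; unmapped peaks fall into `"unknown"`.
#' @param reference list with `category` and `day` anchoring the absolute
#'   scale; `reference_value` is the value assigned there.
#' @param reference_value numeric anchor, default 100.
#' @return a `component_table` data frame with `category`, `day`,
#'   `quantity` (normalized absolute) and `proportion` (percent).
#' @export
group_components <- function(volumes, category_map = NULL,
                             reference = list(category = "proteins", day = 2),
                             reference_value = 100) {
  need <- c("peak", "day", "volume")
  if (!all(need %in% names(volumes))) {
    stop_input("volumes must have columns peak, day, volume")
  }
  if (anyDuplicated(volumes[c("peak", "day")])) {
    dup <- volumes$peak[duplicated(volumes[c("peak", "day")])]
    stop_input("duplicated peak identifiers: ",
               paste(unique(dup), collapse = ", "))
  }
  cats <- component_categories()
  category <- if (is.null(category_map)) {
    rep("unknown", nrow(volumes))
  } else {
    mapped <- unname(category_map[volumes$peak])
    mapped[is.na(mapped)] <- "unknown"
    mapped
  }
  bad <- setdiff(unique(category), cats)
  if (length(bad)) {
    stop_input("unknown categories in map: ", paste(bad, collapse = ", "))
  }
  agg <- stats::aggregate(volume ~ category + day,
                          data = cbind(volumes, category = category), sum)
  totals <- stats::aggregate(volume ~ day, data = agg, sum)
  agg$proportion <- 100 * agg$volume /
    totals$volume[match(agg$day, totals$day)]
  ref_row <- agg$category == reference$category & agg$day == reference$day
  if (!any(ref_row)) {
    stop_input(sprintf("reference %s / day %s absent from the table",
                       reference$category, format(reference$day)))
  }
  agg$quantity <- reference_value * agg$volume / agg$volume[ref_row][1]
  res <- agg[order(agg$day, match(agg$category, cats)),
             c("category", "day", "quantity", "proportion")]
  rownames(res) <- NULL
  attr(res, "reference") <- reference
  class(res) <- c("component_table", "data.frame")
  res
}
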
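#' Construct a 1D frequency-domain spectrum
#'
#' A `spectrum1d` couples a monotone ppm axis with per-point intensities and
#' the acquisition metadata needed for calibrated quantification: sample mass
#' (mg), number of scans, polarization mode and sampling day. The ppm axis is
#' stored as given (generator output is descending, the NMR display
#' convention); all integration is direction-agnostic.
#'
#' @param ppm numeric, strictly monotone chemical-shift axis (ppm).
#' @param intensity numeric, same length as `ppm`.
#' @param sample_mass positive sample mass in mg.
#' @param n_scans number of scans, >= 1.
#' @param mode one of `"qDP"` (quantitative direct polarization, long recycle
#'   delay), `"DP2s"` (mobile-selective short recycle delay) or `"CP"`
#'   (cross polarization, rigid-selective and non-quantitative).
#' @param day acquisition day label.
#' @param non_quantitative logical flag; forced `TRUE` for CP.
#' @return an object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, sample_mass, n_scans,
                       mode = c("qDP", "DP2s", "CP"), day = NA,
                       non_quantitative = NULL) {
  mode <- match.arg(mode)
  if (length(ppm) != length(intensity)) {
    stop_input("ppm and intensity must have the same length")
  }
  if (length(ppm) < 2) stop_input("spectrum needs at least 2 points")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    stop_input("ppm axis must be strictly monotone")
  }
  if (!is_scalar_number(sample_mass) || sample_mass <= 0) {
    stop_input("sample_mass must be a positive number (mg)")
  }
  if (!is_scalar_number(n_scans) || n_scans < 1) {
    stop_input("n_scans must be >= 1")
  }
  structure(
    list(
      ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      sample_mass = sample_mass, n_scans = n_scans, mode = mode, day = day,
      non_quantitative = isTRUE(non_quantitative) || mode == "CP"
    ),
    class = "spectrum1d"
  )
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf(
    "1D 13C spectrum (%s%s), day %s: %d points, %g..%g ppm, %g mg, %d scans\n",
    x$mode, if (x$non_quantitative) ", non-quantitative" else "",
    format(x$day), length(x$ppm), min(x$ppm), max(x$ppm),
    x$sample_mass, as.integer(x$n_scans)
  ))
  invisible(x)
}

#' @export
plot.spectrum1d <- function(x, ...) {
  graphics::plot(x$ppm, x$intensity, type = "l", xlim = rev(range(x$ppm)),
                 xlab = "13C chemical shift (ppm)", ylab = "intensity", ...)
  invisible(x)
}

#' Write / read a spectrum as two-column text with a JSON sidecar
#'
#' The spectrum body is plain two-column text (ppm, intensity); acquisition
#' metadata (`sample_mass_mg`, `n_scans`, `mode`, `day`, `seed`,
#' `non_quantitative`) goes to `<path>.json`.
#'
#' @param x a `spectrum1d`.
#' @param path output path for the two-column body.
#' @param seed optional generator seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "spectrum1d"))
  utils::write.table(
    data.frame(ppm = x$ppm, intensity = x$intensity),
    path, row.names = FALSE, col.names = FALSE, sep = " "
  )
  meta <- list(
    sample_mass_mg = x$sample_mass, n_scans = as.integer(x$n_scans),
    mode = x$mode, day = x$day, non_quantitative = x$non_quantitative
  )
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  body <- utils::read.table(path, header = FALSE,
                            col.names = c("ppm", "intensity"))
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    stop_input("metadata sidecar not found: ", side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  spectrum1d(body$ppm, body$intensity,
             sample_mass = meta$sample_mass_mg, n_scans = meta$n_scans,
             mode = meta$mode, day = meta$day,
             non_quantitative = isTRUE(meta$non_quantitative))
}
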
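#' Fit an inversion-recovery series to the three-parameter recovery model
#'
#' Least-squares fit of `I(t) = A + B exp(-t / T1)` with `B < 0`, the
#' three-parameter form robust to imperfect inversion. Starting values come
#' from the plateau level, the initial intensity and the zero-crossing time
#' (`t0 ~ T1 ln 2` for ideal inversion).
#'
#' @param series an `inversion_recovery` from [emit_inversion_recovery()],
#'   or a data frame / list with `delays` and `intensities` (delay, intensity
#'   columns also accepted).
#' @return object of class `t1_fit` with components `t1` (s), `A`, `B`,
#'   `residual_norm`, `converged`, plus the data.
#' @export
fit_t1 <- function(series) {
  if (is.data.frame(series)) {
    delays <- series$delay %||% series$delays
    intensities <- series$intensity %||% series$intensities
  } else {
    delays <- series$delays
    intensities <- series$intensities
  }
  if (is.null(delays) || is.null(intensities)) {
    stop_input("series must provide delays and intensities")
  }
  if (length(unique(delays)) < 4) {
    stop_input("inversion-recovery series needs >= 4 distinct delays")
  }
  if (any(delays < 0)) stop_input("delays must be >= 0")
  rng <- diff(range(intensities))
  if (rng == 0) stop_fit("constant intensity series cannot be fitted")

  a0 <- max(intensities)
  b0 <- min(intensities) - a0
  cross <- which(diff(sign(intensities)) != 0)
  t1_0 <- if (length(cross)) {
    max(delays[cross[1]], 1e-3) / log(2)
  } else {
    max(diff(range(delays)) / 3, 1e-3)
  }
  dat <- data.frame(t = delays, I = intensities)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ A + B * exp(-t / T1), data = dat,
      start = list(A = a0, B = b0, T1 = t1_0),
      lower = c(A = -Inf, B = -Inf, T1 = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop_fit("T1 fit failed: ", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  if (!is.finite(cf[["T1"]]) || cf[["T1"]] <= 1e-6) {
    stop_fit("T1 fit hit its lower bound; data do not determine a recovery time")
  }
  res <- stats::resid(fit)
  structure(
    list(
      t1 = unname(cf[["T1"]]), A = unname(cf[["A"]]), B = unname(cf[["B"]]),
      residual_norm = sqrt(sum(res^2)),
      converged = fit$convInfo$isConv %||% TRUE,
      delays = delays, intensities = intensities,
      site = series$site %||% NA_character_
    ),
    class = "t1_fit"
  )
}

#' @export
print.t1_fit <- function(x, ...) {
  cat(sprintf("Inversion-recovery fit%s: T1 = %.5g s (A = %.4g, B = %.4g)\n",
              if (is.na(x$site)) "" else paste0(" [", x$site, "]"),
              x$t1, x$A, x$B))
  cat(sprintf("  residual norm %.3g, %d delays, converged: %s\n",
              x$residual_norm, length(x$delays), x$converged))
  invisible(x)
}

#' @export
coef.t1_fit <- function(object, ...) {
  c(A = object$A, B = object$B, T1 = object$t1)
}

#' @export
predict.t1_fit <- function(object, delays = object$delays, ...) {
  object$A + object$B * exp(-delays / object$t1)
}

#' @export
residuals.t1_fit <- function(object, ...) {
  object$intensities - predict(object)
}

#' @export
fitted.t1_fit <- function(object, ...) predict(object)

#' @export
plot.t1_fit <- function(x, ...) {
  graphics::plot(x$delays, x$intensities, xlab = "recovery delay (s)",
                 ylab = "intensity", ...)
  tt <- seq(0, max(x$delays), length.out = 200)
  graphics::lines(tt, x$A + x$B * exp(-tt / x$t1))
  invisible(x)
}
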
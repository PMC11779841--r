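# DIPSHIFT dephasing model.
#
# Under magic-angle spinning the heteronuclear dipolar frequency of a C-H
# vector with polar angles (beta, gamma) in the rotor frame is
#
#   omega(t) = 2 pi d [ sqrt(2)/2 sin(2 beta) cos(w_r t + gamma)
#                       - 1/2 sin^2(beta) cos(2 w_r t + 2 gamma) ]
#
# with d the (FSLG-scaled) coupling and w_r the spinning frequency. The
# accumulated phase over the dipolar evolution time t1 integrates to
#
#   Phi(t1) = (d / nu_r) * g(beta, gamma, f),   f = t1 / tau_r in [0, 1],
#
# with the dimensionless geometry factor g below; Phi is exactly zero at
# f = 0 and f = 1 for every orientation (rotor-echo refocusing). The signal
# is the powder average of cos(Phi) (CH) or of the product of the two C-H
# cosine terms with tetrahedral inter-vector geometry (CH2, cross terms
# neglected). Because Phi is linear in the coupling, the geometry factors
# are precomputed once per curve and reused across couplings during fits.

dipshift_geometry_factor <- function(beta, gamma, f) {
  # outer over orientations (beta, gamma vectors) x time fractions f
  s2b <- sin(2 * beta)
  sb2 <- sin(beta)^2
  term1 <- outer(s2b, rep(1, length(f))) *
    (sin(outer(gamma, 2 * pi * f, `+`)) - sin(gamma))
  term2 <- outer(sb2, rep(1, length(f))) *
    (sin(outer(2 * gamma, 4 * pi * f, `+`)) - sin(2 * gamma))
  sqrt(2) / 2 * term1 - term2 / 4
}

# Powder grids. CH averages over the (beta, gamma) polar angles of the single
# C-H vector; CH2 needs the full crystallite orientation (alpha, beta, gamma_m)
# because the second vector is tied to the first at the tetrahedral angle.
dipshift_geometry <- function(t_frac, multiplicity = c("CH", "CH2"),
                              powder_step = 5, ch2_step = 10) {
  multiplicity <- match.arg(multiplicity)
  if (multiplicity == "CH") {
    step <- powder_step * pi / 180
    beta <- seq(step / 2, pi - step / 2, by = step)
    gamma <- seq(0, 2 * pi - step, by = step)
    grid <- expand.grid(beta = beta, gamma = gamma)
    list(
      G1 = dipshift_geometry_factor(grid$beta, grid$gamma, t_frac),
      G2 = NULL,
      w = sin(grid$beta)
    )
  } else {
    step <- max(powder_step, ch2_step) * pi / 180
    alpha <- seq(0, 2 * pi - step, by = step)
    beta <- seq(step / 2, pi - step / 2, by = step)
    gm <- seq(0, 2 * pi - step, by = step)
    grid <- expand.grid(alpha = alpha, beta = beta, gm = gm)
    theta <- 109.47 * pi / 180
    # first C-H vector along the crystallite z axis
    b1 <- grid$beta
    g1 <- grid$alpha
    # second vector: Rz(alpha) Ry(beta) Rz(gm) applied to (sin theta, 0, cos theta)
    x0 <- sin(theta) * cos(grid$gm)
    y0 <- sin(theta) * sin(grid$gm)
    z0 <- cos(theta)
    x1 <- cos(grid$beta) * x0 + sin(grid$beta) * z0
    z1 <- -sin(grid$beta) * x0 + cos(grid$beta) * z0
    b2 <- acos(pmin(pmax(z1, -1), 1))
    g2 <- atan2(y0, x1) + grid$alpha
    list(
      G1 = dipshift_geometry_factor(b1, g1, t_frac),
      G2 = dipshift_geometry_factor(b2, g2, t_frac),
      w = sin(grid$beta)
    )
  }
}

dipshift_intensity <- function(geom, delta_applied, mas_rate) {
  x <- delta_applied / mas_rate
  if (x == 0) return(rep(1, ncol(geom$G1)))
  if (is.null(geom$G2)) {
    as.numeric(crossprod(geom$w, cos(x * geom$G1))) / sum(geom$w)
  } else {
    as.numeric(crossprod(geom$w, cos(x * geom$G1) * cos(x * geom$G2))) /
      sum(geom$w)
  }
}

#' Simulate a DIPSHIFT dipolar dephasing curve
#'
#' Powder-averaged dephasing of a CH or CH2 group over one rotor period of
#' magic-angle spinning under FSLG homonuclear decoupling. The applied
#' coupling is `scaling x delta_eff`; the reported curve is
#' `<cos Phi(t1)>` for CH and the powder average of the product of the two
#' C-H dephasing terms (tetrahedral inter-vector angle, cross-correlation
#' neglected) for CH2. Every curve equals 1 at `t1 = 0` and refocuses to 1
#' at one full rotor period.
#'
#' @param delta_eff effective C-H dipolar coupling in kHz (>= 0).
#' @param multiplicity `"CH"` or `"CH2"`.
#' @param mas_rate spinning rate in kHz (> 0).
#' @param scaling homonuclear-decoupling scaling factor; the FSLG
#'   theoretical value `1/sqrt(3)` by default.
#' @param n_t1 number of evolution points across one rotor period (>= 2).
#' @param powder_step powder grid step in degrees (CH; also the base step
#'   for CH2, which uses at least `ch2_step`).
#' @param ch2_step minimum grid step in degrees for the three-angle CH2
#'   average.
#' @param t_frac optional explicit evolution-time grid as fractions of the
#'   rotor period in `[0, 1]`; overrides `n_t1`.
#' @return object of class `dipshift_curve`: `t_frac`, `intensity`,
#'   `multiplicity`, `mas_rate`, `scaling`, `delta_eff`.
#' @export
simulate_dipshift <- function(delta_eff, multiplicity = c("CH", "CH2"),
                              mas_rate = 13.5, scaling = 1 / sqrt(3),
                              n_t1 = 16, powder_step = 5, ch2_step = 10,
                              t_frac = NULL) {
  multiplicity <- match.arg(multiplicity)
  if (!is_scalar_number(delta_eff) || delta_eff < 0) {
    stop_input("delta_eff must be >= 0 (kHz)")
  }
  if (!is_scalar_number(mas_rate) || mas_rate <= 0) {
    stop_input("mas_rate must be > 0 (kHz)")
  }
  if (is.null(t_frac)) {
    if (!is_scalar_number(n_t1) || n_t1 < 2) {
      stop_input("n_t1 must be >= 2")
    }
    t_frac <- seq(0, 1, length.out = n_t1)
  }
  geom <- dipshift_geometry(t_frac, multiplicity, powder_step, ch2_step)
  structure(
    list(
      t_frac = t_frac,
      intensity = dipshift_intensity(geom, scaling * delta_eff, mas_rate),
      multiplicity = multiplicity, mas_rate = mas_rate, scaling = scaling,
      delta_eff = delta_eff, powder_step = powder_step, ch2_step = ch2_step
    ),
    class = "dipshift_curve"
  )
}

#' @export
print.dipshift_curve <- function(x, ...) {
  cat(sprintf(
    "DIPSHIFT dephasing curve (%s, %g kHz MAS, scaling %.3f): %d points, min %.3f\n",
    x$multiplicity, x$mas_rate, x$scaling, length(x$t_frac),
    min(x$intensity)
  ))
  invisible(x)
}

#' @export
plot.dipshift_curve <- function(x, ...) {
  graphics::plot(x$t_frac, x$intensity, type = "b",
                 xlab = "t1 / rotor period", ylab = "normalized intensity",
                 ylim = c(min(0, min(x$intensity)), 1), ...)
  invisible(x)
}

#' Fit the effective coupling and order parameter of a dephasing curve
#'
#' One-dimensional least squares over the effective coupling, evaluating the
#' same powder-averaged model as [simulate_dipshift()] (geometry factors are
#' precomputed once, so the search is cheap). The search interval is
#' `[0, 1.2 x delta_rigid]`; an optimum essentially at the upper bound is a
#' fit error rather than a silently clamped value. The order parameter is
#' `S = delta_eff / delta_rigid`, clamped to `[0, 1]` with a warning when
#' noise pushes it above 1.
#'
#' @param curve a `dipshift_curve` (possibly noisy; e.g. [emit_dipshift()]).
#' @param delta_rigid rigid-limit one-bond C-H coupling in kHz; the default
#'   22.7 kHz corresponds to a 1.1 angstrom bond.
#' @param scaling homonuclear-decoupling scaling factor used in acquisition.
#' @param powder_step,ch2_step powder grid steps (degrees) for the model.
#' @param residual_threshold root-mean-square residual above which a
#'   poor-fit warning is issued.
#' @return object of class `order_parameter_fit`: `delta_eff` (kHz),
#'   `order_parameter`, `delta_rigid`, `scaling`, `residual_norm`.
#' @export
fit_order_parameter <- function(curve, delta_rigid = 22.7,
                                scaling = curve$scaling,
                                powder_step = 5, ch2_step = 10,
                                residual_threshold = 0.05) {
  stopifnot(inherits(curve, "dipshift_curve"))
  if (!is_scalar_number(delta_rigid) || delta_rigid <= 0) {
    stop_input("delta_rigid must be > 0 (kHz)")
  }
  geom <- dipshift_geometry(curve$t_frac, curve$multiplicity,
                            powder_step, ch2_step)
  y <- curve$intensity
  obj <- function(delta) {
    sum((dipshift_intensity(geom, scaling * delta, curve$mas_rate) - y)^2)
  }
  upper <- 1.2 * delta_rigid
  opt <- stats::optimize(obj, interval = c(0, upper), tol = 1e-4)
  delta_hat <- opt$minimum
  if (delta_hat > upper - 1e-2) {
    stop_fit(sprintf(
      "effective coupling ran into the search bound (%.2f kHz >= 1.2 x delta_rigid); %s",
      delta_hat, "check delta_rigid, the scaling factor, or the data"
    ))
  }
  s <- delta_hat / delta_rigid
  if (s > 1) {
    warning(sprintf("order parameter %.3f > 1 clamped to 1", s),
            call. = FALSE)
    s <- 1
  }
  rms <- sqrt(opt$objective / length(y))
  if (rms > residual_threshold) {
    warning(sprintf("poor DIPSHIFT fit: rms residual %.3g above %.3g",
                    rms, residual_threshold), call. = FALSE)
  }
  structure(
    list(
      delta_eff = delta_hat, order_parameter = s, delta_rigid = delta_rigid,
      scaling = scaling, residual_norm = sqrt(opt$objective),
      site = curve$site %||% NA_character_,
      multiplicity = curve$multiplicity, curve = curve
    ),
    class = "order_parameter_fit"
  )
}

#' @export
print.order_parameter_fit <- function(x, ...) {
  cat(sprintf(
    "DIPSHIFT fit%s (%s): delta_eff = %.2f kHz, S = %.3f (rigid limit %.1f kHz)\n",
    if (is.na(x$site)) "" else paste0(" [", x$site, "]"),
    x$multiplicity, x$delta_eff, x$order_parameter, x$delta_rigid
  ))
  invisible(x)
}

#' @export
coef.order_parameter_fit <- function(object, ...) {
  c(delta_eff = object$delta_eff, S = object$order_parameter)
}
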
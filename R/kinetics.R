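#' First-order degradation model
#'
#' Container for a first-order substrate degradation process
#' `d[S]/dt = -k [S]`: initial concentration `C0`, rate constant `k`
#' (per day) and compartment volume `V`.
#'
#' @param C0 initial substrate concentration (>= 0, arbitrary units).
#' @param k rate constant (>= 0, per day).
#' @param V volume (> 0, arbitrary units).
#' @return object of class `first_order_model`.
#' @export
first_order_model <- function(C0, k, V = 1) {
  if (!is_scalar_number(C0) || C0 < 0) stop_input("C0 must be >= 0")
  if (!is_scalar_number(k) || k < 0) stop_input("k must be >= 0")
  if (!is_scalar_number(V) || V <= 0) stop_input("V must be > 0")
  structure(list(C0 = C0, k = k, V = V), class = "first_order_model")
}

#' @export
print.first_order_model <- function(x, ...) {
  cat(sprintf("First-order degradation model: C0 = %g, k = %g / d, V = %g\n",
              x$C0, x$k, x$V))
  invisible(x)
}

#' Substrate concentration at time t
#'
#' `[S](t) = C0 exp(-k t)`.
#'
#' @param model a [first_order_model()].
#' @param t time in days (>= 0); vectorized.
#' @return concentration(s).
#' @export
substrate_concentration <- function(model, t) {
  stopifnot(inherits(model, "first_order_model"))
  if (any(t < 0)) stop_input("t must be >= 0")
  model$C0 * exp(-model$k * t)
}

#' Time-averaged substrate concentration over [0, t]
#'
#' Closed form `C0 (1 - exp(-k t)) / (k t)`, with the series expansion
#' `C0 (1 - kt/2 + (kt)^2/6)` substituted when `k t < 1e-8` to avoid
#' catastrophic cancellation.
#'
#' @param model a [first_order_model()].
#' @param t averaging horizon in days (> 0); vectorized.
#' @return average concentration(s).
#' @export
average_concentration <- function(model, t) {
  stopifnot(inherits(model, "first_order_model"))
  if (any(t <= 0)) stop_input("t must be > 0")
  kt <- model$k * t
  out <- numeric(length(kt))
  small <- kt < 1e-8
  out[small] <- model$C0 * (1 - kt[small] / 2 + kt[small]^2 / 6)
  out[!small] <- model$C0 * (-expm1(-kt[!small])) / kt[!small]
  out
}

#' Degraded substrate quantity after time t
#'
#' `D(t) = C0 (1 - exp(-k t)) V`, identically equal to
#' `<[S]> k t V` with the average concentration of
#' [average_concentration()].
#'
#' @param model a [first_order_model()].
#' @param t time in days (>= 0); vectorized.
#' @return degraded quantity(ies).
#' @export
degraded_quantity <- function(model, t) {
  stopifnot(inherits(model, "first_order_model"))
  if (any(t < 0)) stop_input("t must be >= 0")
  model$C0 * (-expm1(-model$k * t)) * model$V
}

#' Composition of the degraded matrix from consecutive degraded quantities
#'
#' Under first-order kinetics the quantity degraded in an interval is
#' proportional to the local substrate concentration, so with equal volume
#' and total biomass in both intervals the protein/carbohydrate percentages
#' `p1 + c1 = 100`, `p2 + c2 = 100` satisfy `p1/p2 = Dp1/Dp2` and
#' `c1/c2 = Dc1/Dc2`. Writing `rp = Dp1/Dp2`, `rc = Dc1/Dc2` the solution is
#' `p2 = 100 (1 - rc) / (rp - rc)`, `p1 = rp p2`, `c_i = 100 - p_i`.
#'
#' The solver is scale-invariant separately in the protein and carbohydrate
#' pairs; a degenerate system (`rp == rc`) and solutions outside `[0, 100]`
#' (which violate the equal-volume/equal-biomass assumption) raise errors
#' rather than being clamped.
#'
#' @param Dp1,Dp2 degraded protein quantities in the two intervals (> 0).
#' @param Dc1,Dc2 degraded carbohydrate quantities in the two intervals (> 0).
#' @return object of class `proportion_solution` with fields `p1`, `p2`,
#'   `c1`, `c2` (percent) and the input ratios.
#' @examples
#' solve_proportions(49.28, 31.31, 14.18, 33.43)
#' @export
solve_proportions <- function(Dp1, Dp2, Dc1, Dc2) {
  vals <- c(Dp1 = Dp1, Dp2 = Dp2, Dc1 = Dc1, Dc2 = Dc2)
  if (!all(vapply(vals, is_scalar_number, logical(1))) || any(vals <= 0)) {
    stop_input("all degraded quantities must be positive numbers")
  }
  rp <- Dp1 / Dp2
  rc <- Dc1 / Dc2
  if (abs(rp - rc) <= 1e-12 * max(abs(rp), abs(rc))) {
    stop_computation(
      "degenerate system: protein and carbohydrate ratios coincide (",
      format(rp), "); the proportions are not identifiable"
    )
  }
  p2 <- 100 * (1 - rc) / (rp - rc)
  p1 <- rp * p2
  c1 <- 100 - p1
  c2 <- 100 - p2
  sol <- c(p1 = p1, p2 = p2, c1 = c1, c2 = c2)
  if (any(sol < 0 | sol > 100)) {
    stop_computation(
      "inconsistent solution outside [0, 100]: ",
      paste(sprintf("%s = %.3f", names(sol), sol), collapse = ", "),
      "; the equal-volume/equal-biomass assumption does not hold for these inputs"
    )
  }
  structure(
    list(p1 = p1, p2 = p2, c1 = c1, c2 = c2, rp = rp, rc = rc,
         inputs = vals),
    class = "proportion_solution"
  )
}

#' @export
print.proportion_solution <- function(x, digits = 1, ...) {
  cat("Degraded-matrix composition (first-order kinetics)\n")
  cat(sprintf("  interval 1: proteins %.*f%%, carbohydrates %.*f%%\n",
              digits, x$p1, digits, x$c1))
  cat(sprintf("  interval 2: proteins %.*f%%, carbohydrates %.*f%%\n",
              digits, x$p2, digits, x$c2))
  cat(sprintf("  input ratios: protein %.4f, carbohydrate %.4f\n",
              x$rp, x$rc))
  invisible(x)
}

#' @export
coef.proportion_solution <- function(object, ...) {
  c(p1 = object$p1, p2 = object$p2, c1 = object$c1, c2 = object$c2)
}

#' Day-over-day degraded quantities from a biomass series
#'
#' Computes, for each requested interval end day, the decrease in a class's
#' relative biomass density from the previous sampled day; these are the
#' degraded quantities fed to [solve_proportions()]. Non-positive decreases
#' (net accumulation) are reported as `NA` with a warning.
#'
#' @param series a `biomass_series` from [component_quant()].
#' @param classes two class labels, proteins first.
#' @param interval_days end days of the intervals (default 3 and 4).
#' @return data frame with `class`, `interval_end`, `degraded`.
#' @export
degradation_observations <- function(series,
                                     classes = c("protein", "carbohydrate"),
                                     interval_days = c(3, 4)) {
  stopifnot(inherits(series, "biomass_series") || is.data.frame(series))
  out <- expand.grid(class = classes, interval_end = interval_days,
                     stringsAsFactors = FALSE)
  out$degraded <- NA_real_
  for (i in seq_len(nrow(out))) {
    cl <- out$class[i]
    d1 <- out$interval_end[i]
    sub <- series[series$class == cl, ]
    prev <- max(sub$day[sub$day < d1])
    q0 <- sub$relative_density[sub$day == prev]
    q1 <- sub$relative_density[sub$day == d1]
    if (length(q0) != 1 || length(q1) != 1) {
      stop_input(sprintf("series lacks days %g/%g for class %s", prev, d1, cl))
    }
    dq <- q0 - q1
    if (dq <= 0) {
      warning(sprintf("class %s accumulated over day %g -> %g; no degraded quantity",
                      cl, prev, d1), call. = FALSE)
    } else {
      out$degraded[i] <- dq
    }
  }
  out
}
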
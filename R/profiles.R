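#' Crank geometry
#'
#' Holds the crank length used to convert cadence into tangential pedal speed
#' and mean pedal force into power. Track sprint cranks are typically 0.165 to
#' 0.175 m; the default everywhere in this package is 0.17 m.
#'
#' @param crank_length_m Crank length in metres, between 0.10 and 0.25.
#' @return An object of class `crank_geometry`.
#' @export
crank_geometry <- function(crank_length_m = 0.17) {
  stopifnot(is.numeric(crank_length_m), length(crank_length_m) == 1L)
  if (crank_length_m < 0.10 || crank_length_m > 0.25) {
    stop("crank_length_m must lie in [0.10, 0.25] m", call. = FALSE)
  }
  structure(list(crank_length_m = crank_length_m), class = "crank_geometry")
}

#' Linear fatigue-free force-velocity profile
#'
#' In maximal multi-joint cycling the relation between mean pedal force and
#' cadence is reliably linear: `F(PR) = a * PR + Fmax`, with negative slope `a`
#' (N per rpm) and intercept `Fmax` (N), the maximal isometric mean pedal force.
#'
#' @param slope_a Slope in N per rpm; must be negative.
#' @param fmax_N Intercept force in N; must be positive.
#' @return An object of class `linear_fv_profile`.
#' @export
linear_fv_profile <- function(slope_a, fmax_N) {
  stopifnot(is.numeric(slope_a), is.numeric(fmax_N))
  if (slope_a >= 0) stop("slope_a must be negative", call. = FALSE)
  if (fmax_N <= 0) stop("fmax_N must be positive", call. = FALSE)
  structure(list(slope_a = slope_a, fmax_N = fmax_N), class = "linear_fv_profile")
}

#' @export
print.linear_fv_profile <- function(x, ...) {
  cat(sprintf("Linear F-v profile: F(PR) = %.3f * PR + %.1f N\n", x$slope_a, x$fmax_N))
  m <- derived_metrics(x)
  cat(sprintf("  PRmax %.1f rpm, PRopt %.1f rpm, Pmax %.0f W (r = 0.17 m)\n",
              m$prmax_rpm, m$propt_rpm, m$pmax_W))
  invisible(x)
}

#' Mean pedal force of a linear profile at a cadence
#'
#' Returns `a * PR + Fmax`. Values above the zero-force cadence `PRmax` come
#' back negative: the algebra is kept exact for the convergence analysis and
#' clamping is left to the caller (the synthetic generator clamps at zero).
#'
#' @param profile A [linear_fv_profile()].
#' @param cadence_rpm Cadence in rpm (vectorised), must be >= 0.
#' @return Force in N.
#' @export
linear_force <- function(profile, cadence_rpm) {
  stopifnot(inherits(profile, "linear_fv_profile"), all(cadence_rpm >= 0))
  profile$slope_a * cadence_rpm + profile$fmax_N
}

#' Power of a linear profile at a cadence
#'
#' Power is force times tangential pedal speed, `P = F * 2 * pi * r * PR`, with
#' cadence converted to rev/s internally.
#'
#' @inheritParams linear_force
#' @param geometry A [crank_geometry()].
#' @return Power in W.
#' @export
linear_power <- function(profile, geometry = crank_geometry(), cadence_rpm) {
  stopifnot(inherits(geometry, "crank_geometry"))
  linear_force(profile, cadence_rpm) *
    2 * pi * geometry$crank_length_m * cadence_rpm / 60
}

#' Derived performance metrics of a linear profile
#'
#' The linear force-velocity relation yields closed-form performance metrics:
#' zero-force cadence `PRmax = -Fmax / a`, power-optimal cadence
#' `PRopt = -Fmax / (2 a) = PRmax / 2`, and maximal power `Pmax`, the power at
#' `PRopt`.
#'
#' @inheritParams linear_power
#' @return A list with `fmax_N`, `prmax_rpm`, `propt_rpm`, `pmax_W`.
#' @export
derived_metrics <- function(profile, geometry = crank_geometry()) {
  prmax <- -profile$fmax_N / profile$slope_a
  propt <- prmax / 2
  list(
    fmax_N = profile$fmax_N,
    prmax_rpm = prmax,
    propt_rpm = propt,
    pmax_W = linear_power(profile, geometry, propt)
  )
}

#' Hill force-velocity profile
#'
#' Hill's rectangular hyperbola `(F + c)(v + d) = (Fmax + c) d` for single-muscle
#' force-velocity behaviour; used here as the fatigue-free substrate of the
#' stroke-based model's power-velocity curve. `v` is tangential pedal speed in
#' m/s; `c` (N) and `d` (m/s) are the Hill constants.
#'
#' @param fmax_N Maximal (isometric) force, N, positive.
#' @param c_N Hill force-like constant, N, positive.
#' @param d_v Hill velocity-like constant, same unit as `v`, positive.
#' @return An object of class `hill_fv_profile`.
#' @export
hill_fv_profile <- function(fmax_N, c_N, d_v) {
  stopifnot(fmax_N > 0, c_N > 0, d_v > 0)
  structure(list(fmax_N = fmax_N, c_N = c_N, d_v = d_v), class = "hill_fv_profile")
}

#' Force of a Hill profile at a velocity
#'
#' Solving the hyperbola for force: `F(v) = (Fmax + c) d / (v + d) - c`, so
#' `F(0) = Fmax` and F decreases strictly in v.
#'
#' @param profile A [hill_fv_profile()].
#' @param v Velocity (vectorised), >= 0; `v + d` must be positive.
#' @return Force in N.
#' @export
hill_force <- function(profile, v) {
  stopifnot(inherits(profile, "hill_fv_profile"), all(v >= 0))
  if (any(v + profile$d_v <= 0)) stop("v + d must be positive", call. = FALSE)
  (profile$fmax_N + profile$c_N) * profile$d_v / (v + profile$d_v) - profile$c_N
}

#' Cubic power-velocity profile
#'
#' Third-order polynomial `P(v) = k1 v + k2 v^2 + k3 v^3` approximating the
#' hyperbolic power-velocity curve near v = 0 (see [cubic_from_hill()]).
#'
#' @param k1,k2,k3 Polynomial coefficients (first to third order); `k1 > 0`.
#' @return An object of class `cubic_pv_profile`.
#' @export
cubic_pv_profile <- function(k1, k2, k3) {
  stopifnot(k1 > 0)
  structure(list(k1 = k1, k2 = k2, k3 = k3), class = "cubic_pv_profile")
}

#' Taylor cubic of the Hill power-velocity curve
#'
#' The hyperbolic power `P(v) = F(v) v` expanded about v = 0 gives
#' `P(v) ~ Fmax v - (Fmax + c)/d v^2 + (Fmax + c)/d^2 v^3`, i.e.
#' `k1 = Fmax`, `k2 = -(Fmax + c)/d`, `k3 = +(Fmax + c)/d^2` (the geometric
#' series of `d/(v + d)` truncated after the cubic term).
#'
#' @param profile A [hill_fv_profile()].
#' @return A [cubic_pv_profile()].
#' @export
cubic_from_hill <- function(profile) {
  stopifnot(inherits(profile, "hill_fv_profile"))
  s <- (profile$fmax_N + profile$c_N)
  cubic_pv_profile(
    k1 = profile$fmax_N,
    k2 = -s / profile$d_v,
    k3 = s / profile$d_v^2
  )
}

#' Power of a cubic profile at a velocity
#'
#' @param profile A [cubic_pv_profile()].
#' @param v Velocity (vectorised).
#' @return Power in W.
#' @export
cubic_power <- function(profile, v) {
  stopifnot(inherits(profile, "cubic_pv_profile"))
  profile$k1 * v + profile$k2 * v^2 + profile$k3 * v^3
}

#' Fatigue-free force-velocity point
#'
#' One per-revolution observation used for the fatigue-free linear fit, tagged
#' with its origin: early `acceleration` revolutions of the isokinetic sprint
#' (< 3 s) or high-cadence (>= 160 rpm) `motoric` sprint revolutions.
#'
#' @param cadence_rpm Cadence in rpm, > 0.
#' @param force_N Mean pedal force in N, >= 0.
#' @param source `"acceleration"` or `"motoric"`.
#' @return A one-row data frame.
#' @export
fv_point <- function(cadence_rpm, force_N, source = c("acceleration", "motoric")) {
  source <- match.arg(source)
  stopifnot(cadence_rpm > 0, force_N >= 0)
  data.frame(cadence_rpm = cadence_rpm, force_N = force_N, source = source,
             stringsAsFactors = FALSE)
}

#' Fit the fatigue-free linear force-velocity profile
#'
#' Ordinary least squares of force on cadence across all selected fatigue-free
#' points (isolated deviations in early acceleration are absorbed by the
#' regression).
#'
#' @param points Data frame with columns `cadence_rpm` and `force_N`
#'   (e.g. rbind of [fv_point()]s or the result of
#'   [select_fatigue_free_points()]).
#' @return A list with `profile` (a [linear_fv_profile()]) and `r2`.
#' @export
fit_linear_fv <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("cadence_rpm", "force_N") %in% names(points)))
  if (length(unique(points$cadence_rpm)) < 2L) {
    stop("need at least 2 distinct cadences to fit a line", call. = FALSE)
  }
  fit <- stats::lm(force_N ~ cadence_rpm, data = points)
  co <- stats::coef(fit)
  sstot <- sum((points$force_N - mean(points$force_N))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sstot
  list(profile = linear_fv_profile(slope_a = unname(co[2]), fmax_N = unname(co[1])),
       r2 = r2)
}
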
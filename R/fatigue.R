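#' Parallel-shift (PASA) fatigue parameters
#'
#' PASA models fatigue as an exponential, time-based decay of the intercept of
#' the linear force-velocity profile toward a residual asymptote `C_F`, after a
#' fatigue-free delay `TD`; the slope is preserved (parallel downward shift).
#' The amplitude is `A_F = Fmax - C_F` and the calibration constraint chain is
#' `A_F > C_F > 0`, `0 < tau_F < 100` s, `TD >= 0`.
#'
#' @param base A [linear_fv_profile()] (fatigue-free substrate).
#' @param cf_N Limiting asymptote force in N, > 0.
#' @param tau_s Time constant in s, in (0, 100).
#' @param td_s Fatigue-free delay in s, >= 0.
#' @param check_amplitude Enforce `A_F > C_F` (default TRUE). Fitted results on
#'   the constraint boundary relax this to `A_F >= C_F`.
#' @return An object of class `pasa_params`.
#' @export
pasa_params <- function(base, cf_N, tau_s, td_s, check_amplitude = TRUE) {
  stopifnot(inherits(base, "linear_fv_profile"))
  if (cf_N <= 0) stop("cf_N must be positive", call. = FALSE)
  if (tau_s <= 0 || tau_s >= 100) stop("tau_s must lie in (0, 100) s", call. = FALSE)
  if (td_s < 0) stop("td_s must be non-negative", call. = FALSE)
  af <- base$fmax_N - cf_N
  if (check_amplitude && af <= cf_N) {
    stop("amplitude A_F = Fmax - C_F must exceed C_F", call. = FALSE)
  }
  structure(list(base = base, af_N = af, cf_N = cf_N, tau_s = tau_s, td_s = td_s),
            class = "pasa_params")
}

#' @export
print.pasa_params <- function(x, ...) {
  cat(sprintf(
    "PASA: Fmax %.1f N, A_F %.1f N, C_F %.1f N, tau_F %.2f s, TD %.2f s, a %.3f N/rpm\n",
    x$base$fmax_N, x$af_N, x$cf_N, x$tau_s, x$td_s, x$base$slope_a))
  invisible(x)
}

#' Stroke-based (PESA) fatigue parameters
#'
#' PESA models fatigue as a constant relative power decrement `delta` per
#' completed pedal stroke after a stroke delay `ND`:
#' `P(n) = Ppeak * (1 - delta)^max(0, n - ND)`. Peak power can be a scalar
#' (identified by the single-cadence isokinetic protocol) or cadence-resolved
#' via a [cubic_pv_profile()] or any function of cadence in rpm.
#'
#' @param peak_power_W Scalar peak power at the evaluation cadence (W), or a
#'   `cubic_pv_profile`, or a function `f(cadence_rpm) -> W`.
#' @param delta Per-stroke relative decrement, in `[0, 1)`.
#' @param nd_strokes Stroke delay (completed strokes), >= 0.
#' @param geometry Crank geometry, needed only to evaluate a cubic profile
#'   (cadence to pedal speed).
#' @return An object of class `pesa_params`.
#' @export
pesa_params <- function(peak_power_W, delta, nd_strokes = 0,
                        geometry = crank_geometry()) {
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)", call. = FALSE)
  if (nd_strokes < 0) stop("nd_strokes must be >= 0", call. = FALSE)
  if (is.numeric(peak_power_W) && peak_power_W <= 0) {
    stop("peak power must be positive", call. = FALSE)
  }
  structure(list(peak_power_W = peak_power_W, delta = delta,
                 nd_strokes = nd_strokes, geometry = geometry),
            class = "pesa_params")
}

#' Peak power of a PESA parameter set at a cadence
#'
#' Scalar peak power is returned as-is (single-cadence use); a cubic profile or
#' function is evaluated at the requested cadence.
#'
#' @param params A [pesa_params()].
#' @param cadence_rpm Cadence in rpm (ignored for scalar peak power).
#' @return Peak power in W.
#' @export
pesa_peak_power <- function(params, cadence_rpm = NULL) {
  pk <- params$peak_power_W
  if (is.numeric(pk)) return(pk)
  if (is.null(cadence_rpm)) stop("cadence needed for cadence-resolved peak power",
                                 call. = FALSE)
  if (inherits(pk, "cubic_pv_profile")) {
    v <- 2 * pi * params$geometry$crank_length_m * cadence_rpm / 60
    return(cubic_power(pk, v))
  }
  if (is.function(pk)) return(pk(cadence_rpm))
  stop("unsupported peak power representation", call. = FALSE)
}

#' PASA time-varying intercept force
#'
#' `Fmax(t) = Fmax` for `t <= TD`, then
#' `(Fmax - C_F) * exp(-(t - TD)/tau) + C_F`: strictly decreasing after the
#' delay with limit `C_F`.
#'
#' @param params A [pasa_params()].
#' @param t_s Time in s (vectorised), >= 0.
#' @return Force in N.
#' @export
pasa_fmax_at_time <- function(params, t_s) {
  stopifnot(inherits(params, "pasa_params"), all(t_s >= 0))
  dt <- pmax(0, t_s - params$td_s)
  params$af_N * exp(-dt / params$tau_s) + params$cf_N
}

#' PASA force at a cadence and time
#'
#' The parallel shift: slope unchanged, intercept time-varying,
#' `F(PR, t) = a * PR + Fmax(t)`.
#'
#' @inheritParams pasa_fmax_at_time
#' @param cadence_rpm Cadence in rpm.
#' @return Force in N (may be negative above the momentary zero-force cadence).
#' @export
pasa_force <- function(params, cadence_rpm, t_s) {
  params$base$slope_a * cadence_rpm + pasa_fmax_at_time(params, t_s)
}

#' PASA power at a cadence and time
#'
#' @inheritParams pasa_force
#' @param geometry A [crank_geometry()].
#' @return Power in W.
#' @export
pasa_power <- function(params, geometry = crank_geometry(), cadence_rpm, t_s) {
  pasa_force(params, cadence_rpm, t_s) *
    2 * pi * geometry$crank_length_m * cadence_rpm / 60
}

#' Cadence series
#'
#' Ordered time stamps with the cadence at each, used to convert between
#' elapsed time and cumulative pedal strokes.
#'
#' @param times_s Strictly increasing times in s.
#' @param cadence_rpm Cadence at each time, >= 0.
#' @return An object of class `cadence_series`.
#' @export
cadence_series <- function(times_s, cadence_rpm) {
  stopifnot(length(times_s) == length(cadence_rpm), length(times_s) >= 2L,
            all(diff(times_s) > 0), all(cadence_rpm >= 0))
  structure(list(times_s = times_s, cadence_rpm = cadence_rpm),
            class = "cadence_series")
}

#' Cumulative pedal strokes at a time
#'
#' `n(t) = integral of PR(t) dt` with cadence in rev/s, evaluated by
#' trapezoidal integration of the cadence series (exact for piecewise-linear
#' cadence). Real-valued and non-decreasing.
#'
#' @param series A [cadence_series()].
#' @param t_s Query time(s) within the series span.
#' @return Stroke count (real).
#' @export
strokes_at_time <- function(series, t_s) {
  stopifnot(inherits(series, "cadence_series"))
  tt <- series$times_s
  if (any(t_s < tt[1] | t_s > tt[length(tt)])) {
    stop("t_s outside the cadence series span", call. = FALSE)
  }
  rev_s <- series$cadence_rpm / 60
  # cumulative trapezoid at the knots
  cum <- c(0, cumsum(diff(tt) * (utils::head(rev_s, -1) + utils::tail(rev_s, -1)) / 2))
  vapply(t_s, function(t) {
    i <- findInterval(t, tt, rightmost.closed = TRUE)
    if (t == tt[i]) return(cum[i])
    # partial trapezoid with linearly interpolated cadence
    f <- (t - tt[i]) / (tt[i + 1] - tt[i])
    r_t <- rev_s[i] + f * (rev_s[i + 1] - rev_s[i])
    cum[i] + (t - tt[i]) * (rev_s[i] + r_t) / 2
  }, numeric(1))
}

#' Stroke delay from the temporal delay
#'
#' `ND = floor(n(TD))`: the number of completed pedal strokes during the
#' fatigue-free delay `TD`.
#'
#' @param series A [cadence_series()].
#' @param td_s Temporal delay in s, within the series span.
#' @return Integer stroke count.
#' @export
nd_from_td <- function(series, td_s) {
  floor(strokes_at_time(series, td_s))
}

#' Original (linear) PESA power at a stroke count
#'
#' `P(n) = Ppeak * (1 - delta * max(0, n - ND))`. The linear form goes negative
#' once `n` exceeds about `ND + 1/delta`; it is retained to reproduce that
#' pathology, which motivated the exponential reformulation.
#'
#' @param params A [pesa_params()].
#' @param n Stroke count (vectorised), >= 0.
#' @param cadence_rpm Optional cadence for cadence-resolved peak power.
#' @return Power in W (may be negative).
#' @export
pesa_power_linear <- function(params, n, cadence_rpm = NULL) {
  stopifnot(all(n >= 0))
  pesa_peak_power(params, cadence_rpm) *
    (1 - params$delta * pmax(0, n - params$nd_strokes))
}

#' Exponential PESA power at a stroke count
#'
#' `P(n) = Ppeak * (1 - delta)^max(0, n - ND)`: strictly positive,
#' non-increasing, with exact geometric ratio `P(n+1)/P(n) = 1 - delta` beyond
#' the stroke delay. `n` may be real-valued (continuous exponent) for
#' time-based evaluation.
#'
#' @inheritParams pesa_power_linear
#' @return Power in W.
#' @export
pesa_power_exp <- function(params, n, cadence_rpm = NULL) {
  stopifnot(all(n >= 0))
  pesa_peak_power(params, cadence_rpm) *
    (1 - params$delta)^pmax(0, n - params$nd_strokes)
}

#' Time-based exponential PESA power
#'
#' Evaluates the exponential PESA at the real-valued stroke count `n(t)`
#' obtained from the cadence series, giving the model's time-based form.
#'
#' @param params A [pesa_params()].
#' @param series A [cadence_series()].
#' @param t_s Time(s) within the series span.
#' @param cadence_rpm Optional cadence for cadence-resolved peak power.
#' @return Power in W.
#' @export
pesa_power_at_time <- function(params, series, t_s, cadence_rpm = NULL) {
  pesa_power_exp(params, strokes_at_time(series, t_s), cadence_rpm)
}

#' PASA per-stroke intercept decrement at a constant cadence
#'
#' Converting the time constant to a per-stroke decrement at constant cadence
#' `PR` (rev/s): `dFmax = 1 - exp(-1 / (PR * tau_F))`, in (0, 1).
#'
#' @param params A [pasa_params()].
#' @param cadence_rev_s Cadence in rev/s, > 0.
#' @return Dimensionless per-stroke decrement.
#' @export
pasa_per_stroke_decrement <- function(params, cadence_rev_s) {
  if (any(cadence_rev_s <= 0)) stop("cadence must be positive", call. = FALSE)
  1 - exp(-1 / (cadence_rev_s * params$tau_s))
}

#' Stroke-indexed PASA intercept force
#'
#' The stroke-based form of the intercept decay at constant cadence:
#' `Fmax(n) = (Fmax - C_F) * (1 - dFmax)^max(0, n - ND) + C_F`, with `dFmax`
#' from [pasa_per_stroke_decrement()]. Algebraically identical to
#' [pasa_fmax_at_time()] at every stroke boundary `t = TD + (n - ND)/PR`.
#'
#' @param params A [pasa_params()].
#' @param n Stroke count (vectorised).
#' @param cadence_rev_s Constant cadence in rev/s.
#' @param nd_strokes Stroke delay; defaults to `TD * PR` (shared delay
#'   convention at constant cadence).
#' @return Force in N.
#' @export
pasa_fmax_at_stroke <- function(params, n, cadence_rev_s,
                                nd_strokes = params$td_s * cadence_rev_s) {
  d <- pasa_per_stroke_decrement(params, cadence_rev_s)
  params$af_N * (1 - d)^pmax(0, n - nd_strokes) + params$cf_N
}
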
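#' Congruence time constant for a per-stroke decrement
#'
#' The time constant at which a time-based exponential intercept decay matches
#' a per-stroke decrement `delta` applied at constant cadence `PR` (rev/s):
#' `tau = 1 / (PR * ln(1/(1 - delta)))`. Exact inverse of
#' [pasa_per_stroke_decrement()]; as a statement about *power* congruence of
#' the two models it is a small-cadence / early-time approximation.
#'
#' @param delta Per-stroke decrement in (0, 1).
#' @param cadence_rev_s Cadence in rev/s, > 0.
#' @return Time constant in s.
#' @export
congruent_tau <- function(delta, cadence_rev_s) {
  if (any(delta <= 0 | delta >= 1)) stop("delta must lie in (0,1)", call. = FALSE)
  if (any(cadence_rev_s <= 0)) stop("cadence must be positive", call. = FALSE)
  1 / (cadence_rev_s * log(1 / (1 - delta)))
}

#' Congruence residual between the two decay laws
#'
#' At constant cadence the models are power-congruent when
#' `(1 - delta)^(n(t) - ND) = (a PR + Fmax(t)) / (a PR + Fmax)` (stroke-based
#' decay factor equals the time-based power ratio). This returns the
#' difference `LHS - RHS` under the shared delay convention `ND = n(TD)` with
#' `n(t) = PR t`; zero means exact congruence at `(PR, t)`, a positive value
#' means the stroke-based model sits above the time-based one.
#'
#' @param pasa A [pasa_params()].
#' @param delta Per-stroke decrement of the stroke-based model.
#' @param cadence_rpm Constant cadence in rpm (below the fatigue-free
#'   zero-force cadence).
#' @param t_s Time in s (vectorised).
#' @return Dimensionless residual.
#' @export
equivalence_residual <- function(pasa, delta, cadence_rpm, t_s) {
  rev_s <- cadence_rpm / 60
  f0 <- pasa$base$slope_a * cadence_rpm + pasa$base$fmax_N
  if (f0 <= 0) {
    stop("fatigue-free force non-positive at this cadence (beyond PRmax)",
         call. = FALSE)
  }
  nd <- rev_s * pasa$td_s
  lhs <- (1 - delta)^pmax(0, rev_s * t_s - nd)
  rhs <- (pasa$base$slope_a * cadence_rpm + pasa_fmax_at_time(pasa, t_s)) / f0
  lhs - rhs
}

#' Stroke-based model paired to a parallel-shift model
#'
#' Builds the stroke-based counterpart of a PASA parameter set for
#' model-to-model comparison: both models share the fatigue-free linear power
#' curve (cadence-resolved peak power), and the decrement defaults to the PASA
#' per-stroke intercept decrement at a reference cadence, i.e. the congruent
#' pairing at that cadence. The stroke delay is `TD` expressed in strokes at
#' the evaluated cadence (each model keeps its own delay on the map).
#'
#' @param pasa A [pasa_params()].
#' @param geometry A [crank_geometry()].
#' @param delta Per-stroke decrement; default derived from `pasa` at
#'   `ref_cadence_rpm`.
#' @param ref_cadence_rpm Reference cadence for the default decrement
#'   (default 135).
#' @return A [pesa_params()] with function-valued peak power.
#' @export
pesa_from_pasa <- function(pasa, geometry = crank_geometry(), delta = NULL,
                           ref_cadence_rpm = 135) {
  if (is.null(delta)) {
    delta <- pasa_per_stroke_decrement(pasa, ref_cadence_rpm / 60)
  }
  base <- pasa$base
  pk <- function(cadence_rpm) linear_power(base, geometry, cadence_rpm)
  pesa_params(pk, delta, nd_strokes = 0, geometry = geometry)
}

pesa_power_surface <- function(pesa, pasa_td_s, cadence_rpm, t_s) {
  rev_s <- cadence_rpm / 60
  n <- rev_s * t_s
  nd <- if (pesa$nd_strokes > 0) pesa$nd_strokes else rev_s * pasa_td_s
  pesa_peak_power(pesa, cadence_rpm) * (1 - pesa$delta)^pmax(0, n - nd)
}

#' Cadence-by-time divergence map of the two models
#'
#' Evaluates both models on a cadence x time grid at constant cadence per
#' column, and reports absolute differences, relative errors (normalised by
#' the time-based prediction, the reference model; `"sym"` normalises by the
#' mean magnitude of the two), and the epsilon-corridor mask
#' `rel_err < eps` marking cells of practical interchangeability.
#'
#' @param pasa A [pasa_params()].
#' @param pesa A [pesa_params()] (e.g. [pesa_from_pasa()]); a scalar peak
#'   power is only meaningful for a single-cadence grid.
#' @param geometry A [crank_geometry()].
#' @param cadence_grid_rpm Sorted cadence grid, default 60-180 by 5.
#' @param time_grid_s Sorted time grid, default 0-60 by 0.5.
#' @param eps Corridor threshold on relative error, default 0.05.
#' @param normalize `"pasa"` (reference) or `"sym"`.
#' @return A `convergence_map`: long-format data frame (`cadence_rpm`, `t_s`,
#'   `p_pasa_W`, `p_pesa_W`, `abs_diff_W`, `rel_err`, `in_corridor`) with the
#'   grids and `eps` as attributes.
#' @export
divergence_map <- function(pasa, pesa, geometry = crank_geometry(),
                           cadence_grid_rpm = seq(60, 180, by = 5),
                           time_grid_s = seq(0, 60, by = 0.5),
                           eps = 0.05, normalize = c("pasa", "sym")) {
  normalize <- match.arg(normalize)
  stopifnot(!is.unsorted(cadence_grid_rpm), !is.unsorted(time_grid_s))
  grid <- expand.grid(t_s = time_grid_s, cadence_rpm = cadence_grid_rpm,
                      KEEP.OUT.ATTRS = FALSE)
  p_pasa <- pasa_power(pasa, geometry, grid$cadence_rpm, grid$t_s)
  p_pesa <- pesa_power_surface(pesa, pasa$td_s, grid$cadence_rpm, grid$t_s)
  abs_diff <- abs(p_pasa - p_pesa)
  denom <- switch(normalize, pasa = abs(p_pasa),
                  sym = (abs(p_pasa) + abs(p_pesa)) / 2)
  rel_err <- ifelse(denom > 0, abs_diff / denom, ifelse(abs_diff > 0, Inf, 0))
  out <- data.frame(cadence_rpm = grid$cadence_rpm, t_s = grid$t_s,
                    p_pasa_W = p_pasa, p_pesa_W = p_pesa,
                    abs_diff_W = abs_diff, rel_err = rel_err,
                    in_corridor = rel_err < eps)
  structure(out, class = c("convergence_map", "data.frame"),
            cadence_grid_rpm = cadence_grid_rpm, time_grid_s = time_grid_s,
            eps = eps)
}

#' Regression of stroke-based on time-based predictions at one cadence
#'
#' OLS of the stroke-based power prediction on the time-based one over a time
#' grid at fixed cadence. A slope of 1 with zero intercept and R2 of 1 means
#' functional equivalence at that cadence; slopes fall below 1 as cadence
#' rises.
#'
#' @inheritParams divergence_map
#' @param cadence_rpm Fixed cadence.
#' @param time_grid_s At least 3 time points.
#' @return List with `cadence_rpm`, `slope`, `intercept_W`, `r2`.
#' @export
regress_predictions <- function(pasa, pesa, geometry = crank_geometry(),
                                cadence_rpm, time_grid_s = seq(0, 45, by = 0.5)) {
  if (length(time_grid_s) < 3L) stop("need >= 3 time points", call. = FALSE)
  x <- pasa_power(pasa, geometry, cadence_rpm, time_grid_s)
  y <- pesa_power_surface(pesa, pasa$td_s, cadence_rpm, time_grid_s)
  if (stats::sd(x) == 0) stop("degenerate (constant) reference prediction",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(cadence_rpm = cadence_rpm, slope = unname(co[2]),
       intercept_W = unname(co[1]), r2 = summary(fit)$r.squared)
}

#' Mean absolute model difference per sprint phase
#'
#' Mean of `|P_pasa - P_pesa|` over each `(t_start, t_end)` phase window at a
#' fixed cadence (evaluated on a 0.1 s grid; a zero-length window is the
#' instantaneous difference).
#'
#' @inheritParams regress_predictions
#' @param phases List of `c(t_start, t_end)` pairs.
#' @return Named numeric vector of per-phase mean absolute differences (W).
#' @export
phase_differences <- function(pasa, pesa, geometry = crank_geometry(),
                              cadence_rpm, phases) {
  vapply(phases, function(ph) {
    stopifnot(length(ph) == 2L, ph[2] >= ph[1])
    tt <- if (ph[2] > ph[1]) seq(ph[1], ph[2], by = 0.1) else ph[1]
    x <- pasa_power(pasa, geometry, cadence_rpm, tt)
    y <- pesa_power_surface(pesa, pasa$td_s, cadence_rpm, tt)
    mean(abs(x - y))
  }, numeric(1))
}
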
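#' Goodness of fit of per-revolution power predictions
#'
#' Root mean square error and coefficient of determination
#' (`R2 = 1 - SSres/SStot` about the observed mean).
#'
#' @param observed_W Observed per-revolution power.
#' @param predicted_W Predicted power, same length.
#' @return List with `rmse_W` and `r2`.
#' @export
goodness <- function(observed_W, predicted_W) {
  if (length(observed_W) != length(predicted_W)) {
    stop("observed and predicted lengths differ", call. = FALSE)
  }
  res <- observed_W - predicted_W
  rmse <- sqrt(mean(res^2))
  sstot <- sum((observed_W - mean(observed_W))^2)
  list(rmse_W = rmse, r2 = 1 - sum(res^2) / sstot)
}

fit_result <- function(model, params, observed_W, predicted_W, extra = list()) {
  g <- goodness(observed_W, predicted_W)
  structure(c(list(model = model, params = params, rmse_W = g$rmse_W, r2 = g$r2,
                   residuals_W = observed_W - predicted_W,
                   n_used = length(observed_W)), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: RMSE %.1f W, R2 %.4f (n = %d)\n",
              x$model, x$rmse_W, x$r2, x$n_used))
  invisible(x)
}

#' Select fatigue-free force-velocity points
#'
#' Combines the first acceleration revolutions of the isokinetic sprint
#' (t < 3 s, at most 4) with up to 3 of the highest-power revolutions at
#' cadence >= 160 rpm from the motoric sprints. These are the points the
#' fatigue-free linear profile is fitted through.
#'
#' @param iso The isokinetic [sprint_trace()].
#' @param motoric List of motoric [sprint_trace()]s (may be empty, with a
#'   warning).
#' @param max_accel,max_motoric Caps on points per source (4 and 3).
#' @param accel_before_s Acceleration cutoff time, default 3 s.
#' @param min_motoric_cadence Motoric qualification cadence, default 160 rpm.
#' @return Data frame of points with columns `cadence_rpm`, `force_N`, `source`.
#' @export
select_fatigue_free_points <- function(iso, motoric = list(),
                                       max_accel = 4L, max_motoric = 3L,
                                       accel_before_s = 3,
                                       min_motoric_cadence = 160) {
  stopifnot(inherits(iso, "sprint_trace"))
  r <- iso$revolutions
  acc <- r[r$t_s < accel_before_s, , drop = FALSE]
  acc <- utils::head(acc, max_accel)
  if (nrow(acc) < 3L) {
    stop("need at least 3 acceleration revolutions before ", accel_before_s,
         " s", call. = FALSE)
  }
  pts <- data.frame(cadence_rpm = acc$cadence_rpm, force_N = acc$force_N,
                    source = "acceleration", stringsAsFactors = FALSE)
  if (length(motoric) == 0L) {
    warning("no motoric traces supplied; using acceleration points only",
            call. = FALSE)
  } else {
    mot <- do.call(rbind, lapply(motoric, function(m) m$revolutions))
    mot <- mot[mot$cadence_rpm >= min_motoric_cadence, , drop = FALSE]
    if (nrow(mot)) {
      mot <- mot[order(-mot$power_W), , drop = FALSE]
      mot <- utils::head(mot, max_motoric)
      pts <- rbind(pts, data.frame(cadence_rpm = mot$cadence_rpm,
                                   force_N = mot$force_N, source = "motoric",
                                   stringsAsFactors = FALSE))
    }
  }
  if (nrow(pts) < 2L) stop("fewer than 2 usable fatigue-free points", call. = FALSE)
  pts
}

#' Calibrate the parallel-shift model on a sprint trace
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box constraints)
#' minimising the squared power residuals over the at-target revolutions,
#' under the physiological constraints `A_F > C_F > 0`, `0 < tau_F < 100`,
#' `TD >= 0`. By default the intercept `Fmax` is fixed to the fatigue-free
#' profile (so `A_F = Fmax - C_F` and the free parameters are
#' `C_F, tau_F, TD`); with `refit_fmax = TRUE` all four of
#' `A_F, C_F, tau_F, TD` are free and the ordering constraint is enforced by a
#' non-negative gap `A_F - C_F`, whose lower bound being active is reported as
#' `pinned`.
#'
#' @param trace Isokinetic [sprint_trace()] with at least 10 at-target
#'   revolutions.
#' @param fv Fatigue-free [linear_fv_profile()] (from
#'   [select_fatigue_free_points()] + [fit_linear_fv()]).
#' @param geometry A [crank_geometry()]; defaults to the trace's.
#' @param refit_fmax Refit `Fmax` instead of fixing it to the intercept.
#' @param window `"isokinetic"` (default; the common scoring window) or
#'   `"all"` revolutions.
#' @param max_restarts Jittered restarts on non-convergence (deterministic
#'   jitter schedule).
#' @return A `fit_result` whose `params` is a [pasa_params()]; extra fields
#'   `converged`, `pinned`, `window_idx`.
#' @export
fit_pasa <- function(trace, fv, geometry = trace$geometry, refit_fmax = FALSE,
                     window = c("isokinetic", "all"), max_restarts = 5L) {
  window <- match.arg(window)
  stopifnot(inherits(trace, "sprint_trace"), inherits(fv, "linear_fv_profile"))
  idx <- if (window == "isokinetic") isokinetic_window(trace) else
    seq_len(nrow(trace$revolutions))
  r <- trace$revolutions[idx, , drop = FALSE]
  if (nrow(r) < 10L) stop("need at least 10 revolutions to fit", call. = FALSE)
  k <- 2 * pi * geometry$crank_length_m / 60
  a <- fv$slope_a
  t_obs <- r$t_s; pr <- r$cadence_rpm; p_obs <- r$power_W
  t_max <- max(t_obs)

  model_power <- function(fmax, cf, tau, td) {
    (a * pr + (fmax - cf) * exp(-pmax(0, t_obs - td) / tau) + cf) * k * pr
  }

  if (!refit_fmax) {
    fmax <- fv$fmax_N
    resid_fn <- function(th) p_obs - model_power(fmax, th[1], th[2], th[3])
    lower <- c(1e-6, 1e-3, 0)
    upper <- c(fmax / 2 - 1e-6, 100 - 1e-6, t_max)
    th0 <- c(0.4 * fmax, 30, min(t_obs[which.max(p_obs)], t_max / 2))
  } else {
    # th = (gap, cf, tau, td); A_F = cf + gap, Fmax = A_F + cf
    resid_fn <- function(th) {
      p_obs - model_power(2 * th[2] + th[1], th[2], th[3], th[4])
    }
    lower <- c(0, 1e-3, 1e-3, 0)
    upper <- c(Inf, Inf, 100 - 1e-6, t_max)
    cf0 <- 0.4 * fv$fmax_N
    th0 <- c(fv$fmax_N - 2 * cf0, cf0, 30,
             min(t_obs[which.max(p_obs)], t_max / 2))
  }

  # deterministic jitter schedule: attempt 1 is the plain start
  jitter_grid <- rbind(c(1, 1, 1), c(0.6, 1.4, 0.5), c(1.4, 0.7, 1.5),
                       c(0.8, 2.0, 0.25), c(1.2, 0.5, 2.0), c(0.5, 1.0, 1.0))
  best <- NULL
  for (i in seq_len(min(max_restarts + 1L, nrow(jitter_grid)))) {
    jf <- jitter_grid[i, ]
    mult <- if (length(th0) == 3L) jf else c(jf[1], jf[1], jf[2], jf[3])
    start <- th0 * mult
    cap <- ifelse(is.finite(upper), upper - 1e-8, start)
    start <- pmin(pmax(start, lower + 1e-8), cap)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-12,
                                                              ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    best <- fit
    break
  }
  if (is.null(best)) {
    stop("PASA fit failed to converge after ", max_restarts, " restarts",
         call. = FALSE)
  }
  th <- best$par
  if (!refit_fmax) {
    cf <- th[1]; tau <- th[2]; td <- th[3]
    fmax_hat <- fv$fmax_N
    pinned <- cf >= fv$fmax_N / 2 - 1e-4
  } else {
    cf <- th[2]; tau <- th[3]; td <- th[4]
    fmax_hat <- 2 * th[2] + th[1]
    pinned <- th[1] <= 1e-6
  }
  params <- pasa_params(linear_fv_profile(a, fmax_hat), cf_N = cf, tau_s = tau,
                        td_s = td, check_amplitude = FALSE)
  fit_result("PASA", params, p_obs,
             pasa_power(params, geometry, pr, t_obs),
             extra = list(converged = TRUE, pinned = pinned, window_idx = idx))
}

#' Detect the stroke delay of the power decline
#'
#' Operational rule: the stroke delay `ND` is the last pedal stroke preceding
#' a sustained decline, i.e. the smallest stroke index `k` (scanning from the
#' first at-target revolution by default) followed by at least `run_length`
#' consecutive strokes with strictly monotonically decreasing mean power
#' (`P(k) > P(k+1) > ... > P(k+run_length)`). Ties break the run (tolerance
#' configurable, default 0 W).
#'
#' @param trace A [sprint_trace()] with at least `run_length + 1` revolutions.
#' @param from Scan start: `"target"` (first at-target revolution) or
#'   `"start"`.
#' @param run_length Required run of declining strokes, default 5.
#' @param tol Minimum per-stroke drop in W to count as declining, default 0.
#' @return Integer stroke index `ND`.
#' @export
detect_nd <- function(trace, from = c("target", "start"), run_length = 5L,
                      tol = 0) {
  from <- match.arg(from)
  r <- trace$revolutions
  if (nrow(r) < run_length + 1L) stop("too few revolutions", call. = FALSE)
  start <- if (from == "target") isokinetic_window(trace)[1] else 1L
  p <- r$power_W
  declining <- diff(p) < -tol            # stroke i+1 lower than stroke i
  for (kpos in seq.int(start, nrow(r) - run_length)) {
    if (all(declining[kpos:(kpos + run_length - 1L)])) {
      return(r$index_n[kpos])
    }
  }
  stop("no sustained power decline found (trace not fatiguing)", call. = FALSE)
}

#' Empirical per-stroke decrement
#'
#' The mean relative per-stroke power loss following `nd` within a time
#' window: the arithmetic mean of `1 - P(i+1)/P(i)` over consecutive
#' revolutions from stroke `nd` up to `window_end_s` (15 s for the short
#' estimate, the full sprint for the long one). Also returns the SD of the
#' individual losses.
#'
#' @param trace A [sprint_trace()].
#' @param nd Stroke delay (from [detect_nd()]).
#' @param window_end_s Window end time in s (e.g. 15, or `Inf` for the whole
#'   sprint).
#' @param geometric Use the geometric mean of the ratios instead (returns
#'   `1 - exp(mean(log(P(i+1)/P(i))))`); second-order different at the ~1.5%
#'   scale.
#' @return List with `delta`, `sd`, `n_losses`, `losses`.
#' @export
estimate_delta <- function(trace, nd, window_end_s = Inf, geometric = FALSE) {
  r <- trace$revolutions
  sel <- which(r$index_n >= nd & r$t_s <= window_end_s)
  if (length(sel) < 2L) stop("window after ND contains fewer than 2 revolutions",
                             call. = FALSE)
  p <- r$power_W[sel]
  ratios <- p[-1] / p[-length(p)]
  # ratios are undefined where the clamped power hits zero; drop those pairs
  ratios <- ratios[is.finite(ratios) & p[-length(p)] > 0 & p[-1] > 0]
  if (length(ratios) < 1L) stop("no usable per-stroke ratios in window",
                                call. = FALSE)
  losses <- 1 - ratios
  delta <- if (geometric) 1 - exp(mean(log(ratios))) else mean(losses)
  list(delta = delta, sd = stats::sd(losses), n_losses = length(losses),
       losses = losses)
}

#' RMSE-optimal per-stroke decrement
#'
#' Treats the decrement as a free parameter with the stroke delay held
#' constant: bounded 1-D minimisation of the RMSE between observed at-target
#' per-revolution power and the exponential stroke-based prediction
#' `Ppeak (1 - delta)^max(0, n - nd)`. Deterministic given the trace.
#'
#' @param trace A [sprint_trace()].
#' @param nd Stroke delay (held fixed).
#' @param ppeak_W Peak power; defaults to the maximum observed at-target
#'   power.
#' @param interval Search interval for `delta`, default `(1e-8, 0.2]`.
#' @return List with `delta_opt` and `fit` (a `fit_result`).
#' @export
optimize_delta <- function(trace, nd, ppeak_W = NULL, interval = c(1e-8, 0.2)) {
  idx <- isokinetic_window(trace)
  r <- trace$revolutions[idx, , drop = FALSE]
  if (is.null(ppeak_W)) ppeak_W <- max(r$power_W)
  pred <- function(delta) ppeak_W * (1 - delta)^pmax(0, r$index_n - nd)
  obj <- function(delta) sqrt(mean((r$power_W - pred(delta))^2))
  opt <- stats::optimize(obj, interval = interval, tol = 1e-10)
  delta_opt <- opt$minimum
  params <- pesa_params(ppeak_W, delta_opt, nd, trace$geometry)
  list(delta_opt = delta_opt,
       fit = fit_result("PESAopt", params, r$power_W, pred(delta_opt),
                        extra = list(window_idx = idx)))
}

#' Calibrate every model variant on one athlete's traces
#'
#' The full single-athlete pipeline: fatigue-free point selection and linear
#' fit, constrained PASA calibration, stroke-delay detection, empirical
#' decrements over 15 s and the full sprint, peak power, the two empirical
#' stroke-based variants, and the RMSE-optimal variant. All variants are
#' scored on the same at-target window so their RMSE/R2 are comparable.
#'
#' @param iso Isokinetic [sprint_trace()].
#' @param motoric List of motoric traces (may be empty).
#' @param geometry A [crank_geometry()]; defaults to the trace's.
#' @param refit_fmax Passed to [fit_pasa()].
#' @return List with `fv` (+ `fv_r2`), `pasa`, `pesa15`, `pesa45`, `pesa_opt`
#'   (fit_results), `nd`, `delta15`, `delta45`, `ppeak_W`, and `row`: a named
#'   numeric vector mirroring the calibrated-parameter table
#'   (Fmax, Pmax, PRopt, a, AF, tauF, CF, TD, Ppeak, Delta15, Delta45, ND,
#'   R2, RMSE).
#' @export
calibrate_athlete <- function(iso, motoric = list(), geometry = iso$geometry,
                              refit_fmax = FALSE) {
  pts <- select_fatigue_free_points(iso, motoric)
  fv_fit <- fit_linear_fv(pts)
  fv <- fv_fit$profile
  pasa <- fit_pasa(iso, fv, geometry, refit_fmax = refit_fmax)

  idx0 <- isokinetic_window(iso)
  r0 <- iso$revolutions[idx0, , drop = FALSE]
  nd <- tryCatch(detect_nd(iso), error = function(e) NA_integer_)
  # a sustained decline cannot begin after the maximum observed power, but
  # stroke-to-stroke noise can delay the first strictly monotone run well past
  # the true fatigue onset (or suppress it entirely); cap the delay at the
  # peak-power stroke
  nd_peak <- r0$index_n[which.max(r0$power_W)]
  nd <- if (is.na(nd)) nd_peak else min(nd, nd_peak)
  d15 <- estimate_delta(iso, nd, window_end_s = 15)
  d45 <- estimate_delta(iso, nd, window_end_s = Inf)
  idx <- isokinetic_window(iso)
  r <- iso$revolutions[idx, , drop = FALSE]
  ppeak <- max(r$power_W)

  pesa_fit <- function(delta, label) {
    params <- pesa_params(ppeak, delta, nd, geometry)
    fit_result(label, params, r$power_W, pesa_power_exp(params, r$index_n),
               extra = list(window_idx = idx))
  }
  pesa15 <- pesa_fit(d15$delta, "PESA15")
  pesa45 <- pesa_fit(d45$delta, "PESA45")
  opt <- optimize_delta(iso, nd, ppeak_W = ppeak)

  met <- derived_metrics(fv, geometry)
  row <- c(Fmax = fv$fmax_N, Pmax = met$pmax_W, PRopt = met$propt_rpm,
           a = fv$slope_a, AF = pasa$params$af_N, tauF = pasa$params$tau_s,
           CF = pasa$params$cf_N, TD = pasa$params$td_s, Ppeak = ppeak,
           Delta15 = d15$delta, Delta15SD = d15$sd,
           Delta45 = d45$delta, Delta45SD = d45$sd, ND = nd,
           DeltaOpt = opt$delta_opt, R2 = pasa$r2, RMSE = pasa$rmse_W,
           RMSE_PESA15 = pesa15$rmse_W, RMSE_PESA45 = pesa45$rmse_W,
           RMSE_PESAopt = opt$fit$rmse_W, FvR2 = fv_fit$r2)
  list(fv = fv, fv_r2 = fv_fit$r2, pasa = pasa, pesa15 = pesa15,
       pesa45 = pesa45, pesa_opt = opt$fit, nd = nd, delta15 = d15,
       delta45 = d45, ppeak_W = ppeak, row = row)
}
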
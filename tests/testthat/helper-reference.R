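# Pooled reference values used across tests (profile + fatigue parameters of
# the elite track-sprint cohort, and the printed group performance summaries).
ref <- list(
  fmax = 1207, a = -4.53, cf = 483, tau = 38, td = 2.55,
  ppeak = 1299, delta15 = 0.0151, delta45 = 0.0145, nd = 5,
  mean_power_male = c(845, 178, 6), mean_power_female = c(573, 89, 6),
  peak_power_male = c(1648, 391, 6), peak_power_female = c(1141, 229, 6)
)

ref_fv <- function() linear_fv_profile(ref$a, ref$fmax)

ref_pasa <- function() {
  pasa_params(ref_fv(), cf_N = ref$cf, tau_s = ref$tau, td_s = ref$td)
}

# constant-cadence trace built directly from per-revolution powers
make_trace <- function(power_W, cadence_rpm = 135, geometry = crank_geometry()) {
  n <- length(power_W)
  t_s <- seq_len(n) * 60 / cadence_rpm
  k <- 2 * pi * geometry$crank_length_m / 60
  revs <- data.frame(index_n = seq_len(n), t_s = t_s,
                     cadence_rpm = rep(cadence_rpm, n),
                     force_N = power_W / (k * cadence_rpm), power_W = power_W)
  sprint_trace(revs, cadence_rpm, geometry, "isokinetic_45s")
}

quiet_calibrate <- function(...) suppressWarnings(calibrate_athlete(...))
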
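#' Reference parameter distributions for elite track sprint cyclists
#'
#' Means and SDs of the fatigue-free profile and fatigue parameters for a
#' 12-athlete elite track-sprint cohort (pooled, plus the male/female
#' subgroup values where reported): intercept force `Fmax` (N), slope `a`
#' (N/rpm), decay amplitude asymptote `C_F` (N), time constant `tau_F` (s),
#' fatigue-free delay `TD` (s), and the per-stroke decrement summaries
#' `Delta15`/`Delta45` (fractions) with stroke delay `ND`.
#'
#' @param sex `"pooled"`, `"male"` or `"female"`.
#' @return Named list of `c(mean, sd)` pairs.
#' @export
reference_parameters <- function(sex = c("pooled", "male", "female")) {
  sex <- match.arg(sex)
  switch(sex,
    pooled = list(
      fmax_N = c(1207, 245), slope_a = c(-4.53, 0.76),
      cf_N = c(483, 129), tau_s = c(38, 12), td_s = c(2.55, 0.53),
      delta15 = c(0.0151, 0.0040), delta45 = c(0.0145, 0.0021),
      nd = c(5, 1), ppeak_W = c(1299, 381)
    ),
    male = list(
      fmax_N = c(1389, 157), slope_a = c(-4.98, 0.63),
      cf_N = c(495, 151), tau_s = c(39.1, 9.2), td_s = c(2.55, 0.53),
      delta15 = c(0.0145, 0.0031), delta45 = c(0.0144, 0.0018),
      nd = c(5, 1), ppeak_W = c(1299, 381)
    ),
    female = list(
      fmax_N = c(1026, 164), slope_a = c(-4.07, 0.62),
      cf_N = c(470, 117), tau_s = c(36.5, 15.5), td_s = c(2.55, 0.53),
      delta15 = c(0.0157, 0.0050), delta45 = c(0.0146, 0.0026),
      nd = c(5, 1), ppeak_W = c(1299, 381)
    ))
}

#' Athlete at the reference means
#'
#' Deterministic athlete whose fatigue-free profile and PASA parameters sit at
#' the pooled reference means; the canonical parameter set for closed-form
#' checks and convergence maps.
#'
#' @param geometry A [crank_geometry()].
#' @return An `athlete_spec`.
#' @export
reference_athlete <- function(geometry = crank_geometry()) {
  p <- reference_parameters("pooled")
  fv <- linear_fv_profile(p$slope_a[1], p$fmax_N[1])
  athlete_spec(fv = fv,
               pasa = pasa_params(fv, cf_N = p$cf_N[1], tau_s = p$tau_s[1],
                                  td_s = p$td_s[1]),
               sex = "pooled", geometry = geometry)
}

#' Athlete specification
#'
#' Bundles the fatigue-free linear profile, the PASA truth parameters, and the
#' geometry. The PESA truth for a given protocol cadence is derived on demand
#' (see [athlete_pesa_truth()]).
#'
#' @param fv A [linear_fv_profile()].
#' @param pasa A [pasa_params()] built on `fv`.
#' @param sex Tag (`"pooled"`, `"male"`, `"female"`).
#' @param geometry A [crank_geometry()].
#' @return An object of class `athlete_spec`.
#' @export
athlete_spec <- function(fv, pasa, sex = "pooled", geometry = crank_geometry()) {
  stopifnot(inherits(fv, "linear_fv_profile"), inherits(pasa, "pasa_params"))
  structure(list(fv = fv, pasa = pasa, sex = sex, geometry = geometry),
            class = "athlete_spec")
}

#' Stroke-based truth parameters of an athlete at a protocol cadence
#'
#' Derives the PESA truth from the athlete's PASA truth so that the two model
#' families stay comparable: peak power is the fatigue-free linear power at the
#' protocol cadence, the decrement is the PASA per-stroke intercept decrement
#' at that cadence, and the stroke delay is the completed-stroke count at `TD`.
#'
#' @param athlete An [athlete_spec()].
#' @param target_cadence_rpm Protocol cadence in rpm.
#' @param nd_strokes Stroke delay; default `floor(TD * PR)` at constant target
#'   cadence.
#' @return A [pesa_params()].
#' @export
athlete_pesa_truth <- function(athlete, target_cadence_rpm = 135,
                               nd_strokes = NULL) {
  rev_s <- target_cadence_rpm / 60
  if (is.null(nd_strokes)) nd_strokes <- floor(athlete$pasa$td_s * rev_s)
  pesa_params(
    peak_power_W = linear_power(athlete$fv, athlete$geometry, target_cadence_rpm),
    delta = pasa_per_stroke_decrement(athlete$pasa, rev_s),
    nd_strokes = nd_strokes,
    geometry = athlete$geometry
  )
}

#' Protocol specification
#'
#' The study conditions: a seated 45 s maximal isokinetic sprint at 135 rpm
#' with a stationary start, acceleration revolutions on a prescribed cadence
#' ramp reaching target by about 3 s, plus short minimal-resistance (motoric)
#' sprints supplying fatigue-free high-cadence (>= 160 rpm) points.
#'
#' @param target_cadence_rpm Enforced cadence, default 135 rpm.
#' @param duration_s Sprint duration, default 45 s.
#' @param accel_fractions Ramp cadences as fractions of target, one revolution
#'   each; defaults reach target in ~2.9 s.
#' @param motoric_duration_s Duration of a motoric sprint, default 6 s.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(target_cadence_rpm = 135, duration_s = 45,
                          accel_fractions = c(0.35, 0.68, 0.88, 0.97),
                          motoric_duration_s = 6) {
  stopifnot(duration_s > 0, all(accel_fractions > 0 & accel_fractions < 1),
            !is.unsorted(accel_fractions))
  accel_span <- sum(60 / (accel_fractions * target_cadence_rpm))
  if (duration_s <= accel_span) {
    stop("duration must exceed the acceleration span", call. = FALSE)
  }
  structure(list(target_cadence_rpm = target_cadence_rpm, duration_s = duration_s,
                 accel_fractions = accel_fractions,
                 motoric_duration_s = motoric_duration_s),
            class = "protocol_spec")
}

#' Noise specification
#'
#' Multiplicative stroke-to-stroke variability: each revolution's power is
#' multiplied by an independent lognormal factor with mean 1 and coefficient of
#' variation `cv` (default 3%, the scale of the observed per-stroke loss SDs).
#' `fatigue_growth` linearly inflates the CV toward the end of the sprint
#' (`cv * (1 + fatigue_growth * t/duration)`) to emulate the increase in
#' late-sprint variability.
#'
#' @param cv Coefficient of variation, >= 0; default 0.03.
#' @param fatigue_growth Linear CV growth factor over the sprint, default 0.
#' @param seed Optional integer seed applied inside the generator.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.03, fatigue_growth = 0, seed = NULL) {
  stopifnot(cv >= 0, fatigue_growth >= 0)
  structure(list(cv = cv, fatigue_growth = fatigue_growth, seed = seed),
            class = "noise_spec")
}

rlnorm_mean1 <- function(n, cv) {
  if (length(cv) == 1L) cv <- rep(cv, n)
  out <- rep(1, n)
  pos <- cv > 0
  if (any(pos)) {
    s2 <- log(1 + cv[pos]^2)
    out[pos] <- stats::rlnorm(sum(pos), meanlog = -s2 / 2, sdlog = sqrt(s2))
  }
  out
}

rtrunc_norm <- function(mean, sd, lower = -Inf, upper = Inf, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
  stop("truncated-normal sampling failed to satisfy bounds", call. = FALSE)
}

#' Sample an athlete from the reference distributions
#'
#' Draws `(Fmax, a, C_F, tau_F, TD)` from truncated normals at the reference
#' means/SDs (pooled or sex-specific), resampling until the calibration
#' constraint chain `A_F > C_F > 0`, `0 < tau_F < 100`, `TD >= 0`, `a < 0`
#' holds. Parameters are drawn independently (marginal SDs only are reported;
#' no correlation structure is assumed).
#'
#' @param seed Integer seed (same seed, same athlete).
#' @param sex `"pooled"`, `"male"` or `"female"`.
#' @param geometry A [crank_geometry()].
#' @param max_tries Resampling budget for the joint constraints.
#' @param require_completion Additionally require the protocol-completion
#'   constraint used for cohort recruitment: the modelled force at the
#'   protocol cadence at sprint end stays above `min_final_force_N` (study
#'   participants all finished the 45 s sprint with substantial positive
#'   power). Off by default so the marginal parameter distributions are
#'   unbiased.
#' @param protocol_cadence_rpm,protocol_duration_s,min_final_force_N The
#'   completion constraint, used when `require_completion = TRUE`.
#' @return An [athlete_spec()].
#' @export
sample_athlete <- function(seed = NULL, sex = c("pooled", "male", "female"),
                           geometry = crank_geometry(), max_tries = 200L,
                           require_completion = FALSE,
                           protocol_cadence_rpm = 135, protocol_duration_s = 45,
                           min_final_force_N = 25) {
  sex <- match.arg(sex)
  if (!is.null(seed)) set.seed(seed)
  p <- reference_parameters(sex)
  for (i in seq_len(max_tries)) {
    fmax <- rtrunc_norm(p$fmax_N[1], p$fmax_N[2], lower = 300)
    a <- rtrunc_norm(p$slope_a[1], p$slope_a[2], upper = -0.5)
    cf <- rtrunc_norm(p$cf_N[1], p$cf_N[2], lower = 1)
    tau <- rtrunc_norm(p$tau_s[1], p$tau_s[2], lower = 1, upper = 99)
    td <- rtrunc_norm(p$td_s[1], p$td_s[2], lower = 0.5)
    ok <- (fmax - cf) > cf   # A_F > C_F
    propt <- -fmax / (2 * a)
    ok <- ok && propt > 100 && propt < 160   # plausible optimal cadence
    if (require_completion) {
      # recruitment filter: positive force at target cadence at sprint end
      fmax_end <- (fmax - cf) *
        exp(-max(0, protocol_duration_s - td) / tau) + cf
      ok <- ok && (a * protocol_cadence_rpm + fmax_end) > min_final_force_N
    }
    if (ok) {
      fv <- linear_fv_profile(a, fmax)
      return(athlete_spec(fv, pasa_params(fv, cf, tau, td), sex, geometry))
    }
  }
  stop("could not satisfy athlete constraints after ", max_tries, " tries",
       call. = FALSE)
}

#' Generate a synthetic isokinetic sprint trace
#'
#' Builds a revolution-by-revolution 45 s isokinetic sprint: acceleration
#' revolutions at the prescribed ramp cadences with forces on the fatigue-free
#' line, then revolutions at target cadence with power from the truth model
#' (time-based PASA at the revolution's end time, or exponential PESA at its
#' stroke count). Each revolution's power is multiplied by independent
#' lognormal noise and clamped at zero; time stamps are cumulative revolution
#' durations.
#'
#' @param athlete An [athlete_spec()].
#' @param protocol A [protocol_spec()].
#' @param noise A [noise_spec()].
#' @param truth `"pasa"` or `"pesa"`: which model governs the power decline.
#' @return A [sprint_trace()] whose `meta` records seed and truth parameters.
#' @export
generate_sprint <- function(athlete, protocol = protocol_spec(),
                            noise = noise_spec(), truth = c("pasa", "pesa")) {
  truth <- match.arg(truth)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  target <- protocol$target_cadence_rpm
  geom <- athlete$geometry
  k <- 2 * pi * geom$crank_length_m / 60   # W per (N * rpm)

  cad_accel <- protocol$accel_fractions * target
  dur_accel <- 60 / cad_accel
  t_accel <- cumsum(dur_accel)
  n_iso <- floor((protocol$duration_s - t_accel[length(t_accel)]) / (60 / target))
  cad <- c(cad_accel, rep(target, n_iso))
  t_end <- c(t_accel, t_accel[length(t_accel)] + seq_len(n_iso) * 60 / target)
  n_rev <- length(cad)
  idx <- seq_len(n_rev)
  iso <- seq.int(length(cad_accel) + 1L, n_rev)

  force_accel <- pmax(0, linear_force(athlete$fv, cad_accel))
  power <- numeric(n_rev)
  power[-iso] <- force_accel * k * cad_accel

  pesa_truth <- athlete_pesa_truth(athlete, target)
  truth_params <- switch(truth, pasa = athlete$pasa, pesa = {
    nd <- sum(t_end <= athlete$pasa$td_s)   # completed strokes during TD
    pesa_params(pesa_truth$peak_power_W, pesa_truth$delta, nd, geom)
  })
  power[iso] <- switch(truth,
    pasa = pasa_power(athlete$pasa, geom, target, t_end[iso]),
    pesa = pesa_power_exp(truth_params, idx[iso]))

  cv_t <- noise$cv * (1 + noise$fatigue_growth * t_end / protocol$duration_s)
  power <- pmax(0, power * rlnorm_mean1(n_rev, cv_t))
  revs <- data.frame(index_n = idx, t_s = t_end, cadence_rpm = cad,
                     force_N = power / (k * cad), power_W = power)
  sprint_trace(revs, target, geom, "isokinetic_45s",
               meta = list(truth = truth, truth_params = truth_params,
                           athlete = athlete, seed = noise$seed,
                           noise_cv = noise$cv))
}

#' Generate a synthetic motoric (minimal-resistance) sprint
#'
#' A short maximal sprint against minimal resistance whose top-cadence
#' revolutions (>= 160 rpm) lie on the fatigue-free force-velocity line (plus
#' multiplicative noise); used solely to supply fatigue-free high-cadence
#' points for the linear fit.
#'
#' @param athlete An [athlete_spec()].
#' @param noise A [noise_spec()] (its `seed` is applied if set).
#' @param protocol A [protocol_spec()] (uses `motoric_duration_s`).
#' @return A [sprint_trace()] with protocol tag `motoric_6s`.
#' @export
generate_motoric <- function(athlete, noise = noise_spec(),
                             protocol = protocol_spec()) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  geom <- athlete$geometry
  k <- 2 * pi * geom$crank_length_m / 60
  prmax <- derived_metrics(athlete$fv, geom)$prmax_rpm
  top <- min(max(165, 0.70 * prmax), 0.93 * prmax)
  frac <- c(0.35, 0.55, 0.72, 0.85, 0.93, 1.0)
  cad <- frac * top
  t_end <- cumsum(60 / cad)
  while (t_end[length(t_end)] < protocol$motoric_duration_s) {
    cad <- c(cad, top)
    t_end <- c(t_end, t_end[length(t_end)] + 60 / top)
  }
  keep <- t_end <= protocol$motoric_duration_s + 1e-9
  cad <- cad[keep]; t_end <- t_end[keep]
  force <- pmax(0, linear_force(athlete$fv, cad))
  power <- pmax(0, force * k * cad * rlnorm_mean1(length(cad), noise$cv))
  revs <- data.frame(index_n = seq_along(cad), t_s = t_end, cadence_rpm = cad,
                     force_N = power / (k * cad), power_W = power)
  sprint_trace(revs, top, geom, "motoric_6s",
               meta = list(seed = noise$seed, noise_cv = noise$cv))
}

#' Generate a seeded synthetic cohort
#'
#' `n` athletes (default the study's 12, split 6 female / 6 male), each with
#' one isokinetic sprint and two motoric sprints. All randomness flows from the
#' master seed through per-athlete sub-seeds, so the cohort is reproducible.
#'
#' @param n Number of athletes, >= 2.
#' @param seed Master integer seed.
#' @param sex_split Length-2 vector `c(n_female, n_male)` summing to `n`, or
#'   `NULL` for pooled sampling.
#' @param truth `"pasa"` or `"pesa"` truth model.
#' @param protocol A [protocol_spec()].
#' @param noise A [noise_spec()] (its `cv`/`fatigue_growth` are used; seeds are
#'   derived from the master seed).
#' @return List of `n` elements, each `list(athlete, iso, motoric)` with
#'   `motoric` a list of two traces.
#' @export
generate_cohort <- function(n = 12, seed = 1, sex_split = c(6, 6),
                            truth = c("pasa", "pesa"),
                            protocol = protocol_spec(), noise = noise_spec()) {
  truth <- match.arg(truth)
  stopifnot(n >= 2)
  if (!is.null(sex_split)) {
    stopifnot(length(sex_split) == 2L, sum(sex_split) == n)
    sexes <- rep(c("female", "male"), times = sex_split)
  } else {
    sexes <- rep("pooled", n)
  }
  set.seed(seed)
  sub <- matrix(sample.int(.Machine$integer.max - 1L, n * 4L), nrow = n)
  lapply(seq_len(n), function(i) {
    athlete <- sample_athlete(seed = sub[i, 1], sex = sexes[i],
                              require_completion = TRUE,
                              protocol_cadence_rpm = protocol$target_cadence_rpm,
                              protocol_duration_s = protocol$duration_s)
    iso <- generate_sprint(athlete, protocol,
                           noise_spec(noise$cv, noise$fatigue_growth, sub[i, 2]),
                           truth = truth)
    mot <- lapply(3:4, function(j) {
      generate_motoric(athlete, noise_spec(noise$cv, 0, sub[i, j]), protocol)
    })
    list(athlete = athlete, iso = iso, motoric = mot)
  })
}
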
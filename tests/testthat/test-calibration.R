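test_that("goodness of fit matches hand arithmetic", {
  obs <- c(100, 200, 300)
  expect_equal(goodness(obs, obs), list(rmse_W = 0, r2 = 1))
  g <- goodness(obs, rep(mean(obs), 3))
  expect_equal(g$r2, 0)
  g2 <- goodness(c(10, 10), c(7, 14))
  expect_equal(g2$rmse_W, sqrt((9 + 16) / 2))
  expect_equal(g2$rmse_W, 3.5355, tolerance = 1e-4)
  expect_error(goodness(1:3, 1:4), "lengths")
})

test_that("fatigue-free point selection combines acceleration and motoric revolutions", {
  ath <- reference_athlete()
  iso <- generate_sprint(ath, noise = noise_spec(cv = 0))
  mot <- generate_motoric(ath, noise_spec(cv = 0))
  pts <- select_fatigue_free_points(iso, list(mot))
  expect_lte(sum(pts$source == "acceleration"), 4)
  expect_gte(sum(pts$source == "acceleration"), 3)
  expect_lte(sum(pts$source == "motoric"), 3)
  expect_true(all(pts$cadence_rpm[pts$source == "motoric"] >= 160))
  # noise-free points lie exactly on the generating line
  expect_equal(pts$force_N, linear_force(ath$fv, pts$cadence_rpm),
               tolerance = 1e-9)
  expect_warning(select_fatigue_free_points(iso, list()), "motoric")
})

test_that("stroke-delay detection applies the sustained-decline rule", {
  p <- c(1200, 1250, 1290, 1300, 1295, 1280, 1270, 1255, 1240, 1250, 1230)
  tr <- make_trace(p, cadence_rpm = 135)
  expect_equal(detect_nd(tr, from = "start"), 4)   # index of the 1300 peak
  expect_error(detect_nd(make_trace(seq(1000, 1500, by = 50)), from = "start"),
               "not fatiguing")
  # invariant to adding a constant to all powers
  tr2 <- make_trace(p + 500)
  expect_equal(detect_nd(tr2, from = "start"), 4)
  # plateau then exact geometric decay: delay equals the last plateau stroke
  pl <- c(rep(1299, 5), 1299 * (1 - 0.0145)^(1:20))
  expect_equal(detect_nd(make_trace(pl), from = "start"), 5)
})

test_that("empirical decrement is the mean relative per-stroke loss", {
  tr <- make_trace(c(rep(1000, 2), 1000, 990, 980.1))
  d <- estimate_delta(tr, nd = 3, window_end_s = Inf)
  expect_equal(d$delta, 0.01)
  expect_equal(d$n_losses, 2)

  # exact geometric trace recovers the generating decrement to machine precision
  pl <- c(rep(1299, 5), 1299 * (1 - 0.0145)^(1:90))
  tr2 <- make_trace(pl)
  d2 <- estimate_delta(tr2, nd = 5, window_end_s = Inf)
  expect_equal(d2$delta, 0.0145, tolerance = 1e-12)
  expect_equal(d2$sd, 0, tolerance = 1e-12)
  dg <- estimate_delta(tr2, nd = 5, window_end_s = Inf, geometric = TRUE)
  expect_equal(dg$delta, 0.0145, tolerance = 1e-12)
  expect_error(estimate_delta(tr2, nd = 95, window_end_s = Inf), "fewer than 2")

  # short-window estimate on a time-decay trace sits at the expected scale
  ath <- reference_athlete()
  iso <- generate_sprint(ath, noise = noise_spec(cv = 0))
  nd <- detect_nd(iso)
  d15 <- estimate_delta(iso, nd, window_end_s = 15)
  expect_gt(d15$delta, 0.010)
  expect_lt(d15$delta, 0.020)
})

test_that("decrement optimisation is exact, optimal and scale-free", {
  pl <- c(rep(1299, 5), 1299 * (1 - 0.0145)^(1:90))
  tr <- make_trace(pl)
  opt <- optimize_delta(tr, nd = 5)
  expect_equal(opt$delta_opt, 0.0145, tolerance = 1e-6)
  expect_lt(opt$fit$rmse_W, 1e-4)
  # rescaling the powers leaves the optimal decrement unchanged
  opt2 <- optimize_delta(make_trace(3.7 * pl), nd = 5)
  expect_equal(opt2$delta_opt, opt$delta_opt, tolerance = 1e-8)

  # optimality against the empirical variants on a noisy trace
  ath <- reference_athlete()
  iso <- generate_sprint(ath, noise = noise_spec(cv = 0.03, seed = 11))
  cal <- quiet_calibrate(iso, list(generate_motoric(ath, noise_spec(0.03, seed = 12))))
  expect_lte(cal$pesa_opt$rmse_W, cal$pesa15$rmse_W + 1e-9)
  expect_lte(cal$pesa_opt$rmse_W, cal$pesa45$rmse_W + 1e-9)
})

test_that("constrained fit recovers the generating decay exactly without noise", {
  ath <- reference_athlete()
  iso <- generate_sprint(ath, noise = noise_spec(cv = 0))
  mot <- generate_motoric(ath, noise_spec(cv = 0))
  fv <- fit_linear_fv(select_fatigue_free_points(iso, list(mot)))$profile
  expect_equal(fv$fmax_N, 1207, tolerance = 1e-6)
  f <- fit_pasa(iso, fv)
  expect_equal(f$params$tau_s, 38, tolerance = 1e-3 / 38)
  expect_equal(f$params$cf_N, 483, tolerance = 1e-3 / 483)
  expect_equal(f$params$td_s, 2.55, tolerance = 1e-3 / 2.55)
  expect_lt(f$rmse_W, 1e-3)
  expect_false(f$pinned)
  expect_error(fit_pasa(make_trace(rep(1000, 8)), fv), "at least 10")
})

test_that("noisy single-athlete fit stays near the generating parameters", {
  ath <- reference_athlete()
  iso <- generate_sprint(ath, noise = noise_spec(cv = 0.03, seed = 101))
  mot <- generate_motoric(ath, noise_spec(0.03, seed = 102))
  fv <- fit_linear_fv(select_fatigue_free_points(iso, list(mot)))$profile
  f <- fit_pasa(iso, fv)
  expect_lt(abs(f$params$tau_s - 38), 6)
  expect_lt(abs(f$params$cf_N - 483), 50)
  expect_gt(f$r2, 0.97)
})

test_that("an optimum violating the amplitude ordering is pinned and flagged", {
  # truth asymptote above half the intercept: the constrained optimum must sit
  # on the C_F = Fmax/2 boundary
  fv <- ref_fv()
  truth <- pasa_params(fv, cf_N = 0.58 * 1207, tau_s = 20, td_s = 2.5,
                       check_amplitude = FALSE)
  t_s <- seq_len(95) * 60 / 135
  k <- 2 * pi * 0.17 / 60
  pw <- pasa_power(truth, crank_geometry(), 135, t_s)
  revs <- data.frame(index_n = seq_along(t_s), t_s = t_s, cadence_rpm = 135,
                     force_N = pw / (k * 135), power_W = pw)
  tr <- sprint_trace(revs, 135)
  f <- fit_pasa(tr, fv)
  expect_true(f$pinned)
  expect_equal(f$params$cf_N, 1207 / 2, tolerance = 1e-3)
})

test_that("single-athlete calibration reproduces the truth end to end", {
  ath <- reference_athlete()
  iso <- generate_sprint(ath, noise = noise_spec(cv = 0))
  mot <- lapply(1:2, function(i) generate_motoric(ath, noise_spec(cv = 0)))
  cal <- quiet_calibrate(iso, mot)
  row <- cal$row
  expect_equal(unname(row["Fmax"]), 1207, tolerance = 1e-6)
  expect_equal(unname(row["tauF"]), 38, tolerance = 1e-4)
  expect_equal(unname(row["CF"]), 483, tolerance = 1e-4)
  expect_equal(unname(row["TD"]), 2.55, tolerance = 1e-4)
  expect_equal(unname(row["PRopt"]), 133.22, tolerance = 1e-4)
  expect_equal(unname(row["R2"]), 1, tolerance = 1e-9)
  # the fit hierarchy holds on time-decay truth even without noise
  expect_lt(row["RMSE"], row["RMSE_PESAopt"])
  expect_lte(row["RMSE_PESAopt"], min(row["RMSE_PESA15"], row["RMSE_PESA45"]))
})
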
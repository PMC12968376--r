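test_that("athlete sampling is reproducible and respects the constraints", {
  a1 <- sample_athlete(seed = 5)
  a2 <- sample_athlete(seed = 5)
  expect_equal(a1$pasa$tau_s, a2$pasa$tau_s)
  expect_equal(a1$fv$fmax_N, a2$fv$fmax_N)

  set.seed(17)
  draws <- replicate(300, {
    a <- sample_athlete()
    c(a$pasa$af_N, a$pasa$cf_N, a$pasa$tau_s, a$pasa$td_s, a$fv$slope_a)
  })
  expect_true(all(draws[1, ] > draws[2, ]))   # A_F > C_F
  expect_true(all(draws[2, ] > 0))
  expect_true(all(draws[3, ] > 0 & draws[3, ] < 100))
  expect_true(all(draws[4, ] >= 0))
  expect_true(all(draws[5, ] < 0))
})

test_that("sampled time constants are centred on the cohort mean", {
  set.seed(123)
  taus <- replicate(1000, sample_athlete()$pasa$tau_s)
  expect_lt(abs(mean(taus) - 38), 1.5)
})

test_that("noise-free generation round-trips the governing model", {
  ath <- reference_athlete()
  tr <- generate_sprint(ath, noise = noise_spec(cv = 0))
  r <- tr$revolutions
  idx <- isokinetic_window(tr)
  # at-target revolutions carry exactly the time-based model power
  expect_equal(r$power_W[idx],
               pasa_power(ath$pasa, ath$geometry, 135, r$t_s[idx]),
               tolerance = 1e-12)
  # acceleration revolutions sit on the fatigue-free line
  acc <- setdiff(seq_len(nrow(r)), idx)
  expect_equal(r$force_N[acc], linear_force(ath$fv, r$cadence_rpm[acc]),
               tolerance = 1e-12)
  # a 45 s sprint at 135 rpm yields about a hundred revolutions
  expect_gte(nrow(r), 92)
  expect_lte(nrow(r), 102)
  expect_true(all(diff(r$t_s) > 0))

  # stroke-based truth decays geometrically at integer strokes
  trp <- generate_sprint(ath, noise = noise_spec(cv = 0), truth = "pesa")
  tp <- trp$meta$truth_params
  rp <- trp$revolutions
  idxp <- isokinetic_window(trp)
  expect_equal(rp$power_W[idxp], pesa_power_exp(tp, rp$index_n[idxp]),
               tolerance = 1e-12)
})

test_that("motoric sprints supply fatigue-free high-cadence points", {
  ath <- reference_athlete()
  m1 <- generate_motoric(ath, noise_spec(cv = 0, seed = 3))
  expect_gte(sum(m1$revolutions$cadence_rpm >= 160), 1)
  expect_equal(m1$revolutions$force_N,
               pmax(0, linear_force(ath$fv, m1$revolutions$cadence_rpm)),
               tolerance = 1e-12)
  m2 <- generate_motoric(ath, noise_spec(cv = 0.03, seed = 3))
  m3 <- generate_motoric(ath, noise_spec(cv = 0.03, seed = 3))
  expect_equal(m2$revolutions$power_W, m3$revolutions$power_W)
  expect_lte(max(m1$revolutions$t_s), 6 + 1e-9)
})

test_that("calibration recovers both truth families without noise", {
  ath <- sample_athlete(seed = 77, require_completion = TRUE)
  iso <- generate_sprint(ath, noise = noise_spec(cv = 0))
  mot <- lapply(1:2, function(i) generate_motoric(ath, noise_spec(cv = 0)))
  cal <- quiet_calibrate(iso, mot)
  expect_equal(unname(cal$row["tauF"]), ath$pasa$tau_s, tolerance = 1e-3)
  expect_equal(unname(cal$row["CF"]), ath$pasa$cf_N, tolerance = 1e-3)
  expect_equal(unname(cal$row["TD"]), ath$pasa$td_s, tolerance = 1e-3)
  expect_equal(unname(cal$row["Fmax"]), ath$fv$fmax_N, tolerance = 1e-6)

  isop <- generate_sprint(ath, noise = noise_spec(cv = 0), truth = "pesa")
  nd <- detect_nd(isop)
  d <- estimate_delta(isop, nd, Inf)
  expect_equal(d$delta, isop$meta$truth_params$delta, tolerance = 1e-9)
  opt <- optimize_delta(isop, nd)
  expect_equal(opt$delta_opt, isop$meta$truth_params$delta, tolerance = 1e-6)
  expect_lt(opt$fit$rmse_W, 1e-3)
})

test_that("fitted error scales with the noise level", {
  ath <- reference_athlete()
  rmse_at <- function(cv) {
    iso <- generate_sprint(ath, noise = noise_spec(cv = cv, seed = 500 + cv * 1000))
    mot <- generate_motoric(ath, noise_spec(cv, seed = 600 + cv * 1000))
    fv <- fit_linear_fv(select_fatigue_free_points(iso, list(mot)))$profile
    fit_pasa(iso, fv)$rmse_W
  }
  r <- vapply(c(0.01, 0.03, 0.06), rmse_at, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_gt(r[2] / r[1], 1.8)     # roughly linear growth in cv
  expect_lt(r[2] / r[1], 4.5)
  expect_gt(r[3] / r[2], 1.4)
  expect_lt(r[3] / r[2], 2.8)
})

test_that("cohort generation is deterministic and structured as the study", {
  coh <- generate_cohort(n = 12, seed = 42)
  expect_length(coh, 12)
  sexes <- vapply(coh, function(a) a$athlete$sex, character(1))
  expect_equal(sum(sexes == "female"), 6)
  expect_equal(sum(sexes == "male"), 6)
  expect_true(all(vapply(coh, function(a) length(a$motoric) == 2L, logical(1))))
  coh2 <- generate_cohort(n = 12, seed = 42)
  expect_equal(coh[[7]]$iso$revolutions$power_W,
               coh2[[7]]$iso$revolutions$power_W)
  coh3 <- generate_cohort(n = 12, seed = 43)
  expect_false(isTRUE(all.equal(coh[[1]]$iso$revolutions$power_W,
                                coh3[[1]]$iso$revolutions$power_W)))
})

test_that("the cohort pipeline reproduces the accuracy hierarchy", {
  coh <- generate_cohort(n = 12, seed = 3)
  cal <- suppressWarnings(calibrate_cohort(coh))
  tab <- cal$table
  expect_lt(mean(tab$RMSE), mean(tab$RMSE_PESA15))
  expect_lt(mean(tab$RMSE), mean(tab$RMSE_PESA45))
  expect_lte(mean(tab$RMSE_PESAopt), mean(tab$RMSE_PESA15))
  expect_gt(mean(tab$R2), 0.97)
  # decrement estimates land at the observed scale (~1.5%)
  expect_gt(mean(tab$Delta15), 0.008)
  expect_lt(mean(tab$Delta15), 0.025)
  rep_tab <- report_table(tab)
  expect_true(all(c("parameter", "mean", "ci_lower", "ci_upper", "sd")
                  %in% names(rep_tab)))
  cmp <- compare_models(tab)
  expect_s3_class(cmp$rmse_anova, "test_result")
  expect_equal(nrow(cmp$posthoc), 3)
  expect_true(all(cmp$posthoc$p_adj >= cmp$posthoc$p - 1e-12))
  expect_false(is.null(cmp$sex_contrasts))
})
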
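test_that("summary-based t-test reproduces the printed sex contrasts", {
  male <- group_summary(6, 845, 178)
  female <- group_summary(6, 573, 89)
  res <- independent_t(male, female)
  expect_equal(res$df, 10)
  expect_equal(res$statistic, 3.35, tolerance = 0.01)   # printed 3.34 from raw data
  expect_lt(res$p_value, 0.01)
  same <- independent_t(group_summary(6, 500, 50), group_summary(6, 500, 50))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(independent_t(group_summary(3, 1, 0), group_summary(3, 2, 0)),
               "zero variance")
})

test_that("summary-based t-tests agree with t.test on raw data", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(7, 10, 3); y <- rnorm(9, 12, 5)
    gx <- group_summary(7, mean(x), sd(x))
    gy <- group_summary(9, mean(y), sd(y))
    pooled <- independent_t(gx, gy)
    oracle_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$statistic, unname(oracle_p$statistic), tolerance = 1e-8)
    expect_equal(pooled$p_value, oracle_p$p.value, tolerance = 1e-8)
    welch <- independent_t(gx, gy, welch = TRUE)
    oracle_w <- t.test(x, y)
    expect_equal(welch$statistic, unname(oracle_w$statistic), tolerance = 1e-8)
    expect_equal(welch$df, unname(oracle_w$parameter), tolerance = 1e-8)
    # Satterthwaite df never exceeds the pooled df
    expect_lte(welch$df, pooled$df + 1e-9)
  }
})

test_that("Hedges g reproduces the printed effect sizes", {
  expect_equal(hedges_g(group_summary(6, 845, 178), group_summary(6, 573, 89)),
               1.78, tolerance = 0.005 / 1.78)
  expect_equal(hedges_g(group_summary(6, 1648, 391), group_summary(6, 1141, 229)),
               1.46, tolerance = 0.005 / 1.46)
  expect_equal(hedges_g(group_summary(5, 10, 2), group_summary(5, 10, 2)), 0)
  # the small-sample correction vanishes as n grows
  d_uncorr <- (11 - 10) / sqrt((2^2 + 2^2) / 2)
  g_big <- hedges_g(group_summary(5000, 11, 2), group_summary(5000, 10, 2))
  expect_equal(g_big, d_uncorr, tolerance = 1e-3)
  expect_error(hedges_g(group_summary(3, 1, 0), group_summary(3, 1, 0)),
               "pooled SD")
})

test_that("paired t matches the closed formula and t.test", {
  set.seed(55)
  x <- rnorm(12, 50, 10)
  y <- x - rnorm(12, 5, 3)
  res <- paired_t(x, y)
  d <- x - y
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(12)), tolerance = 1e-12)
  oracle <- t.test(x, y, paired = TRUE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-8)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-8)
  expect_equal(res$effect_size, mean(d) / sd(d), tolerance = 1e-12)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, x + 3), "zero variance")
})

test_that("Pitman-Morgan detects unequal correlated variances", {
  set.seed(8)
  x <- rnorm(10, 0, 2)
  y <- rev(x) + 100          # equal variances exactly, imperfect correlation
  res <- pitman_morgan(x, y)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$df, 8)
  # sign convention: larger second variance gives a negative statistic
  y2 <- 2 * x + rnorm(10, 0, 0.3)
  expect_lt(pitman_morgan(x, y2)$statistic, 0)
  expect_error(pitman_morgan(x, 2 * x), "undefined")

  # power: variance ratio 2 at n = 12, pair correlation 0.7 (typical for
  # repeated measures), rejects in most replicates
  set.seed(13)
  rej <- mean(replicate(1000, {
    z1 <- rnorm(12); z2 <- 0.7 * z1 + sqrt(1 - 0.49) * rnorm(12)
    pitman_morgan(2 * z1, z2)$p_value < 0.05
  }))
  expect_gte(rej, 0.8)
})

test_that("repeated-measures ANOVA matches a sums-of-squares oracle", {
  set.seed(21)
  n <- 12; k <- 3
  subj <- rnorm(n, 0, 5)
  eff <- c(0, 3, 7)
  y <- outer(subj, rep(1, k)) + outer(rep(1, n), eff) + matrix(rnorm(n * k, 0, 2), n)
  res <- rm_anova_gg(y)

  # oracle 1: aov with an explicit within-subject error stratum
  df <- data.frame(y = as.vector(y),
                   cond = factor(rep(seq_len(k), each = n)),
                   subj = factor(rep(seq_len(n), k)))
  av <- summary(aov(y ~ cond + Error(subj / cond), data = df))
  f_oracle <- av[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res$statistic, f_oracle, tolerance = 1e-8)

  # oracle 2: epsilon from an orthonormal contrast of the covariance matrix
  ctr <- stats::contr.helmert(k)
  ctr <- sweep(ctr, 2, sqrt(colSums(ctr^2)), "/")
  m <- t(ctr) %*% stats::cov(y) %*% ctr
  eps_oracle <- sum(diag(m))^2 / ((k - 1) * sum(m^2))
  expect_equal(res$epsilon, eps_oracle, tolerance = 1e-8)
  expect_equal(res$df, res$uncorrected_df * res$epsilon, tolerance = 1e-12)
  expect_equal(res$p_value,
               pf(res$statistic, res$df[1], res$df[2], lower.tail = FALSE),
               tolerance = 1e-12)

  # forcing sphericity reproduces the uncorrected test
  un <- rm_anova_gg(y, gg = FALSE)
  expect_equal(un$epsilon, 1)
  expect_equal(un$df, c(k - 1, (k - 1) * (n - 1)))
  expect_equal(un$statistic, res$statistic)

  # degenerate inputs
  flat <- outer(rnorm(5), rep(1, 3))
  r0 <- rm_anova_gg(flat)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect_size, 0)
  two <- rm_anova_gg(matrix(rnorm(20), 10, 2))
  expect_equal(two$epsilon, 1)   # sphericity holds trivially for 2 conditions
  expect_error(rm_anova_gg(matrix(c(1, NA, 3, 4), 2)), "complete")
})

test_that("Bonferroni adjustment caps and preserves order", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1)
  p <- c(0.001, 0.04, 0.2, 0.9)
  adj <- bonferroni(p)
  expect_equal(order(adj), order(p))
  expect_equal(adj, p.adjust(p, "bonferroni"), tolerance = 1e-12)
})
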
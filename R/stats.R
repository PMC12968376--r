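#' Group summary
#'
#' Sample size, mean and SD of one group, the inputs to the summary-based
#' tests (printed group summaries are sufficient statistics for them).
#'
#' @param n Sample size, >= 2.
#' @param mean Group mean.
#' @param sd Group SD, >= 0.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

test_result <- function(statistic, df, p_value, effect_size = NA_real_,
                        effect_size_kind = NA_character_, test = "") {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test = test, statistic = statistic, df = df, p_value = p_value,
                 effect_size = effect_size, effect_size_kind = effect_size_kind),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df <- if (length(x$df) == 2L) sprintf("(%.2f, %.2f)", x$df[1], x$df[2]) else
    sprintf("(%.2f)", x$df)
  cat(sprintf("%s: statistic %.3f, df %s, p = %.4g", x$test, x$statistic, df,
              x$p_value))
  if (!is.na(x$effect_size)) {
    cat(sprintf(", %s = %.3f", x$effect_size_kind, x$effect_size))
  }
  cat("\n")
  invisible(x)
}

pooled_sd <- function(g1, g2) {
  df <- g1$n + g2$n - 2
  sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df)
}

#' Independent-samples t-test from group summaries
#'
#' Two-sided pooled-variance Student t (df = n1 + n2 - 2) or Welch t with
#' Welch-Satterthwaite df, computed from (n, mean, sd) summaries. Effect size
#' is Hedges' g (see [hedges_g()]).
#'
#' @param g1,g2 [group_summary()] objects.
#' @param welch Apply Welch's correction for unequal variances.
#' @return A `test_result`.
#' @export
independent_t <- function(g1, g2, welch = FALSE) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  if (g1$sd == 0 && g2$sd == 0) stop("zero variance in both groups", call. = FALSE)
  v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
  if (welch) {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  } else {
    df <- g1$n + g2$n - 2
    se <- pooled_sd(g1, g2) * sqrt(1 / g1$n + 1 / g2$n)
  }
  t <- (g1$mean - g2$mean) / se
  test_result(t, df, 2 * stats::pt(-abs(t), df),
              effect_size = hedges_g(g1, g2), effect_size_kind = "hedges_g",
              test = if (welch) "Welch t" else "Student t")
}

#' Hedges' g from group summaries
#'
#' Bias-corrected standardised mean difference:
#' `g = J * (m1 - m2) / s_pooled` with `J = 1 - 3/(4 df - 1)`,
#' `df = n1 + n2 - 2`.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return Effect size g.
#' @export
hedges_g <- function(g1, g2) {
  sp <- pooled_sd(g1, g2)
  if (sp == 0) stop("zero pooled SD", call. = FALSE)
  df <- g1$n + g2$n - 2
  (1 - 3 / (4 * df - 1)) * (g1$mean - g2$mean) / sp
}

#' Paired t-test with Cohen's d
#'
#' Two-sided t on the paired differences (df = n - 1), with
#' `d = mean(diff) / sd(diff)`.
#'
#' @param x,y Paired samples of equal length >= 2.
#' @return A `test_result`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of the paired differences", call. = FALSE)
  n <- length(d)
  t <- mean(d) / (sdd / sqrt(n))
  test_result(t, n - 1, 2 * stats::pt(-abs(t), n - 1),
              effect_size = mean(d) / sdd, effect_size_kind = "cohens_d",
              test = "paired t")
}

#' Pitman-Morgan test for equality of correlated variances
#'
#' Tests whether two paired samples have equal variances:
#' `t = (s1^2 - s2^2) sqrt(n - 2) / (2 s1 s2 sqrt(1 - r^2))` with `r` the
#' sample correlation, df = n - 2. The sign follows `s1^2 - s2^2`.
#'
#' @param x,y Paired samples of equal length >= 3.
#' @return A `test_result`.
#' @export
pitman_morgan <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) stop("|r| = 1: test undefined", call. = FALSE)
  s1 <- stats::sd(x); s2 <- stats::sd(y)
  t <- (s1^2 - s2^2) * sqrt(n - 2) / (2 * s1 * s2 * sqrt(1 - r^2))
  test_result(t, n - 2, 2 * stats::pt(-abs(t), n - 2), test = "Pitman-Morgan")
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F test on a complete subjects x conditions matrix, with the
#' Greenhouse-Geisser epsilon computed from the double-centred condition
#' covariance matrix, GG-adjusted degrees of freedom and p-value, and partial
#' eta squared `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Numeric matrix, rows = subjects (>= 3), columns = conditions
#'   (>= 2), no missing values.
#' @param gg Apply the Greenhouse-Geisser correction (set `FALSE` for the
#'   uncorrected RM-ANOVA).
#' @return A `test_result` with `df = c(df1, df2)` (possibly fractional) and
#'   extra fields `epsilon`, `F`, `uncorrected_df`.
#' @export
rm_anova_gg <- function(data, gg = TRUE) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("matrix must be complete", call. = FALSE)
  n <- nrow(data); k <- ncol(data)
  stopifnot(n >= 3, k >= 2)
  grand <- mean(data)
  cond_means <- colMeans(data)
  subj_means <- rowMeans(data)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((data - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- if (ss_cond <= 1e-12 * max(ss_tot, 1)) 0 else
    (ss_cond / df1) / (ss_err / df2)

  # GG epsilon from the double-centred covariance of conditions
  s <- stats::cov(data)
  sc <- sweep(sweep(s, 1, rowMeans(s)), 2, colMeans(s)) + mean(s)
  eps <- if (sum(sc^2) <= 1e-300) 1 else sum(diag(sc))^2 / ((k - 1) * sum(sc^2))
  if (!gg) eps <- 1
  eps <- min(max(eps, 1 / (k - 1)), 1)
  adj <- c(df1, df2) * eps
  eta <- if (ss_cond + ss_err <= 0) 0 else ss_cond / (ss_cond + ss_err)
  res <- test_result(f, adj,
                     p_value = stats::pf(f, adj[1], adj[2], lower.tail = FALSE),
                     effect_size = eta,
                     effect_size_kind = "partial_eta_sq",
                     test = if (gg) "RM-ANOVA (GG)" else "RM-ANOVA")
  res$epsilon <- eps
  res$uncorrected_df <- c(df1, df2)
  res
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise; `m` defaults to the number of p-values and
#' must be at least that.
#'
#' @param p_values Vector of p-values.
#' @param m Number of comparisons.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(m >= length(p_values))
  pmin(1, p_values * m)
}
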
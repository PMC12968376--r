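#!/usr/bin/env Rscript
# Model-comparison statistics across the cohort: GG-corrected repeated-measures
# ANOVA of RMSE across PASA/PESA15/PESA45, Bonferroni-corrected paired post
# hocs with Cohen's d, the PASA-vs-optimised contrast, the short- vs
# full-window decrement comparison (paired t + Pitman-Morgan variances), and
# summary-based sex contrasts with Hedges' g.

library(sprintfatigue)

tab <- read.csv(file.path("results", "fit_table.csv"))
cmp <- compare_models(tab)

fmt <- function(tr) {
  sprintf("statistic %.3f, df %s, p = %.4g%s", tr$statistic,
          paste(round(tr$df, 2), collapse = ", "), tr$p_value,
          if (!is.na(tr$effect_size))
            sprintf(", %s = %.2f", tr$effect_size_kind, tr$effect_size) else "")
}

cat("RMSE across model variants (RM-ANOVA, GG-corrected):\n  ",
    fmt(cmp$rmse_anova), "\n")
cat("Post hoc paired contrasts (Bonferroni-adjusted):\n")
print(cmp$posthoc, digits = 3)
cat("PASA vs optimised-decrement variant: ", fmt(cmp$opt_vs_pasa), "\n")
cat("Delta15 vs Delta45 (paired t):       ", fmt(cmp$delta_paired), "\n")
cat("Delta15 vs Delta45 variances (P-M):  ", fmt(cmp$delta_variance), "\n")

rows <- list(
  data.frame(test = "rmse_rm_anova_gg", statistic = cmp$rmse_anova$statistic,
             df1 = cmp$rmse_anova$df[1], df2 = cmp$rmse_anova$df[2],
             p = cmp$rmse_anova$p_value, effect = cmp$rmse_anova$effect_size,
             effect_kind = cmp$rmse_anova$effect_size_kind),
  data.frame(test = paste0("posthoc_", gsub(" ", "", cmp$posthoc$contrast)),
             statistic = cmp$posthoc$t, df1 = cmp$posthoc$df, df2 = NA,
             p = cmp$posthoc$p_adj, effect = cmp$posthoc$cohens_d,
             effect_kind = "cohens_d"),
  data.frame(test = c("pasa_vs_pesaopt", "delta15_vs_delta45",
                      "delta_variances_pitman"),
             statistic = c(cmp$opt_vs_pasa$statistic,
                           cmp$delta_paired$statistic,
                           cmp$delta_variance$statistic),
             df1 = c(cmp$opt_vs_pasa$df, cmp$delta_paired$df,
                     cmp$delta_variance$df),
             df2 = NA,
             p = c(cmp$opt_vs_pasa$p_value, cmp$delta_paired$p_value,
                   cmp$delta_variance$p_value),
             effect = c(cmp$opt_vs_pasa$effect_size,
                        cmp$delta_paired$effect_size, NA),
             effect_kind = c("cohens_d", "cohens_d", NA))
)
write.csv(do.call(rbind, rows), file.path("results", "model_comparison.csv"),
          row.names = FALSE)
if (!is.null(cmp$sex_contrasts)) {
  write.csv(cmp$sex_contrasts, file.path("results", "sex_contrasts.csv"),
            row.names = FALSE)
  cat("Sex contrasts written (largest |g|: ",
      cmp$sex_contrasts$parameter[which.max(abs(cmp$sex_contrasts$hedges_g))],
      ")\n", sep = "")
}
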
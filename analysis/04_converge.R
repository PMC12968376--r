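#!/usr/bin/env Rscript
# Where do the two decay laws agree? Convergence/divergence analysis at the
# cohort-mean parameters: a cadence x time divergence map with the 5% relative
# error corridor, regressions of stroke-based on time-based predictions at
# four cadences, and mean absolute differences per sprint phase.

library(sprintfatigue)

fv <- linear_fv_profile(-4.53, 1207)
pasa <- pasa_params(fv, cf_N = 483, tau_s = 38, td_s = 2.55)
pesa <- pesa_from_pasa(pasa, delta = 0.0145)
geom <- crank_geometry()

map <- divergence_map(pasa, pesa, geom,
                      cadence_grid_rpm = seq(60, 180, by = 5),
                      time_grid_s = seq(0, 60, by = 0.5), eps = 0.05)
dir.create("results", showWarnings = FALSE)
write.csv(map, file.path("results", "convergence_map.csv"), row.names = FALSE)
cat(sprintf("Corridor (<5%% relative difference) covers %.1f%% of the 60-180 rpm x 0-60 s grid\n",
            100 * mean(map$in_corridor)))

regs <- do.call(rbind, lapply(c(90, 110, 135, 170), function(cad) {
  r <- regress_predictions(pasa, pesa, geom, cad, seq(0, 45, by = 0.5))
  data.frame(cadence_rpm = cad, slope = r$slope, intercept_W = r$intercept_W,
             r2 = r$r2)
}))
write.csv(regs, file.path("results", "prediction_regressions.csv"),
          row.names = FALSE)
cat("Stroke-based on time-based prediction regressions:\n")
print(regs, digits = 3)

phases <- list(c(0, 15), c(15, 30), c(30, 45), c(40, 45))
pd <- phase_differences(pasa, pesa, geom, 135, phases)
pd_tab <- data.frame(t_start = sapply(phases, `[`, 1),
                     t_end = sapply(phases, `[`, 2), mean_abs_diff_W = pd)
write.csv(pd_tab, file.path("results", "phase_differences.csv"),
          row.names = FALSE)
cat("Mean |difference| at 135 rpm per phase [W]:\n")
print(pd_tab, digits = 3)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(map, aes(t_s, cadence_rpm, fill = pmin(rel_err, 0.5))) +
    geom_raster() +
    geom_contour(data = map, aes(t_s, cadence_rpm, z = rel_err),
                 breaks = 0.05, colour = "white", inherit.aes = FALSE) +
    scale_fill_viridis_c(name = "relative\ndifference") +
    labs(x = "time [s]", y = "cadence [rpm]",
         title = "Divergence of stroke-based from time-based predictions",
         subtitle = "white contour: 5% corridor boundary")
  ggsave(file.path("results", "convergence_map.png"), p,
         width = 7, height = 4.5, dpi = 150)
}
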
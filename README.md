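# sprintfatigue

Power output during a maximal cycling sprint collapses by more than half
within 45 seconds. Two deterministic models of this neuromuscular fatigue are
in routine use in performance diagnostics, and they disagree about what drives
the decline:

* **PASA** (parallel-shift approach) — *time-based*. The linear
  force–velocity profile of maximal cycling, `F(PR) = a·PR + Fmax` with power
  `P = F · 2πr · PR`, shifts downward in parallel: only the intercept decays,
  `Fmax(t) = (Fmax − C_F)·exp(−(t − TD)/τ_F) + C_F`, toward a residual force
  asymptote `C_F` (a sustainable floor in the spirit of the critical-power
  framework), after a fatigue-free delay `TD`.
* **PESA** (pedal-stroke-based approach) — *stroke-based*. Peak power loses a
  constant relative fraction per completed maximal contraction:
  `P(n) = Ppeak · (1 − Δ)^max(0, n − ND)` after a stroke delay `ND`. (The
  original linear form `Ppeak·(1 − Δ·(n − ND))` goes negative near
  `n = ND + 1/Δ` and is retained only to demonstrate that pathology.)

The two views are linked by the stroke–time conversion `n(t) = ∫ PR dt`: at
constant cadence, an intercept time constant `τ_F` and a per-stroke decrement
`ΔFmax = 1 − exp(−1/(PR·τ_F))` describe identical decay, with congruence at
`τ ≈ 1/(PR·ln(1/(1−Δ)))`. For *power*, the models coincide only near that
single congruent cadence and early in the sprint, because PASA shifts the F–v
line (carrying the `a·PR` offset) while PESA rescales power wholesale.

The package is written for sport scientists and performance modellers. It
provides, as testable units: fatigue-free force–velocity profiling (linear,
and Hill-hyperbola with its cubic power–velocity approximation), both fatigue
models with all cross-representation conversions, the full calibration chain
(fatigue-free point selection, bounded nonlinear least squares for PASA,
sustained-decline stroke-delay detection, empirical Δ over 15 s/45 s windows
and RMSE-optimal Δ for PESA), convergence/divergence analysis across cadence
and time (ε-corridor maps, prediction regressions, phase differences), the
model-comparison statistics (summary t-tests with Hedges' g, paired t with
Cohen's d, Pitman–Morgan, GG-corrected repeated-measures ANOVA, Bonferroni),
and a seeded synthetic-cohort generator reproducing the study conditions
(45 s isokinetic sprints at 135 rpm with multiplicative stroke noise) so the
whole pipeline runs without laboratory data.

## Worked example

Calibrate one synthetic athlete (truth: a time-based parallel shift with
τ_F = 44.9 s, C_F = 550 N, TD = 2.76 s; 3% stroke-to-stroke noise):

```r
library(sprintfatigue)

athlete <- sample_athlete(seed = 42, sex = "male", require_completion = TRUE)
iso     <- generate_sprint(athlete, noise = noise_spec(cv = 0.03, seed = 7))
motoric <- lapply(8:9, function(s) generate_motoric(athlete, noise_spec(0.03, seed = s)))

iso
#> Sprint trace (isokinetic_45s): 98 revolutions over 44.7 s, target 135 rpm
#>   peak power 2105 W, final power 561 W

cal <- calibrate_athlete(iso, motoric)
cal$pasa$params
#> PASA: Fmax 1655.4 N, A_F 1003.7 N, C_F 651.7 N, tau_F 40.49 s, TD 3.46 s, a -5.695 N/rpm
cal$pasa; cal$pesa45; cal$pesa_opt
#> PASA fit: RMSE 38.5 W, R2 0.9926 (n = 94)
#> PESA45 fit: RMSE 45.0 W, R2 0.9899 (n = 94)
#> PESAopt fit: RMSE 44.8 W, R2 0.9900 (n = 94)
```

The fitted decay recovers the generating parameters to within the noise
(τ̂_F = 40.5 s vs 44.9 s, Ĉ_F = 652 N vs 550 N from a single 45 s trace), the
time-based model scores the lowest error on its own truth, and the
stroke-based decrement lands at the familiar ~1.5%/stroke scale
(Δ̂₁₅ = 1.56%, Δ̂₄₅ = 1.43%, Δ̂_opt = 1.42%, N̂D = 10 strokes). Where the two
models agree is a property of cadence and time, not of the athlete:

```r
pasa <- cal$pasa$params
pesa <- pesa_from_pasa(pasa, delta = cal$pesa_opt$params$delta)
regress_predictions(pasa, pesa, crank_geometry(), 90)$slope    # ~1: interchangeable
regress_predictions(pasa, pesa, crank_geometry(), 170)$slope   # < 0.8: diverged
divergence_map(pasa, pesa)                                     # ε-corridor over 60–180 rpm × 0–60 s
```

## Analysis workflow

The `analysis/` scripts run the whole study pipeline on synthetic data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # 12-athlete cohort -> per-revolution trace CSVs + truth sidecar
Rscript analysis/02_fit.R        # calibration of all model variants -> fit_table.csv, parameter_summary.csv
Rscript analysis/03_compare.R    # RM-ANOVA, post hocs, Pitman-Morgan, sex contrasts -> model_comparison.csv
Rscript analysis/04_converge.R   # divergence map, regressions, phase differences (+ heatmap PNG)
Rscript analysis/05_report.R     # cohort table (mean, 95% CI, SD) and recovery check
```

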
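---
title: "Time-based and stroke-based fatigue models for maximal sprint cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-based and stroke-based fatigue models for maximal sprint cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintfatigue)
```

## The two models

During a maximal cycling sprint, power output declines steeply after a short
fatigue-free period. Two deterministic descriptions of this decline are in
common use, and this package implements, calibrates and compares both.

**The parallel-shift approach (PASA)** starts from the empirical observation
that in maximal multi-joint cycling the relation between mean pedal force
$F$ and pedalling rate $PR$ is linear,

$$F(PR) = a\,PR + F_{max}, \qquad P(PR) = F(PR)\cdot 2\pi r\, PR,$$

with slope $a < 0$ (N·rpm$^{-1}$), intercept $F_{max}$ (N) and crank length
$r$ (m). Fatigue is a parallel downward translation of this line: only the
intercept decays, exponentially in *time*, toward a residual asymptote,

$$F_{max}(t) = (F_{max} - C_F)\, e^{-\max(0,\,t - TD)/\tau_F} + C_F ,$$

with amplitude $A_F = F_{max} - C_F$, asymptote $C_F > 0$, time constant
$\tau_F$ and a fatigue-free delay $TD$. The asymptote is the model's
physiological anchor: a sustainable force floor in the spirit of the
critical-power framework.

**The stroke-based approach (PESA)** instead counts maximal contractions.
After a stroke delay $ND$, peak power loses a constant relative fraction
$\Delta$ per completed pedal stroke $n$:

$$P(n) = P_{peak}\,(1-\Delta)^{\max(0,\,n-ND)} .$$

The original formulation was linear in $n$
($P_{peak}(1 - \Delta\,\max(0, n-ND))$) and inevitably crosses zero near
$n = ND + 1/\Delta$; the exponential reformulation keeps the stroke-based
scaling principle while staying positive. Both forms are implemented
(`pesa_power_linear()`, `pesa_power_exp()`); all analyses use the exponential
form.

The bridge between the two representations is the stroke-time conversion
$n(t) = \int_0^t PR(t')\,dt'$ (`strokes_at_time()`, trapezoidal, exact for
piecewise-linear cadence), with $ND = \lfloor n(TD)\rfloor$. At constant
cadence the stroke-based form of the PASA intercept decay with per-stroke
decrement $\Delta F_{max} = 1 - e^{-1/(PR\,\tau_F)}$ is *algebraically
identical* to the time-based form at every stroke boundary; this identity is
the core oracle of the test suite. Inverting it gives the congruence time
constant $\tau \approx 1/(PR \ln\frac{1}{1-\Delta})$ at which a per-stroke
decrement and a time constant describe the same decay.

Congruence of the *intercepts* is not congruence of *power*: PASA shifts the
F-v line, so its power ratio at cadence $PR$ carries the offset $a\,PR$, while
PESA scales the whole power. The two predictions therefore agree closely only
at moderate cadences and early times, and the `convergence` functions map
exactly where: `divergence_map()` computes cadence-by-time relative
differences with a 5% corridor mask, `regress_predictions()` the
prediction-on-prediction regressions at fixed cadences, and
`phase_differences()` the mean absolute differences per sprint phase. At the
reference parameter means the corridor deviation at the congruent cadence
(~104–108 rpm for printed decrements of 1.45–1.51%) stays below 1% over the
first 15 s, while at 135 rpm and above the offset term pushes deviations
beyond the corridor — which is why the convergence zone sits at moderate
cadences.

## Units and conventions

* Cadence is rev/s internally wherever strokes and time are mixed (the
  stroke-time conversions are only dimensionally consistent in rev/s); rpm
  appears at all interfaces, conversion factor 1/60.
* Crank length defaults to 0.17 m (standard track crank; the reference
  $P_{max}$/$F_{max}$ values are consistent with ≈0.17 m). Configurable via
  `crank_geometry()`.
* Forces above the momentary zero-force cadence are returned negative, not
  clamped, keeping the algebra exact for the convergence analysis; only the
  synthetic generator clamps observed power at zero.
* Per-revolution time stamps are end-of-revolution times (cumulative sum of
  revolution durations); stroke indices are 1-based completed-stroke counts.
  The model equations are evaluated at these stamps.

## Calibration

`calibrate_athlete()` reproduces the study's estimation chain:

1. **Fatigue-free profile.** The first 3–4 acceleration revolutions (< 3 s)
   of the isokinetic sprint plus up to 3 of the highest-power revolutions at
   ≥ 160 rpm from the motoric sprints, combined in one OLS line
   (`select_fatigue_free_points()`, `fit_linear_fv()`).
2. **PASA.** Bounded nonlinear least squares on per-revolution power
   (Levenberg–Marquardt with box constraints, `minpack.lm::nls.lm`) under
   $A_F > C_F > 0$, $0 < \tau_F < 100$ s, $TD \ge 0$. By default $F_{max}$ is
   fixed to the fatigue-free intercept, so the free parameters are
   $(C_F, \tau_F, TD)$ and the ordering constraint becomes the bound
   $C_F \le F_{max}/2$; `refit_fmax = TRUE` frees all four with the ordering
   enforced through a non-negative gap $A_F - C_F$ whose active lower bound
   is reported as `pinned`. Initial values: $\tau_0 = 30$ s,
   $C_{F,0} = 0.4\,F_{max}$, $TD_0$ at the peak-power time; up to five
   deterministically jittered restarts on non-convergence.
3. **PESA.** The stroke delay is the last stroke preceding a sustained
   decline — the first stroke followed by five consecutive strokes with
   strictly monotonically decreasing power (`detect_nd()`, scanning from
   target-cadence attainment; ties break the run, tolerance configurable,
   default 0 W). The decrement is the arithmetic mean of the relative
   per-stroke losses $1 - P(i{+}1)/P(i)$ after the delay, over the first 15 s
   and over the full sprint (`estimate_delta()`; a geometric-mean variant is
   available behind a flag, different only at second order at the ~1.5%
   scale). Peak power is the maximum observed at-target revolution power.
   `optimize_delta()` additionally treats $\Delta$ as a free parameter
   (bounded 1-D minimisation of RMSE on (0, 0.2], delay held constant).
4. **Scoring.** All variants are scored on the same at-target window
   (RMSE and $R^2$ per variant), so their errors are directly comparable.

Two numerical choices deserve a note. First, the strict five-stroke rule is
fragile under independent stroke-to-stroke noise: a 3% CV delays or even
suppresses the first strictly monotone run, although fatigue onset is clearly
earlier. Since a sustained decline cannot begin after the maximum observed
power, the pipeline caps the detected delay at the peak-power stroke; on
noise-free traces the rule itself already returns that stroke. Second,
relative per-stroke losses are undefined where the clamped observed power is
zero; such pairs are dropped from the decrement estimate.

## What the synthetic generator emulates

No raw traces are publicly deposited, so the generator produces the study's
conditions from published summary distributions:

* **Protocol** (`protocol_spec()`): 45 s isokinetic sprint at 135 rpm,
  stationary start, acceleration over one revolution each at 35/68/88/97% of
  target (reaching target by ≈2.9 s, three revolutions inside 3 s), then
  constant-cadence revolutions to 45 s — about 98 revolutions in total. Two
  6 s motoric sprints supply fatigue-free points at ≥ 160 rpm.
* **Athletes** (`sample_athlete()`): truncated-normal draws of
  $(F_{max}, a, C_F, \tau_F, TD)$ at the published cohort means/SDs (pooled
  or sex-specific), independently per parameter (no correlation structure is
  published), resampled until the calibration constraint chain holds plus a
  plausibility window of 100–160 rpm on the optimal cadence.
  `generate_cohort()` additionally applies a recruitment filter — the
  modelled end-of-sprint force at target cadence must stay positive (> 25 N)
  — because every study participant completed the sprint with substantial
  power; without it, low-$\tau_F$/low-$C_F$ draws collapse onto the zero
  clamp mid-sprint, which the study cohort did not do. The filter lives in
  cohort recruitment, not in the sampler, so the marginal parameter
  distributions stay unbiased.
* **Traces** (`generate_sprint()`): acceleration revolutions carry the
  fatigue-free line; at-target revolutions carry the truth model — time-based
  PASA at the revolution's end time, or exponential PESA at its stroke count
  (with the PESA truth derived from the PASA truth via the per-stroke
  decrement at the protocol cadence, keeping the two families comparable).
  Every revolution's power is multiplied by independent lognormal noise with
  mean 1 and CV 3% (the scale of the observed per-stroke loss SDs); an
  optional linear CV growth emulates the larger late-sprint variability, off
  by default. All randomness flows from one master seed through recorded
  sub-seeds.

What passing tests on these data do **not** show about real data: the noise
is independent across strokes (real stroke-to-stroke variability is partly
smooth and grows with fatigue), the truth is exactly one of the two models
(real sprints are neither), parameters are drawn independently (real
$F_{max}$ and $\tau_F$ may covary), and cadence is exactly constant after the
ramp. In particular, fitting PASA-truth data charges the full structural
distance between the model families to the stroke-based variants, so their
error advantage over the optimised variant is larger here than on real
traces, where both fitted models approximate the same empirical curve.

## Statistics

The model-comparison battery (`compare_models()`) is authored from the
formulas and cross-checked against independent oracles in the tests:
summary-based pooled/Welch t-tests with Hedges' g
($g = J\,(m_1-m_2)/s_{pooled}$, $J = 1 - 3/(4\,df-1)$), paired t with
Cohen's d on differences, the Pitman–Morgan test for correlated variances
($t = (s_1^2 - s_2^2)\sqrt{n-2}\,/\,2 s_1 s_2\sqrt{1-r^2}$, $df = n-2$), and
the one-way repeated-measures ANOVA with Greenhouse–Geisser correction
(epsilon from the double-centred condition covariance matrix, partial
$\eta^2$ as effect size) plus Bonferroni-corrected post hocs. P-values are
two-sided, $\alpha = 0.05$. The two-factor mixed (model × sex) interaction is
deliberately out of scope; sex enters through independent-sample contrasts.
Normality/homogeneity pre-tests are not re-implemented (standard tests, hooks
only). Degrees of freedom are always reported as computed from the data at
hand.

## Problem sizes

The test suite and the analysis scripts run at the study's own scale: cohorts
of 12 athletes (≈98 revolutions per sprint), 100 seeded replicates for the
recovery checks, 1000–2000 replicates for power/type-I checks of the
variance test, and dense grids (τ × cadence, 20 × 11) for the stroke-time
duality oracle. A full `devtools::test()` run takes a few seconds; the
acceptance script a few seconds more.

## Known limitations

* $\Delta$ is treated as cadence-invariant, per the model definition; the
  convergence module is precisely the tool that exposes how strongly this
  assumption diverges from the time-based view at high cadence.
* The truncated-cubic power-velocity profile obtained from the Hill
  hyperbola has its third-order coefficient positive, so it is monotone
  (peakless) unless the hyperbola's curvature is low ($c > 2 F_{max}$); it is
  a near-origin approximation and is not used as the default substrate of the
  convergence maps, which share the fatigue-free linear power curve between
  models instead (no Hill constants are published for the cohort).
* The optimised decrement is an upper bound of stroke-based performance under
  ideal calibration, not a deployable diagnostic: it requires the full sprint
  it is meant to predict.
* Cadence trajectories are inputs; there is no crank-dynamics simulation and
  no within-revolution (torque-angle) modelling.
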
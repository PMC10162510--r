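---
title: "Predicting Wingate anaerobic power from graded exercise test variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Wingate anaerobic power from graded exercise test variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wantpower)
```

## The modelling problem

A standard graded exercise test (GXT) on a treadmill records time, speed,
slope and heart rate, but no gas exchange. The Wingate anaerobic test (WAnT)
measures anaerobic mechanical power directly: peak power (PP, watts, the
maximum over the first seconds of a 30-s all-out sprint) and mean power (MP,
watts, the 30-s average). `wantpower` predicts PP and MP from GXT variables
alone, on the premise that near-maximal treadmill intensities engage the
anaerobic reservoir enough to leave a readable signature in the mechanical
test state.

The pipeline has four stages: feature derivation, stratified splitting,
greedy forward model selection, and held-out evaluation.

## Feature derivation

For each subject, age-predicted maximal heart rate is the Tanaka formula
HRmax = 208 − 0.7 · age (beats/min, not rounded). Three effort levels are
considered: 85 %, 90 % and 100 % of HRmax — 85–90 % because clinical
ergometry typically terminates there, 100 % for a maximal test.

The trajectory is scanned for the *first upward crossing* of each target
heart rate; time, speed and slope are linearly interpolated at the crossing.
This localisation is deterministic and assumes HR is non-decreasing in the
protocol sense; a target at or below the first sample maps to the first
sample, and a target above the observed maximum is an error naming the
level (the subject did not reach that effort).

Predicted oxygen uptake uses the ACSM running equation

$$\dot VO_2 = 0.2\,v + 0.9\,v\,g + 3.5 \quad [\mathrm{mL\,kg^{-1}\,min^{-1}}]$$

with speed $v$ in m/min and grade $g$ as a dimensionless fraction. The
trajectory stores km/h and percent grade (the units a treadmill reports), so
`derive_feature_vector()` converts by × 1000/60 and ÷ 100 *before* applying
the equation — the equation's source fixes these units even though a table
of treadmill settings does not. Absolute VO2 (mL/min) is relative VO2 ×
body mass.

Eight feature families are evaluated per level — HR, exercise time,
absolute and relative predicted VO2, slope × speed, slope × speed × time,
and absolute and relative VO2 at the anaerobic threshold (AT) — which with
age gives the 25-candidate registry. Two reconstruction choices deserve
note:

- **The AT surrogate.** A plain GXT has no gas exchange, so the ventilatory
  threshold is not observable. The incremental protocol, however, switches
  from speed increments to slope increments when the respiratory quotient
  reaches 1, so the *first slope increase* is the one AT-aligned event
  visible in the mechanical trace. `at_time` can be supplied explicitly
  (e.g. from a gas-exchange record); otherwise the surrogate is used, and if
  neither exists the AT features are missing and are dropped from the
  candidate set at training time. VO2 at AT is recomputed from treadmill
  state at that time via the ACSM equation, not carried over from any
  external measurement. AT features do not depend on the level, so their
  three per-level registry entries share one value.
- **The maximal-intensity composite** is mapped to slope × speed × time,
  the only additional intensity product that appears in the published
  equations.

No intermediate rounding is performed anywhere; display rounding happens
only in `print` methods.

## Splitting and standardisation

`stratified_split()` partitions the cohort into calibration (40 %), test
(30 %) and validation (30 %) subsets, stratified on ACSM-predicted VO2max
(relative VO2 at 100 % HRmax) so each subset spans all exercise-capacity
levels. Subjects are ranked into 4 quantile bins (default; the bin count is
a free parameter), shuffled within bins, and labels are assigned along that
order by largest-deficit sequencing against largest-remainder global
quotas. This construction makes the three sets disjoint and exhaustive with
every size within one subject of its fraction × n, deterministically for
any seed — properties a per-bin independent draw would not guarantee. With
one bin it reduces to a simple random split.

Candidates are z-scored with calibration-set means and sample (n−1) SDs;
the same statistics standardise the test and validation sets, so no
information leaks out of calibration. A zero-variance candidate raises an
error naming the column.

## Greedy forward selection

Starting from the intercept-only model, each iteration fits one ordinary
least-squares regression per remaining candidate (base R's QR `lm.fit`) on
the calibration set and permanently adds the candidate with the smallest
residual sum of squares; ties (exactly equal SSE) keep the lowest registry
index for determinism. After each addition the equation is scored on the
test subset by Spearman rank correlation — recorded as a diagnostic only,
since no decision rule on it is defined. Selection stops before adding a
feature whose *relative* adjusted-R² improvement is negative or below
0.5 %; the phrase "increased or larger than 0.5 %" admits two readings, and
we adopt continue-while-improvement ≥ 0.5 %, which matches the intent of a
minimal-improvement threshold and yields the small (2–4 feature) models the
published tables show. If no single candidate improves on the intercept
(adjusted R² ≤ 0), the single best feature is kept with a warning. A
`max_features` cap (default 10) guarantees termination on adversarial
inputs. Rank-deficient candidate sets are skipped rather than fitted.

Evaluation reports the validation-set Spearman rho with a two-sided
t-approximation p-value (average ranks for ties), RMSE in watts, and the
percent error |Y_real − Y_pred| / Y_real · 100. The percent-error
distribution holds the fitted model *fixed* and applies it to 100 freshly
drawn validation subsets (30 % of the cohort each, drawn without
replacement within a draw), reporting the mean and SD of the per-draw mean
percent errors. Re-drawing validation sets with a fixed model — rather than
refitting per draw — is the literal reading of the stated procedure.

All randomness flows from one root seed through named substreams (`split`,
`error-reps`, `cohort`, `noise`, via `substream_seed()`), so every stage is
independently reproducible and two runs with the same seed are identical.

## The published equations

Six previously published regression equations (PP and MP at each level) are
shipped as a versioned JSON resource and applied by `predict_power()`. Their
coefficient magnitudes (e.g. 225 W per unit of absolute VO2) are only
dimensionally coherent if the predictors are z-scored, so application
requires standardisation statistics; the original calibration cohort's
means and SDs were never published, which makes absolute predictions
reference-frame dependent. This caveat is intrinsic to the published
equations, not to this implementation. Intercepts are watts at the
standardised origin. In the source tables the terms are separated by dashes
that are typographically em-dashes; they are read as minus signs, the only
parse that yields well-formed arithmetic, and the one unit-less VO2 term is
read as absolute VO2 (mL/min) by parallelism with the neighbouring columns.
Time inside the slope × speed × time composite is taken in minutes.

## The synthetic cohort generator

The raw study cohort behind the published equations is not deposited, so
the generator emulates its *statistical* structure: 40 women (age 26 ± 4 y,
mass 60.9 ± 9.8 kg, height 163.8 ± 6.4 cm) and 53 men (29 ± 6 y,
75.7 ± 10 kg, 176.6 ± 6.8 cm), truncated at physiologic bounds (18–50 y,
40–120 kg, 145–210 cm — generator policy, not cohort claims); minute-wise
trajectories starting at 8 km/h (a typical post-warm-up running speed),
+1 km/h per minute until the slope-phase onset (drawn N(8, 2) min, floored
at 3), then +2 % slope per stage for 3–6 stages; heart rate as a linear
ramp from N(110, 8) bpm with 2-bpm jitter, made monotone by a running
maximum and ending exactly at the subject's Tanaka HRmax, so every level is
crossed once. Outcomes come from a planted linear model on cohort-
standardised features at the 85 % level, using the same feature families as
the published 85 % equations — PP: 644 + 225·z(vo2_abs) − 87·z(vo2_rel) −
26·z(slope_speed_time); MP: 475 + 154·z(vo2_abs) − 93·z(vo2_at_rel) +
27·z(time) + 6·z(vo2_at_abs) — plus independent Gaussian noise of SD 40 W
per outcome, consistent with the best published validation RMSE (≈39 W).

What the generator does *not* emulate: VO2 kinetics, lactate dynamics,
inter-feature covariance beyond what the shared protocol induces, the
athlete/non-athlete mix, or measurement error in HR and treadmill state.
Passing pipeline tests on synthetic cohorts therefore demonstrates
algorithmic correctness and statistical behaviour under known ground truth
— not clinical validity on real subjects.

```{r}
co <- simulate_cohort(cohort_config(n_female = 12, n_male = 15), seed = 42)
co[[1]]
head(derive_features(co[1], levels = 0.85))
```

## Numerical choices and degenerate inputs

- Level localisation tolerates a relative 1e−8 overshoot of the target
  above the trajectory maximum, absorbing representation error from CSV
  round trips; beyond that the level is reported as not reached.
- Interpolation at an exact HR knot returns the knot values (the crossing
  weight is exact); flat HR segments cannot host a first crossing because
  the preceding sample must lie strictly below the target.
- Greedy SSE comparisons use a relative 1e−12 guard so that
  floating-point-equal candidates resolve to the lowest index.
- Constant outcome vectors, zero-variance candidates, rank-deficient
  designs, unreached levels and percent error at zero truth all raise
  classed errors rather than propagating NaN.

## Problem sizes in the test suite

The suite validates greedy-vs-exhaustive equivalence on 200 random
instances (n ≤ 60, ≤ 12 candidates), planted-model recovery on n = 100
cohorts over 20 seeds, the noisy-pipeline Spearman property on n = 200
cohorts over 100 seeds, split contracts over 10,000 seeded splits, and
law-of-large-numbers demographic convergence at n = 5,000 — sizes chosen to
give stable statistical verdicts at interactive runtimes.

## Known limitations

- **Greedy selection is not a support-recovery algorithm.** When a
  non-planted candidate is strongly correlated with a planted one — in
  protocol-faithful cohorts, absolute VO2 at the AT surrogate tracks
  absolute VO2 at the 85 % level closely, because the threshold falls near
  85 % HRmax — the first greedy step can select the proxy, and forward
  selection never removes a feature. Predictive performance is essentially
  unaffected (the proxy carries the same signal; validation correlations
  remain high), but the *identity* of the selected features is not
  guaranteed even at zero noise. This is an inherent property of greedy
  forward selection under collinearity; the per-step exhaustive-scan
  equivalence tests show the implementation executes the algorithm exactly.
  Notably, the published 90 %-level PP equation contains both absolute VO2
  terms at once, which is what strong collinearity of this pair looks like
  in practice.
- The published equations cannot be re-derived (the original cohort is
  unavailable), so the package makes no claim of reproducing their
  validation correlations on new data.
- The feature registry is a faithful reconstruction of the documented
  25-candidate set, not a verbatim copy of an unpublished enumeration; it
  is configurable at the `feature_matrix()` level by construction.
- Treadmill running only: cycle-ergometer metabolic equations and
  gas-exchange (breath-by-breath) processing are out of scope, as is
  prediction of the Wingate fatigue index.
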
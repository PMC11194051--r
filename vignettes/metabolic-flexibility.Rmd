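---
title: "Measuring metabolic flexibility: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metabolic flexibility: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metflexr)
```

## The measurement model

Whole-body fuel selection is read off the respiratory exchange ratio
RER = V̇CO2/V̇O2 measured at the mouth: ≈0.70 indicates essentially pure fat
oxidation, ≈1.00 pure carbohydrate oxidation. Metabolic flexibility
(MetFlex) is operationalized twice:

* **Insulin-stimulated MetFlex**: ΔRER = steady-state RER during a
  hyperinsulinemic-euglycemic clamp minus fasting steady-state RER. A
  healthy response to insulin is a shift toward carbohydrate oxidation
  (positive ΔRER); values near or below zero indicate inflexibility.
* **Exercise MetFlex**: ΔRER from the low-intensity (25 W) stage of a
  graded maximal cycle test to the maximal stage, where RER rises with the
  increasing glycolytic contribution.

Substrate oxidation rates come from stoichiometric combinations of the gas
flows (L·min⁻¹), assuming negligible protein oxidation. Distinct
coefficient sets apply at rest, at low exercise intensity, and near maximal
intensity — the exercise sets account for the acid-base shift and the
growing muscle-glycogen contribution at high loads, which is also why
maximal-intensity FATox is routinely negative (RER above the 1.695/1.701
crossover) and is reported as computed rather than clamped. The three sets
ship in `default_stoichiometry()` and every coefficient is overridable.

Resting energy expenditure has no printed equation in the source tables; we
use the standard Weir-form combination `3.941·V̇O2 + 1.106·V̇CO2`
(kcal·min⁻¹, flows in L·min⁻¹) scaled to kcal·day⁻¹, isolated in
`resting_ee_kcal_day()` with configurable coefficients. Percent-of-EE
splits use energy equivalents of 4.07 kcal·g⁻¹ (carbohydrate) and
9.46 kcal·g⁻¹ (fat), clamping negative oxidation rates to zero inside the
share computation only.

## Steady-state detection

The protocol criterion is <10% CV in V̇O2 and V̇CO2 *and/or* <5% CV in RER
sustained for ≥4 min, after discarding the first 4 min under the hood. Three
choices were genuinely open:

* **What the CV is computed on.** Raw breath-to-breath values are so noisy
  that the printed thresholds would almost never be met; we compute CVs on
  non-overlapping 30-s sub-bin means (configurable `bin_s`), which matches
  how metabolic carts average for display.
* **"and/or".** `criterion_mode` defaults to `"either"` (either criterion
  alone qualifies a window), with `"both"`, `"gas_only"`, `"rer_only"`
  available.
* **Which window to report.** All windows of ≥ `min_window_s`, advancing one
  sub-bin at a time, are scanned; the *longest* qualifying window wins, the
  earliest on ties. Longest-first favors stability of the reported means;
  earliest-first keeps ties deterministic. One consequence, verified in the
  tests: a long steady tail can dilute the last seconds of a settling
  transient under the CV threshold, so the accepted window may clip the tail
  of a lead-in. The default 4-min discard removes that overlap in practice.

The window RER defaults to the mean of sub-bin RER values (`rer_mode =
"mean_of_ratios"`), because ΔRER is defined on averaged steady-state RER; a
`"ratio_of_means"` alternative is provided. A series with no qualifying
window raises a classed condition that `process_cohort()` converts into a
reason-coded exclusion, mirroring the participant who never reached steady
state.

## Clamp processing

Whole-body glucose uptake M is computed per 20-min interval as the
time-weighted glucose infusion rate (pump mL·h⁻¹ × 10·concentration% mg·mL⁻¹
/ 60 / kg). "Steady-state glucose values" is made explicit: an interval is
steady when *all* its plasma glucose samples lie within ±5% of the 5.0
mmol·L⁻¹ target (the measurement-span CV reported for this protocol is
~5.5%). The summary M defaults to the last steady interval — insulin action
plateaus late in the clamp — with a mean-of-last-two option. No glucose
space correction is applied, since the protocol does not describe one.
NOGD = max(0, GIR − CHOox), and carbohydrate oxidation beyond the infused
glucose is attributed to other CHO sources (glycogen, endogenous glucose,
lactate). Insulin arrives in pmol·L⁻¹ and is converted to mU·L⁻¹ for
HOMA-IR at 6.945 pmol per mU (configurable).

## Exercise test

Gas values are averaged over 20-s bins aligned to test start (incomplete
trailing bin dropped). Stage summaries use the final 60 s of each 3-min
stage, where values are closest to stage steady state. V̇O2max is the
highest single 20-s bin — plateau and secondary criteria from the original
testing protocol are deliberately out of scope — and the exercise ΔRER uses
the *stage* convention (25 W stage mean to maximal stage mean) rather than
the global bin extrema, which are reported alongside. Delta exercise
efficiency is 100 × ΔPO/ΔEE with watts converted at exactly 0.014
kcal·min⁻¹·W⁻¹ as printed (not the more precise 0.01433), between 25 and
75 W for women and 25 and 100 W for men (≈65% of mean maximal power in each
sex), with stage EE from the low-intensity equation.

## Accelerometry

Epochs are 6 s. Sedentary and standing are both ≤1.5 METs, separated by
posture; LPA is the open interval (1.5, 3.0); MVPA is ≥3.0 — the boundary
conventions match the printed "≤1.5", "1.5–2.9" and "≥3.0". The validated
MAD→MET regression and posture-angle algorithms of the measurement device
are not reproduced (their calibration constants are published elsewhere);
epochs carry device METs and posture, or a configurable monotone MAD→MET
mapping is applied. A break in sedentary time is any worn sedentary epoch
followed by a worn non-sedentary epoch, with no minimum bout imposed (none
is stated). Days are valid at 10–19 h wear; subjects need ≥4 valid days.
Because only worn epochs are classified and the four categories are
exhaustive, category hours sum to wear hours exactly — an invariant the
test suite checks over 10,000 randomized days.

## The synthetic cohort: what it emulates, and what it does not

No participant-level data are deposited for studies of this design, so the
generator is a first-class module. Its defaults *are* the stated world of
the anchor cohort: n = 64 (37 women, 27 men), age 58.3 (SD 6.8) years,
weight 93.2 (16.1) kg, BMI 31.6 (4.3); daily sedentary time 10.04 (1.01) h,
standing 1.79 (0.59) h, LPA 1.74 (0.44) h, MVPA 0.97 (0.32) h, 5,149
(1,825) steps, 29 (8) breaks, over 26 measurement days; fasting RER centred
at 0.91 with clamp ΔRER centred at 0.00 (SD 0.05); exercise RER rising from
0.74 (0.05) at 25 W to 1.12 (0.06) at maximal load; M log-normal with
median 2.5 mg·kg⁻¹·min⁻¹; delta efficiency 16.7 (2.5)%. Wear time is the
sum of the four category hours (10.04 + 1.79 + 1.74 + 0.97 = 14.54 h/day),
which is also how measured wear decomposes. Distributions are truncated
normals for mean (SD) rows and log-normals fitted to median (Q1, Q3) rows.

Noise enters at the raw-stream level: multiplicative breath noise (default
CV 2%) applied to V̇O2 with *ratio* noise riding on the realized V̇O2, so
that E[V̇CO2/V̇O2] equals the planted RER exactly; clamp glucose samples
scatter with SD 0.1 mmol·L⁻¹ around target after a 30-min settling
transient; epoch METs vary within class. Day-level activity varies around
the subject profile, and each day is built as alternating
sedentary/non-sedentary bouts so the planted break count is realized by
construction.

**Effect planting.** Cross-sectional associations are planted on latent
subject traits, not raw streams, so measurement noise attenuates them
realistically. Because wear time is structurally the category sum, a
marginal loading on, say, sedentary hours is *not* the wear-adjusted
partial coefficient. Each planted value is therefore defined as the
covariate-adjusted standardized β (sex, age, wear time for accelerometer
exposures): the generator residualizes the z-scored exposures on those
covariates, solves a small linear system in the residual covariance so that
every single-exposure adjusted regression recovers its planted β in
expectation, and adds independent noise to unit outcome variance. The
default plant is the four significant fasting/clamp associations (sedentary
+0.35 on fasting RER, −0.41 on ΔRER; standing −0.32 on fasting RER; LPA
+0.33 on ΔRER). Calibration at 400 replicates of n = 64 shows all four
recovered within ~1 Monte-Carlo SE; a small finite-sample inflation of
order 0.01 (from re-standardizing on the analysed sample) is visible at
n = 64 and vanishes by n = 2,000.

The generator couples the planted V̇O2max to the planted efficiency: a
subject who completed the 75/100-W efficiency-bound stage must have a VO2
ceiling above that stage's requirement, so drawn V̇O2max values are floored
at 1.10 × the bound-stage VO2. And the final (plateau) stage ramps within
its first third, so noiseless stage-tail means equal the planted targets
exactly — the basis of the float-tolerance recovery tests.

What the generator does **not** emulate: glucose–insulin dynamics (no ODE
model — the pump log converges to the planted uptake by construction),
dietary effects on RER, seasonal or day-of-week activity structure,
device-specific MAD waveforms (epochs carry METs directly), and correlated
exposure structure beyond the wear-time identity (exposures are drawn
mutually independent, so a green recovery test establishes estimator
correctness, not robustness to real-world collinearity between, say,
sedentary time and MVPA).

## Statistical stage

Standardized βs are OLS coefficients with outcome and continuous exposures
z-scored on the per-analysis complete cases (binary sex stays a 0/1
indicator; covariate z-scoring is optional and on by default), with
normal-theory 95% CIs. The covariate policy is: sex and age always;
accelerometer wear time for accelerometer exposures; total PA appended in
the sensitivity refit for sedentary time, standing and steps. The log10
rule replaces a visual normality judgement with an explicit, reproducible
one: transform when base-model residual |skewness| > 1 or Shapiro-Wilk
p < 0.01, recorded per result; outcomes with non-positive values are never
transformed. Missing data are complete-case per analysis; no
multiple-testing correction is applied (none is in the source design);
VIF ≥ 5 flags collinearity. Partial Pearson correlations residualize both
variables on the covariates and use n − 2 − k degrees of freedom; the
matrix-inversion identity is the independent oracle in the tests.

## Numerical and degenerate-input choices

* Sub-bins partially covering the series end are dropped (equal-width bins);
  an empty sub-bin (recording gap) truncates the binning at the gap.
* Ties between equally long steady windows: earliest wins.
* `nonoxidative_disposal()` clamps negative CHOox to zero before
  subtracting, matching the reporting convention for the partition.
* `percent_ee()` signals an undefined share when both rates are ≤ 0.
* The breath writer emits 17 significant digits so write→read cycles are
  bit-exact.
* All randomness is seed-derived; per-subject substreams are offset by data
  type so adding a data type never perturbs existing draws.

## Known limitations

* V̇O2max uses the single best 20-s bin; as a maximum over noisy bins it
  sits slightly above the latent plateau under noise (within one bin SD in
  calibration) — plateau/verification criteria would be needed for a
  bias-free estimate.
* The steady-state CV criterion is scale-free but not drift-free: slow
  drifts just under the threshold pass, as discussed above.
* The ±5% glucose steadiness rule and the last-interval M summary are
  explicit choices where the protocol text is silent; both are
  configurable, and cohort results shift by <5% between the provided modes.
* Planted-effect recovery is exact only in expectation; at n = 64 the
  re-standardization inflation (~0.01) is well inside a single-study CI
  half-width (~0.3) but visible to a 400-replicate calibration.
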
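---
title: "An individual-based microsimulation of albuminuria screening in CKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based microsimulation of albuminuria screening in CKD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdscreen)
```

## The model

`ckdscreen` simulates an adult population, one individual at a time, in
annual cycles from a 2016-style age/sex distribution until death or
censoring at age 90. Each individual carries:

* **Anthropometrics.** A lifelong BMI standard-deviation score (SDS) drawn
  standard-normal and converted to kg/m² through an age- and sex-specific
  LMS (lambda-mu-sigma) reference; individuals keep their percentile while
  the reference shifts with age. SBP works the same way, with two twists:
  the SDS draw is shifted by a calibrated mean (`sbp_mu_adjust`, see
  *Calibration*), and the resulting SBP is raised linearly by
  `sbp_bmi_slope` mmHg per BMI unit above `sbp_bmi_ref`; the SDS of the
  *elevated* value is then stored as the definitive lifelong score.
* **Hypertension and therapy.** SBP strictly above 140 mmHg ("exceeding"
  read literally) marks hypertension; a drug class (ACEI, ARB, other, none)
  is drawn once from the therapy distribution and never changes.
* **Diabetes.** Prevalence at entry and annual incidence come from
  (age, sex) marginal tables combined with relative risks for obesity
  (BMI > 30) and hypertension. The marginal is decomposed into a baseline
  risk for the unexposed via `solve_baseline_risk()`:
  `r0 = marginal / sum(share_k * RR_k)`, with stratum shares taken from the
  simulated population itself, so the mixture reproduces the marginal
  exactly.
* **Renal state.** Albuminuria moves irreversibly
  none → micro → macro; onset and progression probabilities depend on age,
  sex, diabetes and the SBP stratum (< 140 / ≥ 140 mmHg). GFR declines by a
  stratum-specific base loss (ml/min/year), scaled by an age factor, by an
  individual lognormal loss factor, and by the 0.75 GFR-loss calibration
  scale. GFR is floored at 0 and RRT starts, irreversibly, when GFR falls
  strictly below 7 ml/min.
* **Screening and therapy.** In a testing scenario, eligible individuals
  (scenario rule, not on ACEI/ARB, never previously positive, not on RRT,
  on-interval year) undergo two albumin–creatinine tests in the same
  follow-up (sensitivity 0.87, specificity 0.88 per test, independent
  conditional on the true state); therapy starts only if both are positive.
  Every positive — true or false — starts lifelong ACEI: medication costs
  accrue regardless of adherence, while the clinical effects (GFR-loss
  reduction `effect_acei_e_gfr`, micro→macro relative risk
  `effect_acei_rr_progression`, mortality relative risk
  `effect_acei_rr_death`) require adherence (drawn once, probability 0.91)
  *and* an albuminuric state. Individuals on ACEI/ARB for hypertension get
  the clinical effects unconditionally — adherence is only modelled for
  test-initiated therapy, because the hypertension-therapy distribution
  already contains a "no therapy" mass.
* **Mortality.** Life-table probability × mortality calibration factor ×
  a relative risk by CKD stage and albuminuria category, × the ACEI
  mortality effect where applicable, capped at 1.
* **Outcomes.** Each alive year contributes the EQ-5D utility of the
  current CKD stage (stages keyed purely to GFR bands), 63,000 € if on RRT,
  54.79 €/year of ACEI if on test-initiated therapy (15 € per 100 days ×
  365.25/100 — the printed price is read as the price's validity, not as a
  first-year-only cost), and 36.18 € per testing occasion. Discounting uses
  (1.035)^(−t) on a clock shared by all individuals, t = 0 in the first
  cycle, so year-0 events are undiscounted. No half-cycle correction: the
  model is a plain annual-cycle simulation.

### Cycle order

Within a year: ageing/anthropometrics → incident diabetes → albuminuria →
GFR decline → RRT check → screening → mortality → accrual; individuals
reaching 90 are censored after accrual. Screening precedes mortality so
therapy initiated in a cycle can affect that cycle's death risk — the
opposite choice would discard the stated mortality effect in the initiation
year. The order is fixed and documented here rather than configurable.

### Common random numbers

Every stochastic step draws one uniform per individual from a substream
keyed by (master seed, step name, cycle) — never by scenario arm. All arms
therefore see identical per-individual randomness and diverge only where a
decision differs; with null treatment effects the arms are *bit-identical*
in their health trajectories, which the test suite asserts. This also makes
scenario contrasts (e.g. lifetime RRT prevalence differences) far more
precise than independent runs of the same size.

### Renal age profiles

Initial GFR distributions and albuminuria prevalences are only valid at age
30, so `derive_renal_age_profiles()` pre-simulates a cohort of
thirty-year-olds (base case, no screening) to the age cap and tabulates the
surviving non-RRT individuals' GFR mean/sd and albuminuria prevalences per
attained age and sex; ages 18–29 copy the age-30 row. Individuals entering
the main simulation at older ages are initialised from these profiles with
a normal GFR truncated above the RRT threshold (a fresh entrant cannot
start below it — they would be an RRT case, which the profile excludes).

## The fixture parameter set

The published parameterisation lives in supplementary tables that are not
reproduced here, so the package ships a schema-identical fixture,
generated by `fixture_parameters()` and writable/re-loadable as CSV. Every
value carries a provenance flag: quantities printed in the main model
description (`"paper"`: test characteristics 0.87/0.88, two repeats every
two years, adherence 0.91, 140 mmHg and 7 ml/min thresholds, the 0.75
GFR-loss scale, 3.5 %/year discounting, 36.18 €/occasion, 63,000 €/RRT-year,
15 €/100 days, age cap 90) versus documented placeholders (`"placeholder"`:
reference distributions, risk tables, utilities, effect sizes). Swapping in
the real supplementary values is a data change only.

Placeholder choices, made once for epidemiological plausibility and then
frozen:

* BMI reference: L = −1, S = 0.13, median rising from ~22 kg/m² at 18 to
  ~28 around 70, tabulated only to age 79 so the cubic extension to 90 is
  exercised on real package paths.
* SBP reference: normal (L = 1), S = 0.095, median ~121 mmHg at 30 and
  ~138 at 70, tabulated at 5-year midpoints so the cubic smoothing to an
  annual grid is exercised. Both references are polynomial in age by
  construction, so the degree-3 fit introduces no approximation error of
  its own.
* Life table: Gompertz `q = 2.4e-6 · exp(0.12 · age)`, men ×1.6 — roughly
  German-level survival (about 27 % of the mixed-age cohort reaches 90).
* Albuminuria and GFR intensities, utilities (0.86 down to 0.62 by stage),
  effect sizes (GFR-loss reduction 0.40, progression RR 0.50, death RR
  0.85) and diabetes relative risks (3.0 obesity, 2.0 hypertension): chosen
  inside published ranges, then adjusted *once* with the package's own
  calibration hooks so the base case lands at plausible German levels
  (mean age at death ~81, mean age at RRT ~77, lifetime RRT prevalence in
  the low single-digit percent). The shipped `sbp_mu_adjust = -0.19` and
  `mortality_calibration_factor = 0.67` are the outputs of
  `calibrate_sbp_mean()` and `calibrate_mortality_factor()` on exactly this
  fixture.

The generator is deterministic — placeholders are constants, not draws — so
it is trivially a pure function of its seed argument.

### What the fixture does and does not emulate

It reproduces the *structure* of the published inputs (schemas, strata,
irreversibility, all printed constants) and realistic orders of magnitude,
so the tests demonstrate that the machinery behaves correctly: invariants,
calibration recovery, scenario ordering, cost accounting. It does **not**
reproduce the published numeric tables, so passing tests say nothing about
the exact published cost-effectiveness ratios; reproducing those requires
loading the original supplementary tables through `load_parameters()` and
a cohort of 10⁷ individuals, far beyond the test scale.

## Numerical choices

* SDS draws are truncated to ±4 before LMS conversion: for negative L the
  LMS domain requires `1 + L·S·z > 0`, and untruncated ~1-in-16,000 tail
  draws would otherwise abort a large population synthesis. The truncation
  bias on means is < 1e-4 standard deviations.
* `lms_value()` evaluates the general branch as `M·exp(log1p(LSz)/L)`,
  which is accurate and continuous as L → 0 (the L = 0 branch is the exact
  limit).
* `fit_lms()` minimises the squared quantile error with BFGS from four L
  starting points, then polishes with Nelder–Mead; with three percentile
  points the fit is exact to ~1e-12. Non-monotone percentile input is an
  error.
* Percentile-curve extrapolation is an ordinary least-squares cubic per
  percentile; cross-percentile monotonicity is re-checked afterwards and a
  crossing raises an error listing the affected ages — never a silent clamp.
* Probabilities that exceed 1 after relative-risk multiplication are capped
  at 1.
* The BMI LMS extension to the age cap fits the cubic on the last 30
  tabulated ages (a full-range fit would let young-adult curvature distort
  the 80–90 extension).
* Between tabulated ages, L/M/S are interpolated linearly in age.
* Bisection for the SBP mean uses a fixed set of SDS draws, so the
  objective is deterministic and monotone in the shift; tolerance 0.1 mmHg
  on the median, bracket [−4, 1].
* Mortality calibration is iterative proportional fitting on the ratio of
  observed to life-table-expected deaths over the same person-years,
  relative tolerance 1 %, at most 20 iterations.

## Scenario arms and comparison

The four published comparators are built in (`default_scenarios()`): no
testing, testing all individuals with diabetes, all with diabetes or
hypertension, and whole-population screening — each every two years,
skipping anyone already on a renin-angiotensin blocker, never re-testing a
positive. `run_simulation()` builds one population, clones it across arms,
and reports per scenario: lifetime RRT prevalence, mean ages at RRT and
death, share censored at 90, QALYs and cost components per individual
(undiscounted and discounted), and the false-positive share, each with a
Wald 95 % confidence interval over individuals. `compare_scenarios()`
reports (testing + medication cost)/QALY gained and the net ratio after
subtracting RRT savings; a non-positive QALY gain flags the ratio as
undefined rather than emitting a number.

One deliberate reading: the published model description contains an
internal tension on whether false positives' medication costs count; this
package follows the assumption section — false positives pay for medication
until death or the cap, with no clinical effect.

## Sensitivity sweep and validation

`run_sensitivity_sweep()` scales one input at a time (BMI reference median,
SBP percentiles, diabetes prevalence+incidence, albuminuria incidence, GFR
loss) by 0.80…1.20 in 0.05 steps under a common seed and records the
lifetime RRT cost per individual and RRT prevalence; the 1.00 cell equals
the unperturbed run exactly. `validation_report()` compares the simulated
marginals (sex, age bands, BMI/SBP medians, diabetes prevalence,
albuminuria) with the input tables within 3-standard-error bands.

## Problem sizes

The package's own test runs use cohorts of 400–100,000 individuals with
pre-simulation cohorts of 1,200–50,000 — sizes chosen so the full suite
documents every property in a few minutes while leaving Monte-Carlo error
well inside the asserted bounds. Production-style analyses would raise both
(the published analysis used 10⁷ and 10⁶ respectively); runtime scales
linearly in individuals × cycles.

## Limitations

No remission or transplant modelling, no SBP feedback from therapy, no
re-testing of positives, no confirmatory GFR testing, no harms or
psychological effects of false positives, no cost inflation beyond fixed
2016 prices, and no probabilistic sensitivity analysis beyond the one-way
sweep. Initial GFR and albuminuria are conditionally independent given
(age, sex) at initialisation of older entrants — the profile stores
marginals per cell, which understates the within-individual correlation a
joint table would carry.
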
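# ckdscreen

An individual-based, annual-cycle microsimulation of chronic kidney disease
(CKD) for comparing urinary albumin–creatinine screening strategies in a
cost-effectiveness framework. It is aimed at health-economic modellers and
epidemiologists who want to ask: *is it worth testing (parts of) the adult
population for albuminuria every few years, treating positives with an ACE
inhibitor, given what renal replacement therapy (RRT) costs?*

## The model in brief

Each simulated adult carries age, sex, a lifelong BMI percentile and a
lifelong SBP percentile expressed as standard-deviation scores under LMS
(lambda–mu–sigma) references — a value `x` at SDS `z` satisfies
`x = M (1 + L S z)^{1/L}` (`M e^{Sz}` for `L = 0`) — plus diabetes,
albuminuria category (none → micro → macro, irreversible), GFR, and
therapy/cost/QALY state. Per year, in fixed order:

1. ageing: BMI and SBP re-evaluated from fixed SDS at the new age;
2. incident diabetes: baseline risk solved from the marginal incidence so
   that `sum(share_k · RR_k) · r0 = marginal` exactly, RRs for obesity and
   hypertension;
3. albuminuria onset/progression by age, sex, diabetes and SBP stratum;
4. GFR decline (stratum base loss × age factor × individual lognormal
   factor × 0.75 calibration scale), reduced by ACEI in treated
   albuminuric individuals;
5. RRT initiation when GFR < 7 ml/min;
6. scenario-gated screening: two albumin–creatinine tests (sensitivity
   0.87, specificity 0.88 each), both positive ⇒ lifelong ACEI, adherence
   0.91 drawn once, false positives pay but don't benefit;
7. mortality: life table × calibration × CKD-stage/albuminuria relative
   risk × ACEI effect, capped at 1;
8. accrual: EQ-5D utility of the CKD stage, 63,000 €/RRT-year,
   54.79 €/ACEI-year, 36.18 € per testing occasion; discounted at
   3.5 %/year alongside the undiscounted stream.

All scenario arms share one initial population and common per-individual
random substreams, so arms differ only through screening decisions. The
published comparator set — no testing, testing everyone with diabetes,
everyone with diabetes or hypertension, whole-population screening, each
every two years skipping existing ACEI/ARB users — is built in.

Parameters are plain CSV tables plus scalars with a provenance column
(`paper` for constants printed in the published model description,
`placeholder` for the shipped stand-ins for its unpublished supplementary
tables); see the methods vignette
(`vignettes/albuminuria-screening-model.Rmd`) for every default and why.

## Worked example

```r
library(ckdscreen)
p   <- prepare_parameters(fixture_parameters())
run <- run_simulation(p, n_individuals = 20000, seed = 1,
                      profile_cohort_size = 20000)
print(run)
```

```
<ckd_run> n = 20000, seed = 1, 4 scenario arm(s)
                                     base  diabetes diabetes-or-hypertension
rrt_lifetime_prevalence_pct         4.400     4.110                    4.100
mean_age_at_rrt                    76.480    76.693                   76.749
mean_age_at_death                  81.032    81.064                   81.084
censored_at_cap_pct                27.020    27.250                   27.395
qaly_per_individual_undisc         27.121    27.164                   27.190
cost_rrt_per_individual_undisc  13185.900 12505.500                12414.150
cost_test_per_individual_undisc     0.000    82.145                  134.448
cost_med_per_individual_undisc      0.000    52.952                   85.422
false_positive_pct                  0.000     3.265                    5.410
...
Incremental vs base:
                 scenario stream qaly_gained cost_per_qaly net_cost_per_qaly
                 diabetes undisc  0.04321900      3125.871        -12617.205
 diabetes-or-hypertension undisc  0.06927700      3173.787         -7966.274
                      all undisc  0.13751350      5249.698         -4554.430
```

Reading it: under the fixture parameterisation, broader screening strictly
lowers lifetime RRT prevalence (4.40 % → 3.89 %) and strictly raises
testing cost per head (0 → 422 €). Testing and therapy cost ~3,100–5,200 €
per QALY gained on their own; once the avoided RRT costs are credited,
every strategy is net cost-saving (negative €/QALY), most strongly when
only individuals with diabetes are tested — the qualitative pattern of the
published analysis. Each summary row also carries a 95 % confidence
interval (`run$summaries`), and `write_run(run, dir)` exports everything as
CSV/JSON.

The calibration hooks and the one-way sensitivity sweep are exported too:

```r
calibrate_sbp_mean(p)           # mean shift compensating the BMI elevation
calibrate_mortality_factor(p)   # match overall mortality to the life table
run_sensitivity_sweep(p, parameters = "gfr_loss", n = 5000)
```

A thin command-line front end over the same functions lives at
`inst/cli/ckdscreen.R`
(`Rscript inst/cli/ckdscreen.R simulate --out out/ --n 20000 --seed 1`).

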
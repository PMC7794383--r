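# gcmediate

Causal mediation analysis by the parametric g-formula (G-computation)
for birth-cohort studies, built around one question: how much of the
effect of early age at menarche (< 12 years vs ≥ 14) on adult
cardiometabolic risk factors runs through adult body composition?

The package is aimed at epidemiologists and biostatisticians who want a
tested, reproducible implementation of:

* **Natural direct / indirect / total effects** for a categorical
  exposure and a continuous mediator, with an exposure × mediator
  interaction, baseline confounders, and exposure-induced
  (post-)confounders — in which case the reported quantities are the
  randomized-interventional analogues of natural effects;
* **Percentile-bootstrap confidence intervals** with a full model refit
  in every replicate (default 10,000 replications);
* the **proportion mediated**, `100 × NIE / TCE`, set to 0 when the
  direct and indirect effects have opposite signs;
* a **synthetic cohort generator** that emulates the marginal structure
  of a 1982 Brazilian birth cohort's women at age 30 (n = 1,680), with
  closed-form true estimands for validating the estimator;
* supporting analyses: per-exposure-category descriptive tables with
  linear-trend and heterogeneity (ANOVA) tests, geometric means for
  log-scale variables, confounder-adjusted linear regressions,
  robust-variance Poisson prevalence ratios, and the C-reactive-protein
  exclusion filter (CRP > 10 mg/dl, pregnancy, recent postpartum,
  oral-contraceptive use).

## The model

For exposure contrast *a* vs *a**, mediator M, outcome Y, baseline
confounders C and post-confounders L, G-computation fits

```
L_j ~ A + C                     (linear or logistic)
M   ~ A + C + L                 (linear)
Y   ~ A + M + A:M + C + L       (linear; log scale for skewed outcomes)
```

and forms counterfactual means per subject, either by exact plug-in of
conditional means (no post-confounders) or Monte-Carlo simulation.
Then

```
NDE = E[Y(a, M(a*))] − E[Y(a*, M(a*))]
NIE = E[Y(a, M(a))]  − E[Y(a, M(a*))]
TCE = NDE + NIE                  (bit-exact, same arithmetic pass)
```

A closed-form oracle for the linear no-L case,
`NDE = (θ₁ + θ₃(β₀ + β₁a* + c̄))(a − a*)`,
`NIE = (θ₂β₁ + θ₃β₁a)(a − a*)`, backs the test suite.

## Worked example

```r
library(gcmediate)

cfg    <- default_generation_config(n = 1680)   # emulated cohort
cohort <- generate_cohort(cfg, seed = 1)

spec <- mediation_spec(
  mediator = "fat_mass_index", outcome = "dbp",
  base_confounders = c("family_income_cat", "household_score",
                       "maternal_schooling_cat", "maternal_smoking",
                       "birthweight_g", "breastfeeding_cat",
                       "african_ancestry"),
  post_confounders = c("active", "saturated_fat_pct"))

true_effects(cfg, spec)   # estimands implied by the generating process
#> $nde: 0.5999  $nie: 1.0894  $tce: 1.6893

bootstrap_mediation(cohort, spec,
                    gcomp_config(bootstrap_reps = 1000, seed = 2))
#> G-computation mediation: lt12 -> dbp (contrast lt12 vs ge14)
#>   mediator: fat_mass_index   interventional-analogue natural effects
#>   NDE: -0.14 (-1.477; 1.107)
#>   NIE: 1.315 (0.734; 1.992)
#>   TCE: 1.175 (-0.065; 2.355)
#>   % mediated: 0
#>   n = 780, bootstrap reps = 1000 (0 dropped), engine = simulation, seed = 2
```

Reading the output: the indirect effect through fat mass index is
1.32 mmHg of diastolic blood pressure (95% CI 0.73–1.99), close to the
generating truth of 1.09; the direct effect is estimated at −0.14 with a
CI spanning zero (truth 0.60 — a single cohort of 780 usable women
leaves the direct effect noisy).  Because the NDE and NIE point
estimates have opposite signs at this draw, the proportion mediated is
reported as 0 by the opposite-direction rule.  Only the 411-ish `lt12`
and 370-ish `ge14` women enter the contrast; the 12–13 group is set
aside.

Descriptives use the same table:

```r
summarize_by_exposure(cohort, "fat_mass_index", test = "trend")
#> fat_mass_index [identity]  trend test p = <2e-16
#>  level   n estimate lower upper
#>   lt12 409    12.61 12.18 13.05
#>    mid 900    10.36 10.07 10.64
#>   ge14 371     9.68  9.25 10.10
```

A config-driven end-to-end run (`run_pipeline()`, or the thin CLI at
`inst/scripts/cohort_pipeline.R` with verbs `generate` / `describe` /
`fit` / `mediate` / `all`) writes table-style CSV reports plus a run log
with row counts at every filter step.  The cohort CSV schema is
documented in `inst/extdata/data_dictionary.csv`.

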
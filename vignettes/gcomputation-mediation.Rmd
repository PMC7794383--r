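---
title: "G-computation mediation analysis with gcmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G-computation mediation analysis with gcmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmediate)
```

## The scientific problem

Early age at menarche (first menstruation before 12 years) is associated
with worse adult cardiometabolic profiles — higher blood pressure,
cholesterol, triglycerides.  A natural mechanistic question is how much of
that association runs *through* adult body composition: girls with early
menarche tend to carry more body fat into adulthood, and adiposity raises
cardiometabolic risk.  `gcmediate` implements the causal mediation
analysis that answers this question for a categorical exposure (age at
menarche in three classes: `lt12`, `mid` = 12–13, `ge14`), a continuous
body-composition mediator (BMI, fat mass index, or waist-to-hip ratio),
and a continuous outcome, in the presence of

* **base confounders** C — pre-exposure common causes (family income,
  household score, maternal schooling and smoking, birthweight,
  breastfeeding duration, African genomic-ancestry proportion);
* **post-confounders** L — mediator–outcome confounders that may
  themselves be affected by the exposure (adult physical activity,
  dietary saturated fat);
* an **exposure × mediator interaction** in the outcome model.

## Estimands and the g-formula

For exposure levels $a$ (active, `lt12`) versus $a^*$ (reference,
`ge14`), let $Y(a, M(a^*))$ be the outcome under exposure $a$ with the
mediator set to the value it would take under $a^*$.  The package
estimates

$$\mathrm{NDE} = E[Y(a, M(a^*))] - E[Y(a^*, M(a^*))], \qquad
  \mathrm{NIE} = E[Y(a, M(a))] - E[Y(a, M(a^*))],$$

with $\mathrm{TCE} = \mathrm{NDE} + \mathrm{NIE}$ by construction (the
sum is formed in the same arithmetic pass, so the identity is bit-exact
in every bootstrap replicate).  The proportion mediated is
$100 \times \mathrm{NIE}/\mathrm{TCE}$, reported as 0 when the direct
and indirect effects point in opposite directions (a ratio of
opposite-signed quantities is not a proportion).

Estimation is by the parametric g-formula ("G-computation"):

1. each post-confounder $L_j$ is regressed on $(A, C)$ — linear if
   continuous, logistic if binary;
2. the mediator is regressed linearly on $(A, C, L)$;
3. the outcome is regressed linearly on $(A, M, A \times M, C, L)$,
   on the log scale for right-skewed outcomes (triglycerides,
   C-reactive protein); effects for those outcomes are reported on the
   log scale and never back-transformed;
4. counterfactual means are formed per subject and averaged.

Step 4 has two engines.  The **expectation engine** plugs conditional
means into the fitted linear system; because every model is linear, this
is exact and deterministic, but it is only valid when there are no
post-confounders.  The **simulation engine** draws `mc_draws` Monte-Carlo
realisations of $L$ under each exposure setting (Bernoulli for binary,
Gaussian with the fitted residual SD for continuous), draws the mediator
from its fitted Gaussian under the relevant setting, and averages the
predicted outcome.  With post-confounders present, natural effects are
not identified (the mediator–outcome confounder is affected by
exposure), and what the simulation engine targets are the
*randomized-interventional analogues* of natural effects; the output is
flagged accordingly.

Confidence intervals are percentile bootstrap: rows are resampled with
replacement and the **entire** pipeline — including all model refits — is
re-run per replicate (default 10,000 replications).  Percentile rather
than BCa or normal intervals are used because they are the common default
of g-formula implementations and make no symmetry assumption.  The
proportion mediated is computed on the point estimates only, without an
interval, since a ratio of bootstrap quantiles is not a quantile of the
ratio.

## The closed-form oracle

With no post-confounders, numeric exposure codes, mediator model
$M = \beta_0 + \beta_1 A + \beta_2' C + \varepsilon_M$ and outcome model
$Y = \theta_0 + \theta_1 A + \theta_2 M + \theta_3 AM + \theta_4' C +
\varepsilon_Y$,

$$\mathrm{NDE} = \bigl(\theta_1 + \theta_3(\beta_0 + \beta_1 a^* +
\bar c)\bigr)(a - a^*), \qquad
\mathrm{NIE} = (\theta_2\beta_1 + \theta_3\beta_1 a)(a - a^*),$$

where $\bar c$ is the mean confounder contribution to the mediator model.
`closed_form_nde_nie()` implements this; the test suite verifies that the
expectation engine equals it — evaluated at the *fitted* coefficients and
the sample-mean confounder contribution — to below $10^{-8}$, and that
the simulation engine agrees within Monte-Carlo error.  When
$\theta_3 = 0$ the NIE collapses to the familiar product of coefficients
$\theta_2 \beta_1$, which is also tested.

## The synthetic cohort generator

No individual-level data from the emulated study are distributable, so
the package ships a generator (`generate_cohort()`) whose defaults
(`default_generation_config()`) reproduce the *marginal* structure of the
published cohort of 1,680 women: category probabilities for income,
schooling, breastfeeding and birthweight; exposure probabilities
(0.245, 0.535, 0.220); a Beta-distributed African-ancestry proportion
(mean 0.16, SD 0.19); activity prevalence near 20%; and mediator models
whose exposure coefficients equal the published confounder-adjusted
estimates (e.g. +2.84 kg/m² fat mass index for menarche < 12 versus
≥ 14).  The outcome models are calibrated so the implied NDE and NIE of
diastolic blood pressure through fat mass index are 0.58 and 1.07 mmHg.
These are calibration targets describing a plausible population, not
claims about causal truth in the real cohort.

Generation follows the causal ordering C → A → L → M → Y, so every arrow
of the assumed causal diagram corresponds to a draw from a declared
model, and `true_effects()` can compute the exact estimands implied by
the generating coefficients.  Design choices worth knowing:

* **Exposure independent of C by default.** The published tables give
  only exposure marginals, and an independent exposure keeps the truth
  calculators simple.  A multinomial-logit dependence of A on C can be
  switched on (`exposure_dependence`) for confounding-robustness
  experiments.
* **One true mediator.** In the default process every outcome depends on
  fat mass index only; BMI and waist-to-hip ratio respond to the same
  exposure and confounders but do not enter outcome models.  Analyses
  that use them as the working mediator are therefore structurally valid
  but deliberately misspecified against the generating truth — useful
  for studying robustness, and the reason recovery tests use
  fat-mass-index analyses.
* **Log-normal outcomes.** Triglycerides and C-reactive protein are
  generated as `exp(linear predictor + Gaussian noise)`, matching their
  right-skewed empirical distributions; analyses log-transform them.
* **Positivity bounds.** BMI and fat mass index redraw their Gaussian
  noise below 0.1 kg/m² (fewer than 1% of draws at the default
  parameters).  The truth calculators ignore this truncation; the
  resulting bias is negligible at the defaults, and the slim
  configurations used by the oracle tests set no bounds so the closed
  forms are exact.
* **Missingness** is completely at random at a configurable rate
  (default 0: the emulated analysis table is already the complete-case
  set).  The pipeline's complete-case behaviour is what matters
  downstream, not the missingness mechanism.
* **Waist-to-hip ratio is on the ×100 scale** (e.g. 76.1), matching the
  scale on which the published coefficients for this mediator are
  interpretable.

What the generator does *not* emulate: longitudinal attrition,
measurement protocols, residual correlation between body-composition
measures beyond shared predictors, or any dependence of exposure on
confounders.  Passing recovery tests on these synthetic cohorts
demonstrates that the estimator recovers the estimands of its assumed
semiparametric model — not that the published point estimates are
reproducible, which would require the original data.

## Supporting analyses

`summarize_by_exposure()` reproduces per-category descriptive tables:
arithmetic means with t-based 95% CIs, geometric means (back-transformed
means of logs) for log-scale variables, and a between-category p-value.
The **linear-trend test** codes the ordered categories 0/1/2 (youngest
first; the source does not state its scores, and equally spaced scores
are the standard reading of a linear trend) and Wald-tests the slope; the
**heterogeneity test** is a one-way ANOVA F-test.  A constant outcome
returns p = 1 by convention.  For the adjusted regression table both
tests are computed on the confounder-adjusted model (ordinal-score Wald
test and joint F on the exposure dummies) — the source does not say
whether its footnote tests are crude or adjusted, so the crude versions
remain available through the descriptive functions.

`fit_adjusted_linear()` dummy-codes the exposure with `ge14` as
reference.  Confounder encodings mirror the published groupings: income,
schooling and breastfeeding as category dummies, birthweight in grams
and ancestry proportion continuous, and only African ancestry is used
for ancestry adjustment (the European proportion is nearly collinear
with it).  `prevalence_ratio_poisson_robust()` estimates prevalence
ratios for binary outcomes by log-link Poisson regression with HC0
sandwich variance.  `crp_exclusion_filter()` applies the C-reactive
protein analysis rules: CRP strictly above 10 mg/dl (acute
inflammation), pregnancy, recent postpartum, or oral-contraceptive use;
missing flags never exclude.

## Numerical choices and degenerate inputs

* **Exact collinearity** in any g-computation model is handled the way
  `lm()` handles aliasing: the offending columns are dropped
  (coefficient 0), which leaves predictions on the fitted column space
  unique.  This makes degenerate inputs (e.g. a constant mediator, whose
  interaction column is exactly collinear with the exposure) return the
  well-defined answer — zero effects with zero-width intervals — rather
  than erroring.  Non-estimable fits (too few rows, non-converged
  logistic models) do error; inside the bootstrap such replicates are
  dropped and counted, and more than 5% dropped aborts the run.
* **Null contrast** (`a == a_star`) short-circuits to exact zeros.
* **Seeds.** All randomness (simulation engine and bootstrap resampling)
  flows from `gcomp_config(seed = )`; identical seeds give bit-identical
  results.
* **Display rounding** is one decimal, half away from zero, matching the
  published tables; unrounded values are always retained.

## Problem sizes used in the test suite

The suite exercises the estimator at sizes chosen to make the
statistical assertions sharp while keeping a full run around half a
minute: oracle-equivalence checks on single cohorts of 3,000–5,000 rows;
parameter recovery over 200 cohorts of n = 2,000; bootstrap coverage
over 100 cohorts of n = 300 with 500 replications each; marginal
calibration at n = 100,000.  The acceptance script runs the full
pipeline at the emulated study's n = 1,680 with 400 bootstrap
replications; production analyses should use the 10,000-replication
default.

## A worked example

```{r example, eval = FALSE}
cfg <- default_generation_config(n = 1680)
cohort <- generate_cohort(cfg, seed = 1)

spec <- mediation_spec(
  mediator = "fat_mass_index", outcome = "dbp",
  base_confounders = c("family_income_cat", "household_score",
                       "maternal_schooling_cat", "maternal_smoking",
                       "birthweight_g", "breastfeeding_cat",
                       "african_ancestry"),
  post_confounders = c("active", "saturated_fat_pct"))

true_effects(cfg, spec)       # estimands implied by the generator
bootstrap_mediation(cohort, spec,
                    gcomp_config(bootstrap_reps = 1000, seed = 2))
```

## Known limitations

* Natural effects under exposure-induced confounding are reported as
  interventional analogues; no sensitivity analysis for unmeasured
  confounding is provided.
* Missing data are handled by complete-case analysis only.
* The mediator model is Gaussian-linear; heavy-tailed or heteroskedastic
  mediators are outside the fitted family.
* One mediator at a time: joint mediation by several body-composition
  measures is not decomposed.
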
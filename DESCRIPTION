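Package: gcmediate
Title: G-Computation Mediation Analysis for Birth-Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parametric g-formula (G-computation) estimation of natural
    direct, natural indirect and total causal effects of a categorical
    exposure acting through a continuous mediator, with exposure-mediator
    interaction, baseline confounders, exposure-induced (post-)
    confounders and percentile-bootstrap confidence intervals, together
    with the proportion-mediated summary.  Includes a configurable
    synthetic birth-cohort generator with closed-form true estimands for
    validation, per-exposure-category descriptive tables with linear-trend
    and heterogeneity tests, confounder-adjusted linear regression,
    robust-variance Poisson prevalence ratios, and a config-driven
    pipeline that emits table-style CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
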
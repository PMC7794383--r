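test_that("zero-noise data returns the generating coefficients exactly", {
  cfg <- generation_config(
    n = 400, exposure_probs = c(0.3, 0.5, 0.2),
    confounder_specs = list(z = list(type = "normal", mean = 0, sd = 1)),
    beta = list(med = list(b0 = 10, b1 = c(lt12 = 1, mid = 0.5),
                           b2 = c(z = 0.3), sd = 0)),
    theta = list(dbp = list(t0 = 73.1, t1 = c(lt12 = 1.98, mid = 0.67),
                            tm = c(med = 0), t4 = c(z = 0.5), sd = 0)))
  ch <- generate_cohort(cfg, seed = 31)
  fit <- fit_adjusted_linear(ch, "dbp", confounders = "z")
  expect_equal(unname(fit$coefficients["menarche_catlt12"]), 1.98,
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["menarche_catmid"]), 0.67,
               tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-8)
})

test_that("with no confounders the exposure coefficient is the difference in group means", {
  set.seed(32)
  df <- data.frame(
    menarche_cat = factor(sample(c("lt12", "ge14"), 80, TRUE),
                          levels = c("lt12", "mid", "ge14")),
    y = rnorm(80))
  fit <- fit_adjusted_linear(df, "y")
  diff_means <- mean(df$y[df$menarche_cat == "lt12"]) -
    mean(df$y[df$menarche_cat == "ge14"])
  expect_equal(unname(fit$coefficients["menarche_catlt12"]), diff_means,
               tolerance = 1e-10)
})

test_that("the log-outcome flag equals fitting the pre-logged outcome", {
  set.seed(33)
  df <- data.frame(
    menarche_cat = factor(sample(c("lt12", "mid", "ge14"), 120, TRUE),
                          levels = c("lt12", "mid", "ge14")),
    z = rnorm(120))
  df$tg <- exp(0.1 * (df$menarche_cat == "lt12") + 0.2 * df$z +
                 rnorm(120, 0, 0.3))
  df$log_tg <- log(df$tg)
  f1 <- fit_adjusted_linear(df, "tg", "z", log_outcome = TRUE)
  f2 <- fit_adjusted_linear(df, "log_tg", "z")
  expect_equal(unname(f1$coefficients), unname(f2$coefficients),
               tolerance = 1e-12)
  expect_identical(f1$outcome_transform, "log")
})

test_that("noisy simulation recovers the adjusted exposure coefficient on average", {
  cfg <- generation_config(
    n = 1680, exposure_probs = c(0.245, 0.535, 0.220),
    confounder_specs = list(z = list(type = "normal", mean = 0, sd = 1)),
    beta = list(med = list(b0 = 0, b1 = c(lt12 = 0, mid = 0), sd = 1)),
    theta = list(dbp = list(t0 = 73, t1 = c(lt12 = 1.98, mid = 0.67),
                            tm = c(med = 0), t4 = c(z = 1.2), sd = 9)))
  set.seed(34)
  ests <- replicate(200, {
    ch <- generate_cohort(cfg)
    fit_adjusted_linear(ch, "dbp", "z")$coefficients["menarche_catlt12"]
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1.98), 3 * mc_se)
})

test_that("complete-case filtering and rank-deficiency handling behave as declared", {
  set.seed(35)
  df <- data.frame(
    menarche_cat = factor(sample(c("lt12", "mid", "ge14"), 60, TRUE),
                          levels = c("lt12", "mid", "ge14")),
    z = rnorm(60), y = rnorm(60))
  df$y[1:5] <- NA
  df$z[6:8] <- NA
  fit <- fit_adjusted_linear(df, "y", "z")
  expect_equal(fit$n_used, sum(complete.cases(df)))

  df$z2 <- 2 * df$z  # exactly collinear
  expect_error(fit_adjusted_linear(df, "y", c("z", "z2")), "collinear")
})

test_that("the CRP exclusion filter applies each rule with a strict > 10 boundary", {
  toy <- data.frame(
    id = 1:5,
    crp = c(12, 3, 10, 2, 1),
    pregnant = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    postpartum_3m = FALSE,
    oral_contraceptive = FALSE)
  kept <- crp_exclusion_filter(toy)
  expect_equal(kept$id, c(3, 4, 5))  # crp = 10 retained, 12 and pregnant out
  expect_equal(nrow(crp_exclusion_filter(toy[0, ])), 0)

  # missing flags and missing crp are retained
  toy$pregnant[2] <- NA
  toy$crp[1] <- NA
  expect_equal(crp_exclusion_filter(toy)$id, 1:5)
})

test_that("robust Poisson prevalence ratios match saturated-table risk ratios", {
  toy <- data.frame(exposed = rep(c(1, 0), each = 20),
                    y = c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 15)))
  fit <- prevalence_ratio_poisson_robust(toy, "y", exposure = "exposed")
  pr <- fit$pr$pr[fit$pr$term == "exposed"]
  expect_equal(pr, 2.0, tolerance = 1e-8)

  toy$y_same <- rep(c(rep(1, 8), rep(0, 12)), 2)
  fit1 <- prevalence_ratio_poisson_robust(toy, "y_same", exposure = "exposed")
  expect_equal(fit1$pr$pr[fit1$pr$term == "exposed"], 1.0, tolerance = 1e-8)

  expect_error(prevalence_ratio_poisson_robust(
    data.frame(exposed = c(1, 0), y = c(2, 0)), "y", exposure = "exposed"),
    "0/1")
})

test_that("robust Poisson recovers a known log-prevalence-ratio with valid CI coverage", {
  set.seed(36)
  true_log_pr <- 0.4
  p0 <- 0.25
  ests <- numeric(200); cover <- 0L
  for (r in 1:200) {
    x <- rbinom(500, 1, 0.5)
    y <- rbinom(500, 1, p0 * exp(true_log_pr)^x)
    fit <- prevalence_ratio_poisson_robust(
      data.frame(x = x, y = y), "y", exposure = "x")
    i <- which(fit$pr$term == "x")
    ests[r] <- fit$pr$log_pr[i]
    if (log(fit$pr$lower[i]) <= true_log_pr &&
        log(fit$pr$upper[i]) >= true_log_pr) cover <- cover + 1L
  }
  expect_lt(abs(mean(ests) - true_log_pr), 3 * sd(ests) / sqrt(200))
  expect_gt(cover / 200, 0.90)
  expect_lt(cover / 200, 0.99)
})

test_that("overweight derivation uses the inclusive 25 kg/m^2 threshold", {
  expect_identical(derive_overweight(c(24.9, 25.0, 29.11, NA)),
                   c(FALSE, TRUE, TRUE, NA))
})
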
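test_that("closed_form_nde_nie reproduces the linear-system algebra", {
  # no interaction: product-of-coefficients limit
  cf <- closed_form_nde_nie(c(b0 = 3, b1 = 2), c(t1 = 1, t2 = 0.5, t3 = 0))
  expect_equal(unname(cf), c(1, 1))
  # direct substitution with interaction
  cf <- closed_form_nde_nie(c(b0 = 0, b1 = 2), c(t1 = 1, t2 = 0.5, t3 = 0.2))
  expect_equal(unname(cf), c(1, 1.4))
  # null contrast
  cf <- closed_form_nde_nie(c(b0 = 1, b1 = 2), c(t1 = 1, t2 = 0.5, t3 = 0.2),
                            a = 1, a_star = 1)
  expect_equal(unname(cf), c(0, 0))
  # arbitrary coefficients against an independent brute-force expectation
  set.seed(41)
  for (r in 1:5) {
    b <- c(b0 = rnorm(1), b1 = rnorm(1))
    th <- c(t1 = rnorm(1), t2 = rnorm(1), t3 = rnorm(1))
    cmu <- rnorm(1)
    z <- rnorm(2e5, cmu, 1)        # confounder contribution, mean cmu
    m0 <- b[["b0"]] + z + rnorm(2e5)
    m1 <- b[["b0"]] + b[["b1"]] + z + rnorm(2e5)
    yv <- function(a, m) th[["t1"]] * a + (th[["t2"]] + th[["t3"]] * a) * m
    mc <- c(mean(yv(1, m0) - yv(0, m0)), mean(yv(1, m1) - yv(1, m0)))
    se <- c(sd(yv(1, m0) - yv(0, m0)), sd(yv(1, m1) - yv(1, m0))) / sqrt(2e5)
    cf <- closed_form_nde_nie(b, th, c_mean = cmu)
    expect_lt(abs(cf[["nde"]] - mc[1]), 3 * se[1] + 1e-10)
    expect_lt(abs(cf[["nie"]] - mc[2]), 3 * se[2] + 1e-10)
  }
})

test_that("proportion_mediated follows the NIE/TCE formula with the opposite-sign rule", {
  expect_equal(attr(proportion_mediated(1.06, 3.50), "display"), 76.8)
  expect_equal(as.numeric(proportion_mediated(-0.78, 1.12)), 0)
  expect_equal(as.numeric(proportion_mediated(1.0, 0.0)), 0)
  expect_equal(as.numeric(proportion_mediated(0.0, 2.0)), 100)
  pm <- proportion_mediated(0.5, 1.5)
  expect_true(pm >= 0 && pm <= 100)
  expect_error(proportion_mediated(NA, 1))
})

test_that("the expectation engine equals the closed form at the fitted coefficients", {
  cfg <- slim_config(n = 3000)
  ch <- generate_cohort(cfg, seed = 51)
  sp <- slim_spec()
  est <- gcomp_point_estimate(ch, sp, gcomp_config(engine = "expectation"))

  # oracle: refit the two regressions directly and plug into the closed form
  d <- ch[ch$menarche_cat %in% c("lt12", "ge14") &
            complete.cases(ch[, c("menarche_cat", "med", "out", "z")]), ]
  d$a <- as.numeric(d$menarche_cat == "lt12")
  fm <- lm(med ~ a + z, data = d)
  fy <- lm(out ~ a * med + z, data = d)
  cf <- closed_form_nde_nie(
    c(b0 = coef(fm)[["(Intercept)"]], b1 = coef(fm)[["a"]]),
    c(t1 = coef(fy)[["a"]], t2 = coef(fy)[["med"]],
      t3 = coef(fy)[["a:med"]]),
    c_mean = coef(fm)[["z"]] * mean(d$z))
  expect_lt(abs(est[["nde"]] - cf[["nde"]]), 1e-8)
  expect_lt(abs(est[["nie"]] - cf[["nie"]]), 1e-8)
  expect_identical(est[["tce"]], est[["nde"]] + est[["nie"]])
})

test_that("without interaction and post-confounders NIE is the product of coefficients", {
  cfg <- slim_config(n = 2500, tam = 0)
  ch <- generate_cohort(cfg, seed = 52)
  sp <- slim_spec(interaction = FALSE)
  est <- gcomp_point_estimate(ch, sp, gcomp_config(engine = "expectation"))
  d <- ch[ch$menarche_cat %in% c("lt12", "ge14"), ]
  d$a <- as.numeric(d$menarche_cat == "lt12")
  prod_est <- coef(lm(med ~ a + z, d))[["a"]] *
    coef(lm(out ~ a + med + z, d))[["med"]]
  expect_lt(abs(est[["nie"]] - prod_est), 1e-8)
})

test_that("the simulation engine agrees with the expectation engine within MC error", {
  cfg <- slim_config(n = 5000)
  ch <- generate_cohort(cfg, seed = 53)
  sp <- slim_spec()
  exact <- gcomp_point_estimate(ch, sp, gcomp_config(engine = "expectation"))
  sims <- t(vapply(1:10, function(s) {
    gcomp_point_estimate(ch, sp, gcomp_config(mc_draws = 200, seed = 530 + 101 * s,
                                              engine = "simulation"))
  }, numeric(3)))
  for (col in c("nde", "nie")) {
    se_mean <- sd(sims[, col]) / sqrt(nrow(sims))
    expect_lt(abs(mean(sims[, col]) - exact[[col]]), 4 * se_mean + 1e-6)
  }
})

test_that("Monte-Carlo error shrinks as mc_draws grows", {
  cfg <- slim_config(n = 1500, with_L = TRUE)
  ch <- generate_cohort(cfg, seed = 54)
  sp <- slim_spec(with_L = TRUE)
  spread <- function(draws) {
    est <- vapply(1:8, function(s) {
      gcomp_point_estimate(ch, sp, gcomp_config(mc_draws = draws,
                                                seed = 540 + 37 * s,
                                                engine = "simulation"))[["nie"]]
    }, numeric(1))
    sd(est)
  }
  expect_lt(spread(1000), spread(10))
})

test_that("a null contrast returns exact zeros", {
  cfg <- slim_config(n = 500)
  ch <- generate_cohort(cfg, seed = 55)
  sp <- slim_spec(); sp$a_star <- sp$a
  est <- gcomp_point_estimate(ch, sp, gcomp_config())
  expect_identical(as.numeric(est), c(0, 0, 0))
})

test_that("bootstrap is reproducible, decomposes exactly, and handles degeneracy", {
  cfg <- slim_config(n = 400)
  ch <- generate_cohort(cfg, seed = 56)
  sp <- slim_spec()
  bc <- gcomp_config(bootstrap_reps = 100, seed = 99)
  e1 <- bootstrap_mediation(ch, sp, bc)
  e2 <- bootstrap_mediation(ch, sp, bc)
  expect_identical(e1$nde, e2$nde)
  expect_identical(e1$nie, e2$nie)
  expect_identical(e1$tce, e2$tce)
  # tce = nde + nie bit-exactly in every replicate
  expect_identical(e1$replicates[, "tce"],
                   e1$replicates[, "nde"] + e1$replicates[, "nie"])
  expect_equal(e1$reps_dropped, 0L)

  # degenerate table: outcome = mediator = constant -> zero-width CIs
  dg <- data.frame(
    menarche_cat = factor(rep(c("lt12", "ge14"), 20),
                          levels = c("lt12", "mid", "ge14")),
    z = rnorm(40), med = 5, out = 5)
  ed <- bootstrap_mediation(dg, sp, gcomp_config(bootstrap_reps = 50,
                                                 seed = 1))
  for (eff in list(ed$nde, ed$nie, ed$tce)) {
    expect_equal(unname(eff), c(0, 0, 0), tolerance = 1e-10)
    expect_lt(eff[["upper"]] - eff[["lower"]], 1e-10)  # zero-width CI
  }
})

test_that("interventional-analogue estimation with post-confounders recovers the truth", {
  cfg <- slim_config(n = 4000, with_L = TRUE)
  sp <- slim_spec(with_L = TRUE)
  tr <- true_effects(cfg, sp)
  set.seed(57)
  ests <- t(vapply(1:30, function(r) {
    ch <- generate_cohort(cfg)
    gcomp_point_estimate(ch, sp, gcomp_config(mc_draws = 50,
                                              engine = "simulation"))
  }, numeric(3)))
  for (col in c("nde", "nie")) {
    se <- sd(ests[, col]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, col]) - tr[[col]]), 3 * se)
  }
})

test_that("log-scale outcomes are analysed and reported on the log scale", {
  cfg <- slim_config(n = 3000, t0 = 0.5, t1 = 0.1, tm = 0.05, tam = 0.01,
                     sd_y = 0.4)
  cfg$log_scale_outcomes <- "out"
  ch <- generate_cohort(cfg, seed = 58)
  expect_true(all(ch$out > 0))
  sp <- slim_spec(); sp$log_outcome <- TRUE
  tr <- true_effects(cfg, sp)  # theta is the log-scale model
  est <- gcomp_point_estimate(ch, sp, gcomp_config(engine = "expectation"))
  expect_lt(abs(est[["nie"]] - tr$nie), 0.05)
})
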
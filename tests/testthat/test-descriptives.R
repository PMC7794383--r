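test_that("category_prevalence reproduces printed percentages and keeps unrounded values", {
  p <- category_prevalence(c(lt12 = 411, mid = 899, ge14 = 370))
  expect_equal(unname(attr(p, "display")), c(24.5, 53.5, 22.0))
  expect_equal(sum(p), 100)
  expect_equal(unname(p)[1], 100 * 411 / 1680)

  expect_equal(as.numeric(category_prevalence(c(1, 1))), c(50, 50))
  expect_error(category_prevalence(c(0, 0)), "positive sum")
  expect_error(category_prevalence(numeric(0)), "non-empty")
})

test_that("summaries give arithmetic or geometric means with t-based CIs", {
  df <- data.frame(
    menarche_cat = factor(rep(c("lt12", "mid", "ge14"), each = 4),
                          levels = c("lt12", "mid", "ge14")),
    const = 5,
    pos = c(2, 8, 2, 8, 2, 8, 2, 8, 2, 8, 2, 8))
  s <- summarize_by_exposure(df, "const")
  expect_true(all(s$categories$estimate == 5))
  expect_true(all(s$categories$upper - s$categories$lower == 0))
  expect_equal(s$p_value, 1)  # constant outcome convention

  g <- summarize_by_exposure(df, "pos", transform = "log")
  expect_equal(g$categories$estimate, rep(4, 3))  # exp(mean(log(c(2,8))))

  # geometric mean <= arithmetic mean for any positive sample (AM-GM)
  set.seed(1)
  df2 <- data.frame(menarche_cat = df$menarche_cat,
                    x = exp(rnorm(12)))
  am <- summarize_by_exposure(df2, "x")$categories$estimate
  gm <- summarize_by_exposure(df2, "x", transform = "log")$categories$estimate
  expect_true(all(gm <= am + 1e-12))

  expect_error(summarize_by_exposure(df[1:5, ], "pos"), "fewer than 2")
})

test_that("summary means recover configured category means at scale", {
  # diastolic-pressure-like category means with small noise
  cfg <- generation_config(
    n = 1e5, exposure_probs = c(0.245, 0.535, 0.220),
    confounder_specs = list(z = list(type = "normal", mean = 0, sd = 1)),
    beta = list(med = list(b0 = 0, b1 = c(lt12 = 0, mid = 0), sd = 1)),
    theta = list(out = list(t0 = 73.1, t1 = c(lt12 = 2.0, mid = 0.7),
                            tm = c(med = 0), sd = 2)))
  ch <- generate_cohort(cfg, seed = 21)
  s <- summarize_by_exposure(ch, "out")
  target <- c(lt12 = 75.1, mid = 73.8, ge14 = 73.1)
  for (lv in names(target)) {
    row <- s$categories[s$categories$level == lv, ]
    se <- 2 / sqrt(row$n)
    expect_lt(abs(row$estimate - target[[lv]]), 3 * se)
    expect_true(row$lower <= row$estimate && row$estimate <= row$upper)
  }
})

test_that("linear trend test detects perfect trends and is calibrated under the null", {
  lv <- factor(rep(c("lt12", "mid", "ge14"), each = 10),
               levels = c("lt12", "mid", "ge14"))
  score <- as.numeric(lv) - 1
  # noiseless perfect trend: slope -1, p numerically 0
  p <- linear_trend_test(data.frame(menarche_cat = lv, y = 2 - score), "y")
  expect_lt(p, 1e-12)

  # two categories, equal means
  df2 <- data.frame(menarche_cat = droplevels(lv[lv != "mid"]),
                    y = rep(c(1, 2), 10))
  expect_gt(linear_trend_test(df2, "y"), 0.99)

  # permutation null: rejection rate at alpha = 0.05 within (0.02, 0.09)
  set.seed(10)
  n <- 200
  base <- data.frame(menarche_cat = factor(
    sample(c("lt12", "mid", "ge14"), n, TRUE),
    levels = c("lt12", "mid", "ge14")))
  y <- rnorm(n)
  rej <- 0L
  for (r in 1:200) {
    base$y <- sample(y)
    if (linear_trend_test(base, "y") < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 200, 0.02)
  expect_lt(rej / 200, 0.09)
})

test_that("heterogeneity test is a one-way ANOVA with the expected behaviour", {
  set.seed(11)
  lv3 <- factor(sample(c("lt12", "mid", "ge14"), 150, TRUE),
                levels = c("lt12", "mid", "ge14"))
  y <- rnorm(150)
  y[lv3 == "lt12"] <- y[lv3 == "lt12"] + 10  # one category shifted by 10 SD
  expect_lt(heterogeneity_test(data.frame(menarche_cat = lv3, y = y), "y"),
            1e-12)

  # with two categories F equals the squared two-sample t statistic
  df2 <- data.frame(menarche_cat = droplevels(lv3[lv3 != "mid"]),
                    y = rnorm(sum(lv3 != "mid")))
  p_f <- heterogeneity_test(df2, "y")
  tt <- t.test(y ~ menarche_cat, data = df2, var.equal = TRUE)
  expect_equal(p_f, tt$p.value, tolerance = 1e-10)

  # null calibration at alpha = 0.05 over 200 replicates
  set.seed(12)
  rej <- 0L
  for (r in 1:200) {
    d <- data.frame(menarche_cat = lv3, y = rnorm(150))
    if (heterogeneity_test(d, "y") < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 200, 0.02)
  expect_lt(rej / 200, 0.09)

  expect_error(
    heterogeneity_test(data.frame(menarche_cat = factor(c("lt12", "mid",
                                                          "mid")),
                                  y = c(1, 2, 3)), "y"),
    "lt12")
})

test_that("trend and heterogeneity tests are invariant to affine outcome rescaling", {
  set.seed(13)
  df <- data.frame(menarche_cat = factor(
    sample(c("lt12", "mid", "ge14"), 120, TRUE),
    levels = c("lt12", "mid", "ge14")), y = rnorm(120))
  df$y2 <- 3 * df$y - 7
  expect_equal(linear_trend_test(df, "y"), linear_trend_test(df, "y2"),
               tolerance = 1e-10)
  expect_equal(heterogeneity_test(df, "y"), heterogeneity_test(df, "y2"),
               tolerance = 1e-10)
})
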
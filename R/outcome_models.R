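#' Confounder-adjusted linear regression on exposure categories
#'
#' Fits `outcome ~ exposure + confounders` by ordinary least squares on
#' complete cases, dummy-coding the age-at-menarche exposure with the
#' oldest category (`ge14`) as reference, so the reported coefficients are
#' the adjusted mean differences for menarche `< 12` and `12-13` years
#' versus `>= 14`.  Right-skewed outcomes can be log-transformed first, in
#' which case coefficients stay on the log scale.
#'
#' @param table cohort `data.frame`.
#' @param outcome outcome column name.
#' @param confounders character vector of confounder column names (may be
#'   empty).
#' @param log_outcome log-transform the outcome before fitting.
#' @param exposure exposure column name.
#' @param reference exposure reference level (default `"ge14"`).
#' @param conf_level confidence level for coefficient CIs.
#' @return an object of class `cohort_fit`: list with `coefficients`,
#'   `vcov`, `ci`, `residual_sd`, `n_used`, `outcome_transform`, and the
#'   trend/heterogeneity p-values from the adjusted model (`p_trend`:
#'   Wald test on the ordinal exposure score; `p_heterogeneity`: joint F
#'   on the exposure dummies).
#' @export
fit_adjusted_linear <- function(table, outcome, confounders = character(),
                                log_outcome = FALSE,
                                exposure = "menarche_cat",
                                reference = "ge14",
                                conf_level = 0.95) {
  vars <- c(outcome, exposure, confounders)
  miss <- setdiff(vars, names(table))
  if (length(miss)) {
    stop(sprintf("column(s) not found: %s", paste(miss, collapse = ", ")))
  }
  dat <- table[, vars, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  a <- droplevels(as.factor(dat[[exposure]]))
  dat[[exposure]] <- stats::relevel(a, ref = reference)
  y <- dat[[outcome]]
  if (log_outcome) {
    if (any(y <= 0)) stop("log transform requires strictly positive outcome")
    dat[[outcome]] <- log(y)
  }
  for (v in confounders) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  }
  p_needed <- nlevels(dat[[exposure]]) + length(confounders) + 1
  if (nrow(dat) < p_needed + 2) {
    stop("too few complete cases for the requested model")
  }
  form <- stats::reformulate(c(exposure, confounders), response = outcome)
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit)))) {
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }

  # trend: ordinal score 0/1/2 in category order replacing the dummies
  # (`a` keeps the original youngest-first level order, before releveling)
  tdat <- dat
  tdat$..score <- as.numeric(a) - 1
  p_trend <- tryCatch({
    tfit <- lm(stats::reformulate(c("..score", confounders),
                                  response = outcome), data = tdat)
    # suppressWarnings: zero-noise fits trip the perfect-fit warning
    suppressWarnings(summary(tfit)$coefficients["..score", "Pr(>|t|)"])
  }, error = function(e) NA_real_)
  # heterogeneity: joint F for the exposure dummies in the adjusted model
  p_het <- tryCatch({
    null_fit <- lm(stats::reformulate(if (length(confounders)) confounders
                                      else "1", response = outcome),
                   data = dat)
    suppressWarnings(anova(null_fit, fit)[["Pr(>F)"]][2])
  }, error = function(e) NA_real_)

  # vcov/confint route through summary.lm, which warns on perfect fits
  structure(list(coefficients = coef(fit),
                 vcov = suppressWarnings(vcov(fit)),
                 ci = suppressWarnings(confint(fit, level = conf_level)),
                 residual_sd = suppressWarnings(summary(fit)$sigma),
                 n_used = nrow(dat),
                 outcome_transform = if (log_outcome) "log" else "identity",
                 p_trend = p_trend,
                 p_heterogeneity = p_het,
                 exposure = exposure,
                 reference = reference),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("Adjusted model (%s outcome, n = %d, reference = %s)\n",
              x$outcome_transform, x$n_used, x$reference %||% "-"))
  tab <- cbind(estimate = x$coefficients, x$ci)
  print(round(tab, 4))
  if (!is.null(x$p_trend)) {
    cat(sprintf("trend p = %s, heterogeneity p = %s\n",
                format.pval(x$p_trend, digits = 3),
                format.pval(x$p_heterogeneity, digits = 3)))
  }
  invisible(x)
}

#' Exclusion filter for the C-reactive-protein analysis
#'
#' Drops rows with CRP above 10 mg/dl (acute inflammation; the boundary
#' value 10 is retained), pregnant women, women three months or less
#' postpartum, and oral-contraceptive users.  Missing flags are treated as
#' not excluded; missing CRP is retained.  Row order is preserved.
#'
#' @param table cohort `data.frame` with columns `crp`, `pregnant`,
#'   `postpartum_3m`, `oral_contraceptive`.
#' @return the filtered `data.frame` (a subset of the input rows).
#' @export
crp_exclusion_filter <- function(table) {
  flag <- function(nm) {
    if (!nm %in% names(table)) return(rep(FALSE, nrow(table)))
    f <- table[[nm]]
    if (!is.logical(f)) f <- f == 1
    f & !is.na(f)
  }
  crp_high <- if ("crp" %in% names(table)) {
    !is.na(table$crp) & table$crp > 10
  } else rep(FALSE, nrow(table))
  keep <- !crp_high & !flag("pregnant") & !flag("postpartum_3m") &
    !flag("oral_contraceptive")
  table[keep, , drop = FALSE]
}

#' Prevalence ratios by Poisson regression with robust variance
#'
#' Fits a log-link Poisson model to a binary outcome and replaces the
#' model-based variance with the heteroskedasticity-consistent (HC0)
#' sandwich estimate, the standard device for estimating prevalence
#' ratios from cross-sectional data.  Exponentiated coefficients are
#' prevalence ratios.
#'
#' @param table cohort `data.frame`.
#' @param binary_outcome name of a 0/1 (or logical) outcome column.
#' @param confounders character vector of adjustment columns (may be
#'   empty).
#' @param exposure exposure column name; categorical exposures are
#'   dummy-coded with `reference` as baseline.
#' @param reference reference level for a categorical exposure (ignored
#'   for numeric exposures).
#' @param conf_level confidence level.
#' @return a `cohort_fit` whose `pr` element tabulates prevalence ratios
#'   with robust CIs; `vcov` is the sandwich estimate on the log scale.
#' @export
prevalence_ratio_poisson_robust <- function(table, binary_outcome,
                                            confounders = character(),
                                            exposure = "menarche_cat",
                                            reference = "ge14",
                                            conf_level = 0.95) {
  vars <- c(binary_outcome, exposure, confounders)
  dat <- table[, vars, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  y <- dat[[binary_outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stop(sprintf("outcome '%s' must be coded 0/1", binary_outcome))
  }
  dat[[binary_outcome]] <- y
  ex <- dat[[exposure]]
  if (is.character(ex) || is.factor(ex)) {
    ex <- droplevels(as.factor(ex))
    if (reference %in% levels(ex)) ex <- stats::relevel(ex, ref = reference)
    dat[[exposure]] <- ex
  }
  form <- stats::reformulate(c(exposure, confounders),
                             response = binary_outcome)
  fit <- glm(form, data = dat, family = stats::poisson())
  vc <- sandwich::vcovHC(fit, type = "HC0")
  est <- coef(fit)
  se <- sqrt(diag(vc))
  z <- qnorm(1 - (1 - conf_level) / 2)
  pr <- data.frame(term = names(est),
                   log_pr = unname(est),
                   pr = exp(unname(est)),
                   lower = exp(unname(est) - z * se),
                   upper = exp(unname(est) + z * se),
                   p_value = 2 * pnorm(-abs(unname(est) / se)))
  structure(list(coefficients = est, vcov = vc, pr = pr,
                 residual_sd = NA_real_, n_used = nrow(dat),
                 outcome_transform = "log-link",
                 exposure = exposure, reference = reference),
            class = "cohort_fit")
}

#' Overweight indicator from BMI
#'
#' Overweight is body mass index of at least 25 kg/m^2 (boundary
#' inclusive).  Missing BMI yields a missing indicator.
#'
#' @param bmi numeric vector of BMI values (kg/m^2).
#' @return logical vector.
#' @export
derive_overweight <- function(bmi) {
  ifelse(is.na(bmi), NA, bmi >= 25)
}
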
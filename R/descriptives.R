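#' Category prevalences from counts
#'
#' Converts a vector of category counts into percentages of the total.
#' The unrounded values are returned; a `display` attribute carries the
#' one-decimal, half-away-from-zero rounding used in printed tables.
#'
#' @param counts non-empty vector of non-negative integers with positive sum.
#' @return numeric vector of percentages (same names as `counts`), with
#'   attribute `display`.
#' @examples
#' category_prevalence(c(lt12 = 411, mid = 899, ge14 = 370))
#' @export
category_prevalence <- function(counts) {
  if (!length(counts)) stop("counts must be non-empty")
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("counts must have a positive sum")
  pct <- 100 * counts / tot
  attr(pct, "display") <- round_half_up(pct, 1)
  pct
}

#' Per-exposure-category summary of one variable
#'
#' Summarises a cohort variable within each age-at-menarche category:
#' arithmetic mean with a t-based 95% confidence interval, or — for
#' right-skewed variables flagged `transform = "log"` — the geometric mean
#' (back-transformed mean of logs) with a back-transformed CI.  Rows with
#' a missing exposure or variable value are dropped.  A between-category
#' p-value from either the linear-trend or the heterogeneity (one-way
#' ANOVA) test is attached.
#'
#' @param table a cohort `data.frame`.
#' @param variable column name to summarise.
#' @param transform `"identity"` or `"log"`.
#' @param test `"heterogeneity"` (default) or `"trend"`.
#' @param exposure exposure column name (factor, category order youngest
#'   first).
#' @param conf_level confidence level for the category CIs.
#' @return an object of class `descriptive_row`: list with `variable`,
#'   `transform`, `test_kind`, `p_value`, and `categories` (data frame
#'   with `level`, `n`, `estimate`, `lower`, `upper`).
#' @export
summarize_by_exposure <- function(table, variable,
                                  transform = c("identity", "log"),
                                  test = c("heterogeneity", "trend"),
                                  exposure = "menarche_cat",
                                  conf_level = 0.95) {
  transform <- match.arg(transform)
  test <- match.arg(test)
  if (!variable %in% names(table)) {
    stop(sprintf("variable '%s' not found", variable))
  }
  x <- table[[variable]]
  a <- droplevels(as.factor(table[[exposure]]))
  keep <- !is.na(x) & !is.na(a)
  x <- x[keep]; a <- droplevels(a[keep])
  if (transform == "log") {
    if (any(x <= 0)) stop("log transform requires strictly positive values")
    x <- log(x)
  }
  levs <- levels(a)
  rows <- lapply(levs, function(lv) {
    xi <- x[a == lv]
    if (length(xi) < 2) {
      stop(sprintf("exposure category '%s' has fewer than 2 observations", lv))
    }
    m <- mean(xi)
    se <- sd(xi) / sqrt(length(xi))
    tcrit <- qt(1 - (1 - conf_level) / 2, length(xi) - 1)
    est <- c(m, m - tcrit * se, m + tcrit * se)
    if (transform == "log") est <- exp(est)
    data.frame(level = lv, n = length(xi), estimate = est[1],
               lower = est[2], upper = est[3])
  })
  # x is already on the analysis (possibly log) scale here
  p <- if (test == "trend") {
    linear_trend_test(data.frame(y = x, a = a), "y", exposure = "a")
  } else {
    heterogeneity_test(data.frame(y = x, a = a), "y", exposure = "a")
  }
  structure(list(variable = variable, transform = transform,
                 test_kind = test, p_value = p,
                 categories = do.call(rbind, rows)),
            class = "descriptive_row")
}

#' @export
print.descriptive_row <- function(x, ...) {
  cat(sprintf("%s [%s]  %s test p = %s\n", x$variable, x$transform,
              x$test_kind, format.pval(x$p_value, digits = 3)))
  df <- x$categories
  df$estimate <- round_half_up(df$estimate, 2)
  df$lower <- round_half_up(df$lower, 2)
  df$upper <- round_half_up(df$upper, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Linear-trend test across ordered exposure categories
#'
#' Codes the exposure categories as equally spaced ordinal scores
#' (youngest category = 0), regresses the outcome on the score, and
#' returns the two-sided Wald p-value for the slope.  A constant outcome
#' returns p = 1 by convention; a perfect noiseless trend returns p = 0.
#'
#' @param table cohort `data.frame`.
#' @param outcome outcome column name.
#' @param exposure exposure column name (factor; level order defines the
#'   scores).
#' @param log_outcome log-transform the outcome first.
#' @return p-value in \[0, 1\].
#' @export
linear_trend_test <- function(table, outcome, exposure = "menarche_cat",
                              log_outcome = FALSE) {
  a <- droplevels(as.factor(table[[exposure]]))
  y <- table[[outcome]]
  keep <- !is.na(y) & !is.na(a)
  y <- y[keep]; a <- droplevels(a[keep])
  if (log_outcome) y <- log(y)
  if (nlevels(a) < 2) stop("exposure must have at least 2 observed levels")
  score <- as.numeric(a) - 1
  if (sd(y) == 0) return(1)
  fit <- lm(y ~ score)
  # a noiseless perfect trend is valid input; avoid the perfect-fit warning
  cf <- suppressWarnings(summary(fit)$coefficients)
  slope <- cf["score", "Estimate"]
  se <- cf["score", "Std. Error"]
  if (!is.finite(se) || se == 0) {
    return(if (slope == 0) 1 else 0)
  }
  unname(cf["score", "Pr(>|t|)"])
}

#' Heterogeneity (one-way ANOVA) test across exposure categories
#'
#' Compares outcome means across the exposure categories with a one-way
#' analysis-of-variance F test.
#'
#' @inheritParams linear_trend_test
#' @return p-value in \[0, 1\].
#' @export
heterogeneity_test <- function(table, outcome, exposure = "menarche_cat",
                               log_outcome = FALSE) {
  a <- droplevels(as.factor(table[[exposure]]))
  y <- table[[outcome]]
  keep <- !is.na(y) & !is.na(a)
  y <- y[keep]; a <- droplevels(a[keep])
  if (log_outcome) y <- log(y)
  cnt <- vapply(levels(a), function(l) sum(a == l), integer(1))
  if (any(cnt < 2)) {
    stop(sprintf("category '%s' has fewer than 2 observations",
                 names(cnt)[which(cnt < 2)[1]]))
  }
  if (sd(y) == 0) return(1)
  av <- anova(lm(y ~ a))
  p <- av[["Pr(>F)"]][1]
  if (!is.finite(p)) p <- 0  # zero residual variance with group differences
  p
}

#' Table-2-style descriptive report
#'
#' Applies [summarize_by_exposure()] to a set of variables and stacks the
#' results into one data frame suitable for CSV export.
#'
#' @param table cohort `data.frame`.
#' @param variables character vector of column names.
#' @param log_variables subset of `variables` to summarise on the log
#'   scale (geometric means) and test as trend on logs.
#' @param tests named character vector mapping variables to
#'   `"trend"`/`"heterogeneity"`; unnamed default `"heterogeneity"`.
#' @param exposure exposure column name.
#' @return data frame with one row per variable x category plus the test
#'   p-value repeated within variable.
#' @export
descriptive_table <- function(table, variables,
                              log_variables = character(),
                              tests = NULL,
                              exposure = "menarche_cat") {
  rows <- lapply(variables, function(v) {
    tr <- if (v %in% log_variables) "log" else "identity"
    tk <- if (!is.null(tests) && v %in% names(tests)) tests[[v]]
          else "heterogeneity"
    dr <- summarize_by_exposure(table, v, transform = tr, test = tk,
                                exposure = exposure)
    cbind(variable = v, transform = tr, dr$categories,
          test_kind = dr$test_kind, p_value = dr$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
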
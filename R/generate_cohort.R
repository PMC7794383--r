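#' Generate a synthetic cohort table
#'
#' Draws a cohort of `config$n` women following the causal ordering
#' C -> A -> L -> M -> Y: baseline confounders first, then the
#' age-at-menarche exposure, post-confounders (physical activity, dietary
#' saturated fat), body-composition mediators, and finally the
#' cardiometabolic outcomes, each from the parametric model declared in
#' `config`.  Outcomes listed in `config$log_scale_outcomes` are generated
#' log-normally.  Exclusion flags (pregnancy, recent postpartum, oral
#' contraceptive use) and completely-at-random missingness are applied
#' last.
#'
#' Identical `(config, seed)` pairs yield bit-identical tables.
#'
#' @param config a [generation_config()].
#' @param seed integer seed; defaults to `config$seed`.  When both are
#'   `NULL` the current RNG state is used.
#' @return a `data.frame` (class `cohort_table`) with one row per woman:
#'   `id`, confounder columns, `menarche_cat` (factor `lt12`/`mid`/`ge14`),
#'   post-confounder columns, mediator columns, outcome columns and the
#'   logical flags `pregnant`, `postpartum_3m`, `oral_contraceptive`.
#' @examples
#' cohort <- generate_cohort(default_generation_config(n = 500), seed = 1)
#' table(cohort$menarche_cat)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_generation_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n

  ## baseline confounders
  C <- draw_confounders(config$confounder_specs, n)
  Xc <- expand_confounders(C, config$confounder_specs)

  ## exposure
  A <- draw_exposure(config, Xc, n)
  Adum <- cbind(lt12 = as.numeric(A == "lt12"),
                mid = as.numeric(A == "mid"))

  ## post-confounders
  Lmat <- matrix(numeric(0), nrow = n, ncol = 0)
  for (nm in names(config$alpha_L)) {
    al <- config$alpha_L[[nm]]
    lp <- al$a0 + lp_from(al$a1, Adum) + lp_from(al$a2, Xc)
    x <- if (al$type == "binary") rbinom(n, 1, plogis(lp))
         else rnorm(n, lp, al$sd)
    Lmat <- cbind(Lmat, x)
    colnames(Lmat)[ncol(Lmat)] <- nm
  }

  ## mediators
  Mmat <- matrix(numeric(0), nrow = n, ncol = 0)
  for (nm in names(config$beta)) {
    b <- config$beta[[nm]]
    lp <- b$b0 + lp_from(b$b1, Adum) + lp_from(b$b2, Xc) + lp_from(b$bL, Lmat)
    m <- lp + rnorm(n, 0, b$sd)
    lower <- b$lower %||% -Inf
    # positivity bound enforced by redrawing noise (rejection sampling)
    while (any(bad <- m < lower)) {
      m[bad] <- lp[bad] + rnorm(sum(bad), 0, b$sd)
    }
    Mmat <- cbind(Mmat, m)
    colnames(Mmat)[ncol(Mmat)] <- nm
  }

  ## outcomes
  Ymat <- matrix(numeric(0), nrow = n, ncol = 0)
  for (nm in names(config$theta)) {
    th <- config$theta[[nm]]
    lp <- th$t0 + lp_from(th$t1, Adum) + lp_from(th$tm, Mmat) +
      lp_from(th$t4, Xc) + lp_from(th$tL, Lmat)
    for (m in names(th$tam)) {
      lp <- lp + lp_from(th$tam[[m]], Adum) * Mmat[, m]
    }
    y <- lp + rnorm(n, 0, th$sd)
    if (nm %in% config$log_scale_outcomes) y <- exp(y)
    Ymat <- cbind(Ymat, y)
    colnames(Ymat)[ncol(Ymat)] <- nm
  }

  er <- config$exclusion_rates
  out <- data.frame(id = sprintf("w%05d", seq_len(n)), C,
                    menarche_cat = A, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (mat in list(Lmat, Mmat, Ymat)) {
    if (ncol(mat)) out[colnames(mat)] <- as.data.frame(mat)
  }
  out$pregnant <- rbinom(n, 1, er$pregnant %||% 0) == 1
  out$postpartum_3m <- rbinom(n, 1, er$postpartum_3m %||% 0) == 1
  out$oral_contraceptive <- rbinom(n, 1, er$oral_contraceptive %||% 0) == 1

  miss <- er$missing %||% 0
  if (miss > 0) {
    for (nm in c("menarche_cat", colnames(Mmat), colnames(Ymat))) {
      out[[nm]][runif(n) < miss] <- NA
    }
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

draw_confounders <- function(specs, n) {
  C <- data.frame(row.names = seq_len(n))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    C[[nm]] <- switch(
      sp$type,
      categorical = factor(sample(sp$levels, n, replace = TRUE,
                                  prob = sp$probs), levels = sp$levels),
      binary = rbinom(n, 1, sp$p),
      normal = {
        x <- rnorm(n, sp$mean, sp$sd)
        lo <- sp$lower %||% -Inf; hi <- sp$upper %||% Inf
        while (any(bad <- x < lo | x > hi)) {
          x[bad] <- rnorm(sum(bad), sp$mean, sp$sd)
        }
        x
      },
      beta = {
        pr <- beta_shapes(sp$mean, sp$sd)
        rbeta(n, pr[1], pr[2])
      })
  }
  C
}

# Method-of-moments Beta shapes for a mean/SD parameterisation.
beta_shapes <- function(mean, sd) {
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) stop_config("beta confounder", "sd too large for mean")
  c(mean * nu, (1 - mean) * nu)
}

# Deterministic dummy expansion matching confounder_columns().
expand_confounders <- function(C, specs) {
  cols <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (identical(sp$type, "categorical")) {
      for (lvl in sp$levels[-1]) {
        cols[[paste0(nm, "_", lvl)]] <- as.numeric(C[[nm]] == lvl)
      }
    } else {
      cols[[nm]] <- as.numeric(C[[nm]])
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow = nrow(C), ncol = 0))
  do.call(cbind, cols)
}

draw_exposure <- function(config, Xc, n) {
  p <- config$exposure_probs
  if (is.null(config$exposure_dependence)) {
    lv <- sample(menarche_levels, n, replace = TRUE, prob = p)
  } else {
    # multinomial logit around the marginal log-odds vs the reference
    eta <- cbind(lt12 = rep(log(p[1] / p[3]), n),
                 mid = rep(log(p[2] / p[3]), n))
    for (lvl in names(config$exposure_dependence)) {
      eta[, lvl] <- eta[, lvl] + lp_from(config$exposure_dependence[[lvl]], Xc)
    }
    w <- cbind(exp(eta), 1)
    w <- w / rowSums(w)
    u <- runif(n)
    idx <- 1L + (u > w[, 1]) + (u > w[, 1] + w[, 2])
    lv <- menarche_levels[idx]
  }
  factor(lv, levels = menarche_levels)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Synthetic cohort table: %d rows, %d columns\n",
              nrow(x), ncol(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
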
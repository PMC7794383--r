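#' Define a mediation analysis
#'
#' Names the variables playing each causal role and the exposure contrast.
#' The default contrast compares menarche before 12 years (`a = "lt12"`)
#' against the reference of 14 years or later (`a_star = "ge14"`); rows at
#' the intermediate level are discarded for estimation.  An alternative
#' contrast (e.g. `lt12` versus everyone else) can be requested by
#' recoding the exposure column beforehand.
#'
#' @param mediator mediator column name (continuous, e.g. `bmi`,
#'   `fat_mass_index`, `waist_hip_ratio`).
#' @param outcome outcome column name.
#' @param base_confounders character vector of baseline confounders C.
#' @param post_confounders character vector of exposure-induced
#'   mediator-outcome confounders L (may be empty).  When non-empty the
#'   estimated effects are the randomized-interventional analogues of
#'   natural effects.
#' @param exposure exposure column name.
#' @param a active exposure level.
#' @param a_star reference exposure level.  `a == a_star` defines the null
#'   contrast, for which all effects are exactly zero.
#' @param interaction include the exposure-by-mediator product in the
#'   outcome model (default `TRUE`).
#' @param log_outcome analyse the outcome on the log scale; effects are
#'   then reported on the log scale and never back-transformed.
#' @return an object of class `mediation_spec`.
#' @export
mediation_spec <- function(mediator, outcome,
                           base_confounders = character(),
                           post_confounders = character(),
                           exposure = "menarche_cat",
                           a = "lt12", a_star = "ge14",
                           interaction = TRUE, log_outcome = FALSE) {
  roles <- list(exposure = exposure, mediator = mediator, outcome = outcome)
  all_vars <- c(unlist(roles), base_confounders, post_confounders)
  if (anyDuplicated(all_vars)) {
    stop("exposure, mediator, outcome, confounders and post-confounders ",
         "must be mutually disjoint")
  }
  structure(list(exposure = exposure, a = a, a_star = a_star,
                 mediator = mediator, outcome = outcome,
                 base_confounders = base_confounders,
                 post_confounders = post_confounders,
                 interaction = isTRUE(interaction),
                 log_outcome = isTRUE(log_outcome)),
            class = "mediation_spec")
}

#' G-computation settings
#'
#' @param bootstrap_reps number of bootstrap replications (default 10000,
#'   the convention for percentile intervals in this design; reduce for
#'   exploratory runs).
#' @param mc_draws Monte-Carlo draws per subject in the simulation engine.
#' @param seed integer seed controlling the bootstrap resampling and all
#'   simulation-engine draws.
#' @param ci_level confidence level for the percentile intervals.
#' @param engine `"auto"` (expectation when no post-confounders, else
#'   simulation), `"expectation"` (deterministic plug-in of conditional
#'   means; valid only with no post-confounders and linear models) or
#'   `"simulation"` (full Monte-Carlo g-formula).
#' @return an object of class `gcomp_config`.
#' @export
gcomp_config <- function(bootstrap_reps = 10000, mc_draws = 50,
                         seed = NULL, ci_level = 0.95,
                         engine = c("auto", "expectation", "simulation")) {
  engine <- match.arg(engine)
  if (bootstrap_reps < 1) stop("bootstrap_reps must be >= 1")
  if (mc_draws < 1) stop("mc_draws must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  structure(list(bootstrap_reps = as.integer(bootstrap_reps),
                 mc_draws = as.integer(mc_draws), seed = seed,
                 ci_level = ci_level, engine = engine),
            class = "gcomp_config")
}

# ---- internal machinery -------------------------------------------------

# Assemble the complete-case analysis set and all model design matrices.
gcomp_prepare <- function(table, spec) {
  vars <- c(spec$exposure, spec$mediator, spec$outcome,
            spec$base_confounders, spec$post_confounders)
  miss <- setdiff(vars, names(table))
  if (length(miss)) {
    stop(sprintf("column(s) not found: %s", paste(miss, collapse = ", ")))
  }
  dat <- as.data.frame(table)[, vars, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  A <- as.character(dat[[spec$exposure]])
  keep <- A %in% c(spec$a, spec$a_star)
  dat <- dat[keep, , drop = FALSE]
  A <- A[keep]
  n <- nrow(dat)

  a01 <- as.numeric(A == spec$a)
  m <- as.numeric(dat[[spec$mediator]])
  y <- as.numeric(dat[[spec$outcome]])
  if (spec$log_outcome) {
    if (any(y <= 0)) stop("log_outcome requires a strictly positive outcome")
    y <- log(y)
  }
  Xc <- design_matrix(dat[, spec$base_confounders, drop = FALSE])
  Ldf <- dat[, spec$post_confounders, drop = FALSE]
  nL <- ncol(Ldf)
  Lmat <- matrix(0, n, nL,
                 dimnames = list(NULL, spec$post_confounders))
  Lbin <- logical(nL)
  for (j in seq_len(nL)) {
    lj <- Ldf[[j]]
    if (is.logical(lj)) lj <- as.numeric(lj)
    Lmat[, j] <- as.numeric(lj)
    Lbin[j] <- is_binary01(Lmat[, j])
  }

  int <- spec$interaction
  pXc <- ncol(Xc)
  DL <- cbind(1, a01, Xc)                       # L_j ~ A + C
  DM <- cbind(1, a01, Xc, Lmat)                 # M ~ A + C + L
  DY <- if (int) cbind(1, a01, m, a01 * m, Xc, Lmat)
        else cbind(1, a01, m, Xc, Lmat)         # Y ~ A + M (+ A:M) + C + L
  if (n < ncol(DY) + 2) {
    stop("too few complete cases in the chosen exposure contrast")
  }
  list(n = n, a01 = a01, m = m, y = y, Xc = Xc, Lmat = Lmat, Lbin = Lbin,
       DL = DL, DM = DM, DY = DY, interaction = int,
       # column positions of the modifiable terms
       iM_a = 2L, iM_L = if (nL) 2L + pXc + seq_len(nL) else integer(0),
       iY_a = 2L, iY_m = 3L, iY_am = if (int) 4L else NA_integer_,
       iY_L = if (nL) (if (int) 4L else 3L) + pXc + seq_len(nL)
              else integer(0),
       null_contrast = identical(spec$a, spec$a_star))
}

resolve_engine <- function(engine, has_L) {
  if (engine == "auto") {
    return(if (has_L) "simulation" else "expectation")
  }
  if (engine == "expectation" && has_L) {
    stop("the expectation engine is only valid with no post-confounders; ",
         "use engine = \"simulation\"")
  }
  engine
}

# One full g-computation pass on the rows `idx`, refitting every model.
# Returns c(nde, nie, tce) with tce = nde + nie in the same pass.
gcomp_core <- function(prep, idx, engine, mc_draws) {
  if (prep$null_contrast) return(c(nde = 0, nie = 0, tce = 0))
  fm <- fast_lm(prep$DM[idx, , drop = FALSE], prep$m[idx])
  fy <- fast_lm(prep$DY[idx, , drop = FALSE], prep$y[idx])

  predY <- function(aval, mv, Lsub = NULL) {
    X <- prep$DY[idx, , drop = FALSE]
    X[, prep$iY_a] <- aval
    X[, prep$iY_m] <- mv
    if (prep$interaction) X[, prep$iY_am] <- aval * mv
    if (!is.null(Lsub) && length(prep$iY_L)) X[, prep$iY_L] <- Lsub
    drop(X %*% fy$coef)
  }
  predM <- function(aval, Lsub = NULL) {
    X <- prep$DM[idx, , drop = FALSE]
    X[, prep$iM_a] <- aval
    if (!is.null(Lsub) && length(prep$iM_L)) X[, prep$iM_L] <- Lsub
    drop(X %*% fm$coef)
  }

  if (engine == "expectation") {
    m0 <- predM(0); m1 <- predM(1)
    ybar_a_m0 <- mean(predY(1, m0))
    ybar_astar_m0 <- mean(predY(0, m0))
    ybar_a_m1 <- mean(predY(1, m1))
  } else {
    nL <- length(prep$Lbin)
    Lfits <- vector("list", nL)
    DLs <- prep$DL[idx, , drop = FALSE]
    for (j in seq_len(nL)) {
      lj <- prep$Lmat[idx, j]
      if (prep$Lbin[j]) {
        gf <- suppressWarnings(
          glm.fit(DLs, lj, family = binomial()))
        if (!gf$converged) stop("post-confounder model did not converge")
        Lfits[[j]] <- list(type = "binary", coef = coef(gf))
      } else {
        fl <- fast_lm(DLs, lj)
        Lfits[[j]] <- list(type = "continuous", coef = fl$coef,
                           sigma = fl$sigma)
      }
    }
    ns <- length(idx)
    drawL <- function(aval) {
      if (!nL) return(NULL)
      X <- DLs
      X[, 2] <- aval
      out <- matrix(0, ns, nL)
      for (j in seq_len(nL)) {
        lp <- drop(X %*% Lfits[[j]]$coef)
        out[, j] <- if (Lfits[[j]]$type == "binary") {
          rbinom(ns, 1, plogis(lp))
        } else rnorm(ns, lp, Lfits[[j]]$sigma)
      }
      out
    }
    acc <- c(0, 0, 0)
    for (k in seq_len(mc_draws)) {
      La <- drawL(1)
      Lastar <- drawL(0)
      M_astar <- rnorm(ns, predM(0, Lastar), fm$sigma)
      M_a <- rnorm(ns, predM(1, La), fm$sigma)
      acc <- acc + c(mean(predY(1, M_astar, La)),
                     mean(predY(0, M_astar, Lastar)),
                     mean(predY(1, M_a, La)))
    }
    ybar_a_m0 <- acc[1] / mc_draws
    ybar_astar_m0 <- acc[2] / mc_draws
    ybar_a_m1 <- acc[3] / mc_draws
  }
  nde <- ybar_a_m0 - ybar_astar_m0
  nie <- ybar_a_m1 - ybar_a_m0
  c(nde = nde, nie = nie, tce = nde + nie)
}

# ---- user-facing estimators --------------------------------------------

#' G-computation point estimates of NDE, NIE and TCE
#'
#' Implements the parametric g-formula for a single continuous mediator:
#' linear (or logistic, for binary) models for each post-confounder given
#' exposure and baseline confounders; a linear model for the mediator
#' given exposure, confounders and post-confounders; and a linear model
#' for the (possibly log-transformed) outcome given exposure, mediator,
#' their interaction, confounders and post-confounders.  Counterfactual
#' outcome means are formed either by deterministic plug-in of conditional
#' means (expectation engine, valid with no post-confounders) or by
#' Monte-Carlo simulation of post-confounder and mediator values per
#' subject (simulation engine).  Then
#' `NDE = E[Y(a, M(a*))] - E[Y(a*, M(a*))]`,
#' `NIE = E[Y(a, M(a))] - E[Y(a, M(a*))]`, `TCE = NDE + NIE`.
#' With post-confounders these are the randomized-interventional
#' analogues of natural effects.
#'
#' @param table cohort `data.frame`.
#' @param spec a [mediation_spec()].
#' @param config a [gcomp_config()]; only `mc_draws`, `seed` and `engine`
#'   are used here.
#' @return named numeric vector `c(nde, nie, tce)` with attributes
#'   `n_used` and `engine`.
#' @export
gcomp_point_estimate <- function(table, spec, config = gcomp_config()) {
  prep <- gcomp_prepare(table, spec)
  engine <- resolve_engine(config$engine, length(spec$post_confounders) > 0)
  if (engine == "simulation" && !is.null(config$seed)) set.seed(config$seed)
  est <- gcomp_core(prep, seq_len(prep$n), engine, config$mc_draws)
  attr(est, "n_used") <- prep$n
  attr(est, "engine") <- engine
  est
}

#' Closed-form NDE and NIE for the linear two-model system
#'
#' Analytic oracle for the no-post-confounder case with numeric exposure
#' codes: mediator model `M = b0 + b1*A + (confounders)` and outcome model
#' `Y = t0 + t1*A + t2*M + t3*A*M + (confounders)`.  Then
#' `NDE = (t1 + t3*(b0 + b1*a_star + c_mean)) * (a - a_star)` and
#' `NIE = (t2*b1 + t3*b1*a) * (a - a_star)`, where `c_mean` is the mean
#' confounder contribution to the mediator model.
#'
#' @param beta mediator coefficients: named vector with `b0`, `b1` (or
#'   length 2, in that order).
#' @param theta outcome coefficients: named vector with `t1`, `t2`, `t3`
#'   (or length 3, in that order; set `t3 = 0` for no interaction).
#' @param a,a_star numeric exposure codes for the contrast.
#' @param c_mean mean confounder contribution to the mediator linear
#'   predictor.
#' @return named numeric vector `c(nde, nie)`.
#' @examples
#' closed_form_nde_nie(c(b0 = 0, b1 = 2), c(t1 = 1, t2 = 0.5, t3 = 0.2))
#' @export
closed_form_nde_nie <- function(beta, theta, a = 1, a_star = 0, c_mean = 0) {
  b0 <- if (!is.null(names(beta))) beta[["b0"]] else beta[[1]]
  b1 <- if (!is.null(names(beta))) beta[["b1"]] else beta[[2]]
  t1 <- if (!is.null(names(theta))) theta[["t1"]] else theta[[1]]
  t2 <- if (!is.null(names(theta))) theta[["t2"]] else theta[[2]]
  t3 <- if (!is.null(names(theta))) theta[["t3"]] else theta[[3]]
  nde <- (t1 + t3 * (b0 + b1 * a_star + c_mean)) * (a - a_star)
  nie <- (t2 * b1 + t3 * b1 * a) * (a - a_star)
  c(nde = nde, nie = nie)
}

#' Proportion of the total effect that is mediated
#'
#' `100 * NIE / (NDE + NIE)`, reported as 0 whenever the direct and
#' indirect effects point in opposite directions (and when `NIE = 0`).
#' The unrounded value is returned; a `display` attribute carries the
#' one-decimal table rounding.
#'
#' @param nde,nie natural direct and indirect effect point estimates.
#' @return percentage in \[0, 100\] with attribute `display`.
#' @examples
#' proportion_mediated(1.06, 3.50)   # 76.8 after display rounding
#' proportion_mediated(-0.78, 1.12)  # 0: opposite directions
#' @export
proportion_mediated <- function(nde, nie) {
  stopifnot(is.finite(nde), is.finite(nie))
  pm <- if (nie == 0 || nde * nie < 0) {
    0
  } else {
    tce <- nde + nie
    if (tce == 0) stop("proportion mediated undefined: NDE + NIE = 0")
    100 * nie / tce
  }
  attr(pm, "display") <- round_half_up(pm, 1)
  pm
}

#' Bootstrap G-computation mediation analysis
#'
#' Nonparametric bootstrap of the full g-computation pipeline: rows are
#' resampled with replacement and every model (post-confounder, mediator,
#' outcome) is refitted within each replicate.  Percentile confidence
#' intervals are taken from the replicate distributions of NDE, NIE and
#' TCE; point estimates come from the original sample, and the proportion
#' mediated is computed on the point estimates only.  Replicates with a
#' non-estimable fit are dropped and counted; more than 5% dropped is an
#' error.  Results are fully reproducible given `config$seed`.
#'
#' @inheritParams gcomp_point_estimate
#' @param config a [gcomp_config()].
#' @return an object of class `mediation_estimate`: list with elements
#'   `nde`, `nie`, `tce` (each `c(est, lower, upper)`), `pm` (percent,
#'   with `display` attribute), `n_used`, `reps`, `reps_dropped`, `seed`,
#'   `engine`, `interventional` (TRUE when post-confounders are present),
#'   and the replicate matrix `replicates`.
#' @export
bootstrap_mediation <- function(table, spec, config = gcomp_config()) {
  prep <- gcomp_prepare(table, spec)
  engine <- resolve_engine(config$engine, length(spec$post_confounders) > 0)
  if (!is.null(config$seed)) set.seed(config$seed)

  point <- gcomp_core(prep, seq_len(prep$n), engine, config$mc_draws)
  reps <- config$bootstrap_reps
  out <- matrix(NA_real_, reps, 3,
                dimnames = list(NULL, c("nde", "nie", "tce")))
  dropped <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(prep$n, prep$n, replace = TRUE)
    est <- tryCatch(gcomp_core(prep, idx, engine, config$mc_draws),
                    error = function(e) NULL)
    if (is.null(est) || any(!is.finite(est))) dropped <- dropped + 1L
    else out[r, ] <- est
  }
  if (dropped > 0.05 * reps) {
    stop(sprintf("%d of %d bootstrap replicates failed (> 5%%)",
                 dropped, reps))
  }
  ok <- stats::complete.cases(out)
  alpha <- 1 - config$ci_level
  ci <- function(col) {
    q <- quantile(out[ok, col], probs = c(alpha / 2, 1 - alpha / 2),
                  names = FALSE)
    c(est = unname(point[col]), lower = q[1], upper = q[2])
  }
  pm <- tryCatch(proportion_mediated(point[["nde"]], point[["nie"]]),
                 error = function(e) NA_real_)
  structure(list(nde = ci("nde"), nie = ci("nie"), tce = ci("tce"),
                 pm = pm, n_used = prep$n, reps = reps,
                 reps_dropped = dropped, seed = config$seed,
                 engine = engine,
                 interventional = length(spec$post_confounders) > 0,
                 mediator = spec$mediator, outcome = spec$outcome,
                 contrast = c(a = spec$a, a_star = spec$a_star),
                 log_outcome = spec$log_outcome,
                 replicates = out[ok, , drop = FALSE]),
            class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, digits = 3, ...) {
  kind <- if (x$interventional) {
    "interventional-analogue natural effects"
  } else "natural effects"
  cat(sprintf("G-computation mediation: %s -> %s (contrast %s vs %s)\n",
              x$contrast[["a"]], x$outcome, x$contrast[["a"]],
              x$contrast[["a_star"]]))
  cat(sprintf("  mediator: %s   %s%s\n", x$mediator, kind,
              if (x$log_outcome) "   [log outcome scale]" else ""))
  fmt <- function(v) sprintf("%s (%s; %s)",
                             format(round(v[1], digits)),
                             format(round(v[2], digits)),
                             format(round(v[3], digits)))
  cat(sprintf("  NDE: %s\n  NIE: %s\n  TCE: %s\n",
              fmt(x$nde), fmt(x$nie), fmt(x$tce)))
  cat(sprintf("  %% mediated: %s\n",
              if (is.na(x$pm)) "NA" else format(attr(x$pm, "display"))))
  cat(sprintf("  n = %d, bootstrap reps = %d (%d dropped), engine = %s%s\n",
              x$n_used, x$reps, x$reps_dropped, x$engine,
              if (!is.null(x$seed)) sprintf(", seed = %s", x$seed) else ""))
  invisible(x)
}
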
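#' True mediation estimands implied by a generating configuration
#'
#' Computes, from the generating coefficients alone, the natural direct
#' effect (NDE), natural indirect effect (NIE) and total causal effect
#' (TCE = NDE + NIE) of the exposure contrast in `spec` through the focal
#' mediator.  Because every structural model in the generator is linear in
#' its inputs, the estimands have closed forms in the coefficients and the
#' expected confounder contribution; the only non-linear ingredient is a
#' logistic post-confounder, whose marginal expectation under each exposure
#' setting is obtained by averaging the inverse-logit over a large
#' fixed-seed Monte-Carlo draw of the confounders (2e5 draws; the caller's
#' RNG state is preserved).  With no post-confounders, or only linear ones,
#' the result is exact.
#'
#' Pathways through non-focal mediators are part of the direct effect (they
#' take their natural value under the active exposure setting), matching
#' the single-mediator decomposition estimated by [gcomp_point_estimate()].
#'
#' @param config a [generation_config()].
#' @param spec a [mediation_spec()]; only its `mediator`, `outcome`, `a`
#'   and `a_star` fields are used (the generator's own confounder and
#'   post-confounder structure defines the rest).
#' @return list with `nde`, `nie`, `tce` (`tce = nde + nie` exactly) and
#'   `method` (`"closed_form"` or `"closed_form_mc_logistic"`).  Effects
#'   for log-scale outcomes are on the log scale.
#' @export
true_effects <- function(config, spec) {
  validate_generation_config(config)
  med <- spec$mediator
  out <- spec$outcome
  if (!med %in% names(config$beta)) {
    stop(sprintf("mediator '%s' is not generated by this config", med))
  }
  if (!out %in% names(config$theta)) {
    stop(sprintf("outcome '%s' is not generated by this config", out))
  }
  a <- spec$a
  a_star <- spec$a_star
  if (identical(a, a_star)) {
    return(list(nde = 0, nie = 0, tce = 0, method = "null_contrast"))
  }

  EXc <- expected_confounder_design(config$confounder_specs)
  EL <- expected_post_confounders(config, EXc)  # level -> named vector
  method <- attr(EL, "method")

  dv <- function(coefs, level) {
    if (is.null(coefs) || !level %in% names(coefs)) 0 else unname(coefs[level])
  }
  dot <- function(coefs, evec) {
    if (is.null(coefs) || !length(coefs)) return(0)
    sum(coefs * evec[names(coefs)])
  }

  # E[M_j(x)] for every generated mediator
  EM <- function(mname, x) {
    b <- config$beta[[mname]]
    b$b0 + dv(b$b1, x) + dot(b$b2, EXc) + dot(b$bL, EL[[x]])
  }

  th <- config$theta[[out]]
  tamv <- function(mname, x) {
    if (is.null(th$tam) || !mname %in% names(th$tam)) 0
    else dv(th$tam[[mname]], x)
  }
  tmv <- function(mname) {
    if (is.null(th$tm) || !mname %in% names(th$tm)) 0
    else unname(th$tm[mname])
  }

  other <- setdiff(names(config$beta), med)
  # E[Y(x, G_med(x'))]: focal mediator drawn under x', everything else
  # (post-confounders, non-focal mediators) follows x.
  EY <- function(x, xp) {
    v <- th$t0 + dv(th$t1, x) +
      (tmv(med) + tamv(med, x)) * EM(med, xp) +
      dot(th$t4, EXc) + dot(th$tL, EL[[x]])
    for (m2 in other) v <- v + (tmv(m2) + tamv(m2, x)) * EM(m2, x)
    v
  }

  nde <- EY(a, a_star) - EY(a_star, a_star)
  nie <- EY(a, a) - EY(a, a_star)
  list(nde = nde, nie = nie, tce = nde + nie, method = method)
}

# Expected value of each expanded confounder design column.
expected_confounder_design <- function(specs) {
  ev <- numeric(0)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (sp$type == "categorical") {
      v <- sp$probs[-1]
      names(v) <- paste0(nm, "_", sp$levels[-1])
    } else if (sp$type == "binary") {
      v <- setNames(sp$p, nm)
    } else if (sp$type == "normal") {
      lo <- sp$lower %||% -Inf; hi <- sp$upper %||% Inf
      if (is.finite(lo) || is.finite(hi)) {
        al <- (lo - sp$mean) / sp$sd; be <- (hi - sp$mean) / sp$sd
        m <- sp$mean + sp$sd * (dnorm(al) - dnorm(be)) /
          (pnorm(be) - pnorm(al))
      } else m <- sp$mean
      v <- setNames(m, nm)
    } else {  # beta
      v <- setNames(sp$mean, nm)
    }
    ev <- c(ev, v)
  }
  ev
}

# E[L_j | do(A = x)] for each exposure level.  Linear L is exact; a
# logistic L with confounder effects needs E_C[plogis(.)], taken over a
# fixed-seed Monte-Carlo confounder draw.
expected_post_confounders <- function(config, EXc, n_mc = 2e5) {
  res <- setNames(vector("list", length(menarche_levels)), menarche_levels)
  method <- "closed_form"
  if (!length(config$alpha_L)) {
    for (lv in menarche_levels) res[[lv]] <- numeric(0)
    attr(res, "method") <- method
    return(res)
  }
  needs_mc <- any(vapply(config$alpha_L, function(al) {
    al$type == "binary" && length(al$a2 %||% numeric(0)) > 0
  }, logical(1)))
  Xmc <- NULL
  if (needs_mc) {
    method <- "closed_form_mc_logistic"
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    set.seed(700301L)
    Cmc <- draw_confounders(config$confounder_specs, n_mc)
    Xmc <- expand_confounders(Cmc, config$confounder_specs)
  }
  for (lv in menarche_levels) {
    v <- numeric(0)
    for (nm in names(config$alpha_L)) {
      al <- config$alpha_L[[nm]]
      a1v <- if (lv %in% names(al$a1 %||% numeric(0))) al$a1[[lv]] else 0
      if (al$type == "continuous") {
        e <- al$a0 + a1v +
          (if (length(al$a2)) sum(al$a2 * EXc[names(al$a2)]) else 0)
      } else if (length(al$a2 %||% numeric(0)) == 0) {
        e <- plogis(al$a0 + a1v)
      } else {
        e <- mean(plogis(al$a0 + a1v + lp_from(al$a2, Xmc)))
      }
      v <- c(v, setNames(e, nm))
    }
    res[[lv]] <- v
  }
  attr(res, "method") <- method
  res
}
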
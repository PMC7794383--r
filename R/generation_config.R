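#' Specify the data-generating process for a synthetic cohort
#'
#' A `generation_config` holds every parameter of the synthetic cohort's
#' causal structure: baseline confounders C, a three-category exposure A
#' (age at menarche: `lt12`, `mid` = 12-13 years, `ge14`), post-confounders
#' L affected by the exposure, continuous mediators M, and outcomes Y that
#' may depend on the exposure, mediators, an exposure-by-mediator
#' interaction, confounders and post-confounders.  Generation follows the
#' causal ordering C -> A -> L -> M -> Y, so the configuration is also the
#' source of analytic truth for the mediation estimands (see
#' [true_effects()]).
#'
#' @param n number of rows to generate.
#' @param exposure_probs length-3 probability vector for the menarche
#'   categories, in the order `lt12`, `mid`, `ge14`; must sum to 1.
#' @param confounder_specs named list of distribution descriptions, one per
#'   baseline confounder.  Each element is a list with a `type` field:
#'   `"categorical"` (`levels`, `probs`), `"binary"` (`p`), `"normal"`
#'   (`mean`, `sd`, optional `lower`/`upper` truncation bounds) or
#'   `"beta"` (`mean`, `sd`, rescaled to \[0,1\]).
#' @param alpha_L named list of post-confounder models, each a list with
#'   `type` (`"binary"` for a logistic model, `"continuous"` for linear),
#'   intercept `a0`, exposure effects `a1` (named vector over non-reference
#'   exposure levels), confounder effects `a2` (named by expanded
#'   confounder columns) and, for continuous L, residual `sd`.
#' @param beta named list of mediator models, each a list with intercept
#'   `b0`, exposure effects `b1`, confounder effects `b2`, post-confounder
#'   effects `bL` (named by post-confounder), residual `sd`, and optional
#'   `lower` positivity bound enforced by redrawing noise.
#' @param theta named list of outcome models, each a list with intercept
#'   `t0`, exposure effects `t1`, mediator effects `tm` (named by
#'   mediator), exposure-by-mediator interactions `tam` (named list:
#'   mediator -> named vector over non-reference exposure levels),
#'   confounder effects `t4`, post-confounder effects `tL`, residual `sd`.
#' @param log_scale_outcomes character vector of outcomes generated as
#'   `exp(linear predictor + Normal noise)` (log-normal), used for
#'   right-skewed variables such as triglycerides and C-reactive protein.
#' @param exclusion_rates list with Bernoulli rates `pregnant`,
#'   `postpartum_3m`, `oral_contraceptive`, and an MCAR `missing` rate
#'   applied independently to the exposure, mediators and outcomes.
#' @param exposure_dependence optional named list (`lt12`, `mid`) of
#'   confounder coefficient vectors inducing a multinomial-logit
#'   dependence of the exposure on C; `NULL` (the default) draws the
#'   exposure independently of C.
#' @param seed default seed used by [generate_cohort()] when none is given.
#'
#' @return an object of class `generation_config`.
#' @seealso [default_generation_config()] for a configuration calibrated to
#'   the published cohort's marginal structure.
#' @export
generation_config <- function(n,
                              exposure_probs,
                              confounder_specs,
                              alpha_L = list(),
                              beta,
                              theta,
                              log_scale_outcomes = character(),
                              exclusion_rates = list(pregnant = 0,
                                                     postpartum_3m = 0,
                                                     oral_contraceptive = 0,
                                                     missing = 0),
                              exposure_dependence = NULL,
                              seed = NULL) {
  cfg <- structure(list(n = n,
                        exposure_probs = exposure_probs,
                        confounder_specs = confounder_specs,
                        alpha_L = alpha_L,
                        beta = beta,
                        theta = theta,
                        log_scale_outcomes = log_scale_outcomes,
                        exclusion_rates = exclusion_rates,
                        exposure_dependence = exposure_dependence,
                        seed = seed),
                   class = "generation_config")
  validate_generation_config(cfg)
  cfg
}

# Expanded (dummy-coded) column names implied by the confounder specs;
# coefficient vectors in alpha_L / beta / theta must refer to these.
confounder_columns <- function(specs) {
  unlist(lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    if (identical(sp$type, "categorical")) {
      paste0(nm, "_", sp$levels[-1])
    } else nm
  }), use.names = FALSE)
}

#' Validate a generation configuration
#'
#' Checks the invariants of a [generation_config()]: probabilities in
#' range and summing to one, non-negative residual SDs, and every
#' coefficient name resolving to a declared confounder column, exposure
#' level, post-confounder or mediator.  Errors name the offending field.
#'
#' @param cfg a `generation_config`.
#' @return `cfg`, invisibly, when valid.
#' @export
validate_generation_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1L || cfg$n < 1 ||
      cfg$n != floor(cfg$n)) {
    stop_config("n", "must be a positive integer")
  }
  p <- cfg$exposure_probs
  if (length(p) != 3L || any(p < 0) || any(p > 1)) {
    stop_config("exposure_probs", "must be 3 probabilities in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop_config("exposure_probs", "must sum to 1 (within 1e-12)")
  }
  if (!length(names(cfg$confounder_specs))) {
    stop_config("confounder_specs", "must be a named list")
  }
  for (nm in names(cfg$confounder_specs)) {
    sp <- cfg$confounder_specs[[nm]]
    field <- paste0("confounder_specs$", nm)
    if (is.null(sp$type)) stop_config(field, "missing 'type'")
    if (sp$type == "categorical") {
      if (length(sp$levels) != length(sp$probs)) {
        stop_config(field, "levels and probs lengths differ")
      }
      if (abs(sum(sp$probs) - 1) > 1e-8) {
        stop_config(field, "category probabilities must sum to 1")
      }
    } else if (sp$type == "binary") {
      if (is.null(sp$p) || sp$p < 0 || sp$p > 1) {
        stop_config(field, "'p' must lie in [0, 1]")
      }
    } else if (sp$type %in% c("normal", "beta")) {
      if (is.null(sp$mean) || is.null(sp$sd) || sp$sd < 0) {
        stop_config(field, "needs 'mean' and non-negative 'sd'")
      }
    } else {
      stop_config(field, sprintf("unknown type '%s'", sp$type))
    }
  }
  ccols <- confounder_columns(cfg$confounder_specs)
  lnames <- names(cfg$alpha_L) %||% character()
  exlev <- menarche_levels[-3]  # non-reference exposure levels

  check_names <- function(vals, allowed, field) {
    if (is.null(vals) || !length(vals)) return(invisible())
    bad <- setdiff(names(vals), allowed)
    if (length(bad)) {
      stop_config(field, paste("unknown coefficient name(s):",
                               paste(bad, collapse = ", ")))
    }
  }

  for (nm in lnames) {
    al <- cfg$alpha_L[[nm]]
    field <- paste0("alpha_L$", nm)
    if (!al$type %in% c("binary", "continuous")) {
      stop_config(field, "type must be 'binary' or 'continuous'")
    }
    check_names(al$a1, exlev, paste0(field, "$a1"))
    check_names(al$a2, ccols, paste0(field, "$a2"))
    if (al$type == "continuous" && (is.null(al$sd) || al$sd < 0)) {
      stop_config(field, "continuous L needs non-negative 'sd'")
    }
  }
  for (nm in names(cfg$beta)) {
    b <- cfg$beta[[nm]]
    field <- paste0("beta$", nm)
    if (is.null(b$sd) || b$sd < 0) stop_config(field, "residual sd must be >= 0")
    check_names(b$b1, exlev, paste0(field, "$b1"))
    check_names(b$b2, ccols, paste0(field, "$b2"))
    check_names(b$bL, lnames, paste0(field, "$bL"))
  }
  for (nm in names(cfg$theta)) {
    th <- cfg$theta[[nm]]
    field <- paste0("theta$", nm)
    if (is.null(th$sd) || th$sd < 0) stop_config(field, "residual sd must be >= 0")
    check_names(th$t1, exlev, paste0(field, "$t1"))
    check_names(th$tm, names(cfg$beta), paste0(field, "$tm"))
    check_names(th$t4, ccols, paste0(field, "$t4"))
    check_names(th$tL, lnames, paste0(field, "$tL"))
    if (!is.null(th$tam)) {
      check_names(th$tam, names(cfg$beta), paste0(field, "$tam"))
      for (m in names(th$tam)) {
        check_names(th$tam[[m]], exlev, paste0(field, "$tam$", m))
      }
    }
  }
  bad_log <- setdiff(cfg$log_scale_outcomes, names(cfg$theta))
  if (length(bad_log)) {
    stop_config("log_scale_outcomes",
                paste("not an outcome:", paste(bad_log, collapse = ", ")))
  }
  er <- cfg$exclusion_rates
  for (f in c("pregnant", "postpartum_3m", "oral_contraceptive", "missing")) {
    v <- er[[f]] %||% 0
    if (v < 0 || v > 1) stop_config(paste0("exclusion_rates$", f),
                                    "must lie in [0, 1]")
  }
  if (!is.null(cfg$exposure_dependence)) {
    for (lvl in names(cfg$exposure_dependence)) {
      if (!lvl %in% exlev) {
        stop_config("exposure_dependence",
                    sprintf("unknown exposure level '%s'", lvl))
      }
      check_names(cfg$exposure_dependence[[lvl]], ccols,
                  paste0("exposure_dependence$", lvl))
    }
  }
  invisible(cfg)
}

#' @export
print.generation_config <- function(x, ...) {
  cat("Synthetic cohort generating process\n")
  cat(sprintf("  n: %d   exposure probs (lt12, mid, ge14): %s\n", x$n,
              paste(format(x$exposure_probs), collapse = ", ")))
  cat(sprintf("  confounders: %s\n",
              paste(names(x$confounder_specs), collapse = ", ")))
  cat(sprintf("  post-confounders: %s\n",
              if (length(x$alpha_L)) paste(names(x$alpha_L), collapse = ", ")
              else "(none)"))
  cat(sprintf("  mediators: %s\n", paste(names(x$beta), collapse = ", ")))
  cat(sprintf("  outcomes: %s\n", paste(names(x$theta), collapse = ", ")))
  if (length(x$log_scale_outcomes)) {
    cat(sprintf("  log-normal outcomes: %s\n",
                paste(x$log_scale_outcomes, collapse = ", ")))
  }
  invisible(x)
}
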
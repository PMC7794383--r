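#' Write a cohort table to CSV
#'
#' UTF-8, header row, missing values as empty cells, logical flags as 0/1.
#' A sidecar JSON file recording the full generating configuration and
#' seed is written alongside when `config` is supplied.
#'
#' @param table cohort `data.frame`.
#' @param path output CSV path.
#' @param config optional [generation_config()] to record as
#'   `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path, config = NULL) {
  out <- as.data.frame(table)
  for (nm in names(out)) {
    if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
    if (is.double(out[[nm]])) {
      # 17 significant digits so doubles round-trip bit-exactly
      v <- formatC(out[[nm]], digits = 17, format = "g")
      v[is.na(out[[nm]])] <- NA
      out[[nm]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Inverse of [write_cohort_csv()]: empty cells become `NA`, the exposure
#' column is restored as a factor with the canonical youngest-first level
#' order, and flag columns become logical.
#'
#' @param path CSV path.
#' @param exposure exposure column name.
#' @param exposure_levels level order for the exposure factor.
#' @param flag_columns columns to coerce to logical.
#' @return a `cohort_table` `data.frame`.
#' @export
read_cohort_csv <- function(path, exposure = "menarche_cat",
                            exposure_levels = menarche_levels,
                            flag_columns = c("pregnant", "postpartum_3m",
                                             "oral_contraceptive")) {
  out <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
  if (exposure %in% names(out)) {
    out[[exposure]] <- factor(out[[exposure]], levels = exposure_levels)
  }
  for (nm in intersect(flag_columns, names(out))) {
    out[[nm]] <- out[[nm]] == 1
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Assemble a pipeline run configuration
#'
#' @param mode `"generate"` (simulate a cohort from `generation`) or
#'   `"read"` (load `csv_path`).
#' @param generation a [generation_config()] (generate mode).
#' @param csv_path cohort CSV path (read mode).
#' @param roles named list mapping causal roles to column names:
#'   `exposure`, `mediators`, `outcomes`, `base_confounders`,
#'   `post_confounders`, `flags`.
#' @param analyses subset of `c("descriptives", "adjusted", "mediation")`.
#' @param mediation_grid data frame with columns `mediator`, `outcome`
#'   (and optionally `log_outcome`) defining which mediator/outcome pairs
#'   to run; defaults to the full grid of roles with log flags taken from
#'   `log_outcomes`.
#' @param log_outcomes outcomes analysed on the log scale.
#' @param gcomp a [gcomp_config()].
#' @param out_dir output directory for report CSVs and the run log.
#' @param seed seed for generate mode (overrides the generation config's).
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("generate", "read"),
                       generation = NULL, csv_path = NULL,
                       roles, analyses = c("descriptives", "adjusted",
                                           "mediation"),
                       mediation_grid = NULL,
                       log_outcomes = character(),
                       gcomp = gcomp_config(),
                       out_dir = ".", seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "generate" && is.null(generation)) {
    stop("generate mode requires a generation config")
  }
  if (mode == "read" && is.null(csv_path)) {
    stop("read mode requires csv_path")
  }
  if (!length(analyses)) stop("analysis list must be non-empty")
  analyses <- match.arg(analyses, several.ok = TRUE)
  for (f in c("exposure", "mediators", "outcomes", "base_confounders")) {
    if (is.null(roles[[f]])) stop(sprintf("roles$%s is required", f))
  }
  structure(list(mode = mode, generation = generation, csv_path = csv_path,
                 roles = roles, analyses = analyses,
                 mediation_grid = mediation_grid,
                 log_outcomes = log_outcomes, gcomp = gcomp,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full reporting pipeline
#'
#' Executes the stages in order — load (or generate) the cohort, apply the
#' CRP exclusion filter for the C-reactive-protein analysis, descriptive
#' summaries by exposure category, confounder-adjusted regressions, and
#' the mediation grid — writing one CSV per table analogue plus a run log
#' recording the seed, package version and row counts at every filter
#' step.  Re-running with an identical configuration reproduces identical
#' outputs.
#'
#' @param rc a [run_config()].
#' @return (invisibly) list with `files` (paths written), `cohort`, and
#'   the per-stage results.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(rc$out_dir, "run_log.txt")
  log_lines <- character()
  logi <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  logi("gcmediate pipeline run, package version %s",
       as.character(utils::packageVersion("gcmediate")))

  roles <- rc$roles
  if (rc$mode == "generate") {
    seed <- rc$seed %||% rc$generation$seed
    cohort <- generate_cohort(rc$generation, seed = seed)
    logi("generated cohort: n = %d (seed = %s)", nrow(cohort),
         format(seed %||% "NULL"))
    cohort_path <- file.path(rc$out_dir, "cohort.csv")
    write_cohort_csv(cohort, cohort_path, config = rc$generation)
    logi("wrote %s (+ sidecar config)", cohort_path)
  } else {
    cohort <- read_cohort_csv(rc$csv_path, exposure = roles$exposure)
    logi("read cohort: n = %d from %s", nrow(cohort), rc$csv_path)
  }

  mapped <- unlist(roles[c("exposure", "mediators", "outcomes",
                           "base_confounders", "post_confounders",
                           "flags")], use.names = FALSE)
  missing_cols <- setdiff(mapped, names(cohort))
  if (length(missing_cols)) {
    stop(sprintf("role mapping does not match the table schema; missing: %s",
                 paste(missing_cols, collapse = ", ")))
  }

  files <- character()
  results <- list()
  emit <- function(df, name) {
    path <- file.path(rc$out_dir, name)
    write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
    logi("wrote %s (%d rows)", path, nrow(df))
  }

  n_total <- nrow(cohort)
  exposure_obs <- !is.na(cohort[[roles$exposure]])
  logi("exposure observed: %d of %d rows", sum(exposure_obs), n_total)

  analysis_vars <- c(roles$mediators, roles$outcomes)

  if ("descriptives" %in% rc$analyses) {
    counts <- vapply(levels(as.factor(cohort[[roles$exposure]])),
                     function(l) sum(cohort[[roles$exposure]] == l,
                                     na.rm = TRUE), integer(1))
    prev <- category_prevalence(counts)
    emit(data.frame(category = names(counts), n = unname(counts),
                    percent = unname(attr(prev, "display"))),
         "table1_exposure.csv")
    desc <- descriptive_table(cohort, analysis_vars,
                              log_variables = rc$log_outcomes,
                              exposure = roles$exposure)
    emit(desc, "table2_descriptives.csv")
    results$descriptives <- desc
  }

  if ("adjusted" %in% rc$analyses) {
    rows <- list()
    for (y in roles$outcomes) {
      use <- cohort
      if (identical(y, "crp")) {
        use <- crp_exclusion_filter(cohort)
        logi("CRP analysis filter: %d retained, %d excluded of %d",
             nrow(use), nrow(cohort) - nrow(use), nrow(cohort))
      }
      fit <- fit_adjusted_linear(use, y, roles$base_confounders,
                                 log_outcome = y %in% rc$log_outcomes,
                                 exposure = roles$exposure)
      cf <- fit$coefficients
      keep <- grep(roles$exposure, names(cf), fixed = TRUE)
      rows[[y]] <- data.frame(
        outcome = y,
        term = sub(roles$exposure, "", names(cf)[keep], fixed = TRUE),
        estimate = unname(cf[keep]),
        lower = fit$ci[keep, 1], upper = fit$ci[keep, 2],
        transform = fit$outcome_transform, n_used = fit$n_used,
        p_trend = fit$p_trend, p_heterogeneity = fit$p_heterogeneity)
    }
    tab3 <- do.call(rbind, rows)
    rownames(tab3) <- NULL
    emit(tab3, "table3_adjusted.csv")
    results$adjusted <- tab3
  }

  if ("mediation" %in% rc$analyses) {
    grid <- rc$mediation_grid %||%
      expand.grid(mediator = roles$mediators, outcome = roles$outcomes,
                  stringsAsFactors = FALSE)
    if (is.null(grid$log_outcome)) {
      grid$log_outcome <- grid$outcome %in% rc$log_outcomes
    }
    rows <- list()
    ests <- list()
    for (i in seq_len(nrow(grid))) {
      sp <- mediation_spec(mediator = grid$mediator[i],
                           outcome = grid$outcome[i],
                           base_confounders = roles$base_confounders,
                           post_confounders = roles$post_confounders %||%
                             character(),
                           exposure = roles$exposure,
                           log_outcome = grid$log_outcome[i])
      use <- if (identical(grid$outcome[i], "crp")) {
        crp_exclusion_filter(cohort)
      } else cohort
      est <- bootstrap_mediation(use, sp, rc$gcomp)
      ests[[paste(grid$outcome[i], grid$mediator[i], sep = "~")]] <- est
      rows[[i]] <- data.frame(
        outcome = grid$outcome[i], mediator = grid$mediator[i],
        nde = est$nde[["est"]], nde_lower = est$nde[["lower"]],
        nde_upper = est$nde[["upper"]],
        nie = est$nie[["est"]], nie_lower = est$nie[["lower"]],
        nie_upper = est$nie[["upper"]],
        tce = est$tce[["est"]], tce_lower = est$tce[["lower"]],
        tce_upper = est$tce[["upper"]],
        pct_mediated = if (is.na(est$pm)) NA_real_
                       else unname(attr(est$pm, "display")),
        n_used = est$n_used, reps = est$reps, engine = est$engine)
      logi("mediation %s ~ %s: NDE %.3f, NIE %.3f, TCE %.3f",
           grid$outcome[i], grid$mediator[i], est$nde[["est"]],
           est$nie[["est"]], est$tce[["est"]])
    }
    tab4 <- do.call(rbind, rows)
    path <- file.path(rc$out_dir, "table4_mediation.csv")
    hdr <- c(sprintf("# gcmediate mediation report"),
             sprintf("# bootstrap_reps=%d mc_draws=%d ci_level=%s seed=%s",
                     rc$gcomp$bootstrap_reps, rc$gcomp$mc_draws,
                     format(rc$gcomp$ci_level),
                     format(rc$gcomp$seed %||% "NULL")))
    writeLines(hdr, path)
    suppressWarnings(
      write.table(tab4, path, sep = ",", row.names = FALSE, na = "",
                  append = TRUE, qmethod = "double"))
    files <- c(files, path)
    logi("wrote %s (%d rows)", path, nrow(tab4))
    results$mediation <- ests
    results$mediation_table <- tab4
  }

  writeLines(log_lines, log_path)
  files <- c(files, log_path)
  invisible(list(files = files, cohort = cohort, results = results))
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a config file describing a pipeline run.  Recognised top-level
#' keys mirror the arguments of [run_config()]; `generation: default`
#' requests [default_generation_config()] with keys `n_rows` and `seed`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  gen <- NULL
  if (identical(raw$mode, "generate")) {
    if (identical(raw$generation, "default") || is.null(raw$generation)) {
      # key is n_rows because a bare `n` is a YAML 1.1 boolean
      gen <- default_generation_config(n = raw$n_rows %||% raw$n %||% 1680,
                                       seed = raw$seed)
    } else {
      stop("only 'generation: default' configs are supported from file; ",
           "construct custom generation configs in R")
    }
  }
  gc_args <- raw$gcomp %||% list()
  gcomp <- do.call(gcomp_config, gc_args)
  run_config(mode = raw$mode %||% "generate",
             generation = gen, csv_path = raw$csv_path,
             roles = lapply(raw$roles, unlist),
             analyses = raw$analyses %||% c("descriptives", "adjusted",
                                            "mediation"),
             mediation_grid = if (!is.null(raw$mediation_grid)) {
               as.data.frame(raw$mediation_grid)
             },
             log_outcomes = unlist(raw$log_outcomes) %||% character(),
             gcomp = gcomp, out_dir = raw$out_dir %||% ".",
             seed = raw$seed)
}
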
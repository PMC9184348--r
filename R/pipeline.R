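#' Pipeline configuration
#'
#' Single configuration object for the end-to-end run: simulate (or load)
#' a cohort, derive clinical covariates, select and fit the Cox model on
#' the derivation set, build the score sheet and risk table, and evaluate
#' discrimination and calibration on both sets.
#'
#' @param cohort_spec a [cohort_spec()], or a path to an existing cohort
#'   table in the [write_cohort()] schema.
#' @param split_seed seed of the 2:1 derivation/validation split.
#' @param horizons evaluation horizons in years, positive and sorted.
#' @param screening_alpha univariable candidate threshold (default 0.20).
#' @param retention_alpha backward-elimination retention threshold
#'   (default 0.05); must not exceed `screening_alpha`.
#' @param hl_groups Hosmer-Lemeshow group count (default 10).
#' @param candidates candidate model terms for selection.
#' @param output_dir directory for serialized artifacts (`NULL`: nothing
#'   written).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(cohort_spec = ckdscore::cohort_spec(),
                            split_seed = 1,
                            horizons = c(3, 5, 10),
                            screening_alpha = 0.20,
                            retention_alpha = 0.05,
                            hl_groups = 10,
                            candidates = c("age", "sex", "duration_cat",
                                           "bmi_cat", "fpgcv_cat", "stroke",
                                           "hypertension", "smoking",
                                           "alcohol", "physical_inactivity",
                                           "coronary_artery_disease",
                                           "carotid_atherosclerosis",
                                           "retinopathy", "hyperlipidemia",
                                           "hyperuricemia"),
                            output_dir = NULL) {
  if (!(retention_alpha > 0 && retention_alpha <= screening_alpha &&
        screening_alpha < 1))
    stop_invalid("retention_alpha",
                 "need 0 < retention_alpha <= screening_alpha < 1")
  if (any(horizons <= 0) || is.unsorted(horizons))
    stop_invalid("horizons", "must be positive and sorted increasing")
  structure(list(cohort_spec = cohort_spec, split_seed = split_seed,
                 horizons = horizons, screening_alpha = screening_alpha,
                 retention_alpha = retention_alpha, hl_groups = hl_groups,
                 candidates = candidates, output_dir = output_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `cohort_spec`
#' may be a path string or a mapping with `n_subjects`, `seed`,
#' `covariate_params`, `true_coefficients`, `baseline_hazard`,
#' `censoring`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cs <- y$cohort_spec
  if (is.list(cs)) {
    cs <- cohort_spec(
      n_subjects = cs$n_subjects %||% 2051,
      seed = cs$seed %||% 1,
      covariate_params = cs$covariate_params %||% list(),
      true_coefficients = if (!is.null(cs$true_coefficients))
        unlist(cs$true_coefficients) else NULL,
      baseline_hazard = cs$baseline_hazard %||% list(shape = 1.4, scale = 300),
      censoring = cs$censoring %||% list(admin_years = 10,
                                         annual_dropout = 0.005)
    )
  }
  pipeline_config(
    cohort_spec = cs %||% cohort_spec(),
    split_seed = y$split_seed %||% 1,
    horizons = y$horizons %||% c(3, 5, 10),
    screening_alpha = y$screening_alpha %||% 0.20,
    retention_alpha = y$retention_alpha %||% 0.05,
    hl_groups = y$hl_groups %||% 10,
    candidates = y$candidates %||% eval(formals(pipeline_config)$candidates),
    output_dir = y$output_dir
  )
}

#' Run the full derivation/validation pipeline
#'
#' Stages: simulate (or load) the cohort; split 2:1 into derivation and
#' validation sets; derive clinical covariates; compute crude hazard
#' ratios and the stratified incidence table; two-stage variable selection
#' and final Cox fit on the derivation set; score sheet and risk table;
#' evaluation on both sets. When `output_dir` is set, every artifact is
#' serialized (cohort and derived tables as TSV, fit / selection / sheet /
#' report as JSON, risk table as TSV) together with a run log recording
#' seeds and package versions. A stage failure aborts with the stage name
#' and leaves a FAILED marker in the output directory.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return invisibly, a list with `cohort`, `derived`, `split` (row
#'   indices), `incidence`, `crude_hr`, `selection`, `fit`, `ph_check`,
#'   `sheet`, `risk_table`, `report`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(c(log_lines, paste("FAILED at stage:", name),
                     conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (is.character(config$cohort_spec)) read_cohort(config$cohort_spec)
    else generate_cohort(config$cohort_spec)
  })
  say("cohort: %d subjects", nrow(cohort))

  split <- stage("split", split_cohort(cohort, c(2, 1), config$split_seed))
  derived <- stage("derive", derive_covariates(cohort))
  deriv <- derive_covariates(split$derivation)
  valid <- derive_covariates(split$validation)

  incid <- stage("incidence", incidence_table(
    derived, c("duration_cat", "bmi_cat", "fpgcv_cat", "stroke",
               "hypertension")))
  crude <- stage("crude-hazard-ratios", {
    fs <- c("duration_cat", "bmi_cat", "fpgcv_cat", "stroke", "hypertension")
    stats::setNames(lapply(fs, function(f) crude_hazard_ratios(derived, f)), fs)
  })

  sel <- stage("select", select_model(
    deriv, config$candidates, config$screening_alpha,
    config$retention_alpha, horizons = config$horizons))
  if (is.null(sel$fit))
    stop("pipeline failed at stage 'select': empty final model", call. = FALSE)
  say("final model terms: %s", paste(sel$trace$final_terms, collapse = ", "))

  ph <- stage("ph-check", check_proportional_hazards(sel$fit))

  sheet <- stage("build-score", build_score_sheet(sel$fit))
  risk_table <- stage("risk-table", build_risk_table(
    sheet, sel$fit, config$horizons,
    anchor = "mean", mean_points = mean(score_subjects(deriv, sheet))))
  say("score range 0-%d", sheet$max_total)

  report <- stage("evaluate", evaluate_model(
    deriv, valid, sheet, risk_table, config$horizons, config$hl_groups))

  res <- list(cohort = cohort, derived = derived,
              split = split, incidence = incid, crude_hr = crude,
              selection = sel$trace, fit = sel$fit, ph_check = ph,
              sheet = sheet, risk_table = risk_table, report = report)

  if (!is.null(out_dir)) {
    stage("write-artifacts", {
      spec <- if (is.character(config$cohort_spec)) NULL else config$cohort_spec
      write_cohort(cohort, file.path(out_dir, "cohort.tsv"), spec)
      utils::write.table(derived, file.path(out_dir, "derived.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_selection_trace(sel$trace, file.path(out_dir, "selection.json"))
      write_cox_fit(sel$fit, file.path(out_dir, "fit.json"))
      write_score_sheet(sheet, file.path(out_dir, "score_sheet.json"))
      write_risk_table(risk_table, file.path(out_dir, "risk_table.tsv"))
      jsonlite::write_json(
        list(split_sizes = as.list(report$split_sizes),
             standardized_differences = as.list(report$standardized_differences),
             auc = report$auc, hl = report$hl),
        file.path(out_dir, "evaluation.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      seeds <- c(cohort_seed = if (is.null(spec)) NA else spec$seed,
                 split_seed = config$split_seed)
      writeLines(c(
        sprintf("ckdscore %s on R %s.%s",
                as.character(utils::packageVersion("ckdscore")),
                R.version$major, R.version$minor),
        sprintf("survival %s, pROC %s",
                as.character(utils::packageVersion("survival")),
                as.character(utils::packageVersion("pROC"))),
        sprintf("seeds: %s", paste(names(seeds), seeds, sep = "=",
                                   collapse = ", ")),
        log_lines
      ), file.path(out_dir, "run_log.txt"))
    })
  }
  invisible(res)
}
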
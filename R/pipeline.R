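# End-to-end orchestration: characterise -> shift tables -> redistribution
# -> survival evaluation, as a pure function of (inputs, config, seeds).

#' Pipeline configuration
#'
#' @param models Risk models to analyse (any of `"eau"`, `"aua"`, `"cpg"`).
#' @param diagnostic_cohort Diagnostic cohort tibble, or `NULL` to use the
#'   default deterministic synthetic cohort from [gen_diagnostic_cohort()].
#' @param allocations Named list of group allocation tibbles (one per
#'   model), or `NULL` to use the published original allocations shipped
#'   with the package ([table3_allocation()]).
#' @param mode Redistribution mode, `"expected"` or `"stochastic"`.
#' @param seed Integer seed used for every stochastic stage.
#' @param bootstrap Bootstrap replicates for C-index CIs (0 = none).
#' @param evaluate Run the survival evaluation stage (the slowest stage).
#' @param population Generator configuration for expanding allocations
#'   (see [population_config()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(models = c("eau", "aua", "cpg"),
                            diagnostic_cohort = NULL,
                            allocations = NULL,
                            mode = c("expected", "stochastic"),
                            seed = 1L,
                            bootstrap = 0L,
                            evaluate = TRUE,
                            population = population_config()) {
  models <- match.arg(models, several.ok = TRUE)
  mode <- match.arg(mode)
  structure(list(models = models, diagnostic_cohort = diagnostic_cohort,
                 allocations = allocations, mode = mode, seed = as.integer(seed),
                 bootstrap = as.integer(bootstrap), evaluate = evaluate,
                 population = population),
            class = "pipeline_config")
}

stage_call <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "progshift_pipeline_error", parent = e)
  })
}

#' Run the full reclassification-impact pipeline
#'
#' Stages: (1) classify both characterisations of the diagnostic cohort and
#' build stage, grade and per-model risk shift tables plus crosstabs;
#' (2) retrofit each model's percentage-point shifts onto its population
#' allocation ([redistribute()]); (3) expand the original and redistributed
#' allocations to individual records and evaluate each model's hazard
#' ratios and Harrell's C ([evaluate_allocation()]), with Kaplan-Meier
#' curve data for plotting. The result is a pure function of the inputs,
#' the configuration and the seed; metadata records seeds and a
#' configuration digest.
#'
#' @param config A [pipeline_config()].
#' @return A `progshift_report` list with elements `shift_tables`,
#'   `crosstabs`, `redistributed`, `fits`, `km`, `metadata`.
#' @examples
#' report <- run_pipeline(pipeline_config(models = "eau", evaluate = FALSE))
#' report$shift_tables$risk$eau
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cohort <- config$diagnostic_cohort %||%
    stage_call("simulate-cohort", gen_diagnostic_cohort())
  shift_tables <- list(
    stage = stage_call("shift-table", stage_shift(cohort)),
    grade = stage_call("shift-table", grade_shift(cohort)),
    risk = purrr::map(setNames(config$models, config$models),
                      ~ stage_call("shift-table", risk_shift(cohort, .x)))
  )
  crosstabs <- purrr::map(setNames(config$models, config$models),
                          ~ stage_call("crosstab", risk_crosstab(cohort, .x)))
  allocations <- config$allocations %||%
    purrr::map(setNames(config$models, config$models),
               ~ stage_call("load-allocation", table3_allocation(.x)))
  redistributed <- purrr::map(setNames(config$models, config$models), function(m) {
    stage_call("redistribute",
               redistribute(allocations[[m]], shift_tables$risk[[m]],
                            mode = config$mode, seed = config$seed))
  })
  fits <- NULL
  km <- NULL
  if (isTRUE(config$evaluate)) {
    fits <- purrr::map(setNames(config$models, config$models), function(m) {
      orig <- stage_call("evaluate",
        evaluate_allocation(allocations[[m]], m, config = config$population,
                            boot = config$bootstrap, seed = config$seed))
      redis <- stage_call("evaluate",
        evaluate_allocation(redistributed[[m]][, c("model", "group", "n_alive",
                                                   "n_dead", "n_total")],
                            m, config = config$population,
                            boot = config$bootstrap, seed = config$seed))
      list(original = orig, redistributed = redis)
    })
    km <- purrr::map(setNames(config$models, config$models), function(m) {
      pop <- stage_call("evaluate",
        expand_allocation(allocations[[m]], config = config$population,
                          seed = config$seed))
      km_estimate(pop, m)
    })
  }
  structure(
    list(shift_tables = shift_tables, crosstabs = crosstabs,
         redistributed = redistributed, fits = fits, km = km,
         metadata = list(
           package_version = as.character(utils::packageVersion("progshift")),
           models = config$models, mode = config$mode, seed = config$seed,
           bootstrap = config$bootstrap,
           config_hash = rlang::hash(config))),
    class = "progshift_report")
}

#' Individualised survival prediction hook (not implemented)
#'
#' Placeholder for contrasting per-patient overall-survival predictions
#' between the clinical and MRI-enhanced characterisations with an external
#' individualised prognostic model (such as the Predict Prostate
#' algorithm). The external model is out of scope for this package; the
#' hook documents the intended interface and always raises a
#' `progshift_not_implemented` condition.
#'
#' @param cohort Diagnostic cohort tibble.
#' @param horizon_years Prediction horizon(s) in years.
#' @return Never returns.
#' @export
individual_predictions <- function(cohort, horizon_years = c(10, 15)) {
  abort(paste("Individualised prediction requires an external prognostic",
              "model and is not implemented; this hook documents the",
              "intended interface only."),
        class = "progshift_not_implemented")
}

#' Flatten Kaplan-Meier curves to long-format plot data
#'
#' @param curves A `km_curves` tibble from [km_estimate()], or a named list
#'   of them.
#' @return A tibble with columns `model`, `group`, `time`, `survival`,
#'   `at_risk`, suitable for any plotting front end.
#' @export
render_km <- function(curves) {
  if (inherits(curves, "km_curves")) curves <- list(curves)
  if (length(curves) == 0) {
    abort("No curves to render", class = "progshift_validation_error")
  }
  purrr::map_dfr(curves, function(k) {
    tibble(model = attr(k, "model") %||% NA_character_,
           group = as.character(k$group), time = k$time,
           survival = k$survival, at_risk = k$n_risk)
  })
}

#' Write a pipeline report to machine-readable files
#'
#' Writes every shift table, crosstab and redistributed allocation as CSV,
#' KM curve data as CSV, fit summaries and metadata as JSON. Re-running with
#' an identical configuration and seed reproduces identical file contents.
#'
#' @param report A `progshift_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_report requires the jsonlite package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(report$shift_tables$stage), file.path(dir, "shift_stage.csv"))
  readr::write_csv(tidy(report$shift_tables$grade), file.path(dir, "shift_grade.csv"))
  for (m in names(report$shift_tables$risk)) {
    readr::write_csv(tidy(report$shift_tables$risk[[m]]),
                     file.path(dir, sprintf("shift_risk_%s.csv", m)))
    readr::write_csv(as_tibble(unclass(report$crosstabs[[m]])),
                     file.path(dir, sprintf("crosstab_%s.csv", m)))
    readr::write_csv(as_tibble(unclass(report$redistributed[[m]])),
                     file.path(dir, sprintf("redistributed_%s.csv", m)))
  }
  if (!is.null(report$km)) {
    readr::write_csv(render_km(report$km), file.path(dir, "km_curves.csv"))
  }
  if (!is.null(report$fits)) {
    fits <- purrr::map(report$fits, function(f) {
      purrr::map(f, function(x) {
        list(hazard_ratios = tidy(x), summary = glance(x))
      })
    })
    jsonlite::write_json(fits, file.path(dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(report$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
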
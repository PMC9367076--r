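# CSV schemas, readers/writers and validation for the three tabular inputs:
# diagnostic cohorts (one row per patient, paired clinical/MRI attributes),
# grouped population allocations (per-risk-group alive/dead counts) and
# individual-level population cohorts (censored survival records).
# Dialect: comma-separated UTF-8, mandatory header, missing values as empty
# strings. PSA density is always recomputed from PSA and volume, never read.

diagnostic_required_cols <- c("patient_id", "age", "psa", "clinical_t",
                              "radiological_t", "gg_systematic", "gg_combined")
diagnostic_all_cols <- c("patient_id", "age", "psa", "prostate_volume",
                         "likert", "clinical_t", "radiological_t",
                         "gg_systematic", "gg_combined")

parse_num_col <- function(x, col, id, strict, integer = FALSE) {
  val <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x != "" & is.na(val)
  if (integer) bad <- bad | (!is.na(val) & val != floor(val))
  if (any(bad)) {
    msg <- sprintf("Non-numeric %s for patient_id %s: '%s'",
                   col, id[bad][1], x[bad][1])
    if (strict) abort(msg, class = "progshift_validation_error")
  }
  list(value = val, bad = bad)
}

#' Read and validate a diagnostic cohort CSV
#'
#' Expects columns `patient_id`, `age`, `psa`, `prostate_volume`, `likert`,
#' `clinical_t`, `radiological_t`, `gg_systematic`, `gg_combined` (volume and
#' likert optional). Row-level invariants: PSA finite and positive;
#' `gg_systematic` in 0-5 (0 = benign systematic biopsy); `gg_combined` in
#' 1-5 (every retained record is a diagnosed cancer); valid T stages. A
#' `psa_density` column (PSA / volume) and a `benign_systematic` flag are
#' derived. Under `strict = TRUE` any violation aborts naming the patient
#' and column; otherwise offending rows are dropped with a message.
#'
#' @param path Path to a CSV file.
#' @param strict Abort on invalid rows (`TRUE`, default) or drop them.
#' @return A validated tibble, one row per patient.
#' @seealso [write_diagnostic_cohort()], [gen_diagnostic_cohort()]
#' @export
read_diagnostic_cohort <- function(path, strict = TRUE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(diagnostic_required_cols, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "progshift_schema_error")
  }
  if (!"prostate_volume" %in% names(raw)) raw$prostate_volume <- ""
  if (!"likert" %in% names(raw)) raw$likert <- ""
  if (nrow(raw) == 0) return(validate_diagnostic_cohort(empty_diagnostic(), strict))

  id <- raw$patient_id
  num <- list(
    age = parse_num_col(raw$age, "age", id, strict),
    psa = parse_num_col(raw$psa, "psa", id, strict),
    prostate_volume = parse_num_col(raw$prostate_volume, "prostate_volume", id, strict),
    likert = parse_num_col(raw$likert, "likert", id, strict, integer = TRUE),
    gg_systematic = parse_num_col(raw$gg_systematic, "gg_systematic", id, strict, integer = TRUE),
    gg_combined = parse_num_col(raw$gg_combined, "gg_combined", id, strict, integer = TRUE)
  )
  out <- tibble(
    patient_id = id,
    age = num$age$value,
    psa = num$psa$value,
    prostate_volume = num$prostate_volume$value,
    likert = as.integer(num$likert$value),
    clinical_t = dplyr::na_if(raw$clinical_t, ""),
    radiological_t = dplyr::na_if(raw$radiological_t, ""),
    gg_systematic = as.integer(num$gg_systematic$value),
    gg_combined = as.integer(num$gg_combined$value)
  )
  unparsable <- Reduce(`|`, lapply(num, `[[`, "bad"))
  validate_diagnostic_cohort(out[!unparsable, , drop = FALSE], strict,
                             n_unparsable = sum(unparsable))
}

empty_diagnostic <- function() {
  tibble(patient_id = character(), age = numeric(), psa = numeric(),
         prostate_volume = numeric(), likert = integer(),
         clinical_t = character(), radiological_t = character(),
         gg_systematic = integer(), gg_combined = integer())
}

#' Validate a diagnostic cohort data frame
#'
#' Applies the row-level invariants documented in
#' [read_diagnostic_cohort()] and derives `psa_density` and
#' `benign_systematic`. Normalises T stages to whole groups while retaining
#' any substage detail in `clinical_t_detail` / `radiological_t_detail`.
#'
#' @param data Data frame with the diagnostic cohort columns.
#' @param strict Abort on invalid rows or drop them with a message.
#' @param n_unparsable Internal; count of rows already dropped upstream.
#' @return Validated tibble.
#' @export
validate_diagnostic_cohort <- function(data, strict = TRUE, n_unparsable = 0) {
  data <- as_tibble(data)
  bad_reason <- rep(NA_character_, nrow(data))
  flag <- function(cond, reason) {
    cond <- !is.na(cond) & cond
    bad_reason[cond & is.na(bad_reason)] <<- reason
  }
  flag(is.na(data$patient_id) | data$patient_id == "", "missing patient_id")
  flag(is.na(data$psa) | !is.finite(data$psa) | data$psa <= 0, "psa")
  flag(!is.na(data$prostate_volume) & data$prostate_volume <= 0, "prostate_volume")
  flag(!is.na(data$likert) & !(data$likert %in% 1:5), "likert")
  flag(is.na(data$gg_systematic) | !data$gg_systematic %in% 0:5, "gg_systematic")
  flag(is.na(data$gg_combined) | !data$gg_combined %in% 1:5, "gg_combined")
  t_ok <- function(x) grepl("^[Tt][1-4][a-c]?$", x)
  flag(is.na(data$clinical_t) | !t_ok(data$clinical_t), "clinical_t")
  flag(is.na(data$radiological_t) | !t_ok(data$radiological_t), "radiological_t")

  bad <- !is.na(bad_reason)
  if (any(bad)) {
    if (strict) {
      abort(sprintf("Invalid %s for patient_id %s",
                    bad_reason[bad][1], data$patient_id[bad][1]),
            class = "progshift_validation_error")
    }
    data <- data[!bad, , drop = FALSE]
  }
  n_dropped <- sum(bad) + n_unparsable
  if (!strict && n_dropped > 0) {
    inform(sprintf("Dropped %d invalid row(s) from diagnostic cohort", n_dropped))
  }
  substage <- function(x) ifelse(grepl("^[Tt][1-4][a-c]$", x), toupper(x), NA_character_)
  data %>%
    mutate(
      clinical_t_detail = substage(.data$clinical_t),
      radiological_t_detail = substage(.data$radiological_t),
      clinical_t = t_group(.data$clinical_t),
      radiological_t = t_group(.data$radiological_t),
      psa_density = .data$psa / .data$prostate_volume,
      benign_systematic = .data$gg_systematic == 0L
    )
}

#' Write a diagnostic cohort CSV
#'
#' Writes the schema columns only; derived columns (`psa_density`,
#' `benign_systematic`, substage detail) are recomputed on read, so a
#' write/read round trip is the identity on the stored fields.
#'
#' @param data Diagnostic cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnostic_cohort <- function(data, path) {
  out <- as_tibble(data)
  # reattach substage detail for display faithfulness
  if ("clinical_t_detail" %in% names(out)) {
    out$clinical_t <- dplyr::coalesce(out$clinical_t_detail, out$clinical_t)
    out$radiological_t <- dplyr::coalesce(out$radiological_t_detail, out$radiological_t)
  }
  readr::write_csv(out[, diagnostic_all_cols], path, na = "")
  invisible(path)
}

#' Read a grouped population allocation CSV
#'
#' Expects columns `model`, `group`, `n_alive`, `n_dead` where `n_dead`
#' counts prostate-cancer deaths only. Group labels must belong to the
#' model's canonical set; output rows are ordered best to worst prognosis.
#'
#' @param path Path to a CSV file.
#' @param model Optionally restrict to one of `"eau"`, `"aua"`, `"cpg"`.
#' @return A tibble with columns `model`, `group` (factor in prognostic
#'   order), `n_alive`, `n_dead`.
#' @export
read_group_allocation <- function(path, model = NULL) {
  raw <- readr::read_csv(path, col_types = "ccdd", progress = FALSE)
  required <- c("model", "group", "n_alive", "n_dead")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "progshift_schema_error")
  }
  raw$model <- tolower(raw$model)
  if (!is.null(model)) raw <- raw[raw$model == tolower(model), , drop = FALSE]
  validate_group_allocation(raw)
}

validate_group_allocation <- function(data) {
  data <- as_tibble(data)
  bad_model <- setdiff(unique(data$model), risk_models())
  if (length(bad_model)) {
    abort(sprintf("Unknown risk model '%s'", bad_model[1]),
          class = "progshift_validation_error")
  }
  for (m in unique(data$model)) {
    lev <- risk_group_levels(m)
    bad <- setdiff(data$group[data$model == m], lev)
    if (length(bad)) {
      abort(sprintf("Unknown group label '%s' for model %s", bad[1], m),
            class = "progshift_validation_error")
    }
  }
  if (any(data$n_alive < 0 | data$n_dead < 0, na.rm = TRUE) ||
      anyNA(data$n_alive) || anyNA(data$n_dead)) {
    abort("Allocation counts must be non-negative",
          class = "progshift_validation_error")
  }
  data %>%
    group_by(.data$model) %>%
    group_modify(function(d, key) {
      lev <- risk_group_levels(key$model)
      if (anyDuplicated(d$group)) {
        abort(sprintf("Duplicated group label in model %s", key$model),
              class = "progshift_validation_error")
      }
      d$group <- factor(d$group, levels = lev)
      arrange(d, .data$group)
    }) %>%
    ungroup() %>%
    mutate(n_total = .data$n_alive + .data$n_dead)
}

#' Read an individual-level population cohort CSV
#'
#' Expects columns `subject_id`, `group_eau`, `group_aua`, `group_cpg`,
#' `time_years`, `event` with `event` one of `pc_death`, `other_death`,
#' `censored`. Prostate-cancer-specific analyses treat `other_death` as
#' censoring.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_population_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = "ccccdc", na = "", progress = FALSE)
  required <- c("subject_id", "group_eau", "group_aua", "group_cpg",
                "time_years", "event")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "progshift_schema_error")
  }
  validate_population_cohort(raw)
}

validate_population_cohort <- function(data) {
  data <- as_tibble(data)
  if (any(!data$event %in% c("pc_death", "other_death", "censored"))) {
    abort("event must be one of pc_death, other_death, censored",
          class = "progshift_validation_error")
  }
  if (any(!is.finite(data$time_years) | data$time_years <= 0)) {
    abort("time_years must be finite and > 0",
          class = "progshift_validation_error")
  }
  for (m in risk_models()) {
    col <- paste0("group_", m)
    vals <- data[[col]]
    bad <- !is.na(vals) & !vals %in% risk_group_levels(m)
    if (any(bad)) {
      abort(sprintf("Unknown group label '%s' in %s", vals[bad][1], col),
            class = "progshift_validation_error")
    }
    data[[col]] <- factor(vals, levels = risk_group_levels(m))
  }
  data
}

#' Write a population cohort CSV
#'
#' @param data Population cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_cohort <- function(data, path) {
  cols <- c("subject_id", "group_eau", "group_aua", "group_cpg",
            "time_years", "event")
  readr::write_csv(as_tibble(data)[, cols], path, na = "")
  invisible(path)
}

#' Published population-cohort group allocations
#'
#' Grouped alive / prostate-cancer-death counts for the East-of-England
#' population cohort (n = 10,139; 789 prostate cancer deaths; median
#' follow-up 6.9 years) under each risk model, as published: the original
#' allocation and the redistributed allocation obtained in the source
#' study's own simulation run. Shipped as plain-text fixtures.
#'
#' @param model `"eau"`, `"aua"` or `"cpg"`.
#' @param arm `"original"` or `"redistributed"`.
#' @return Allocation tibble (see [read_group_allocation()]).
#' @examples
#' table3_allocation("eau")
#' @export
table3_allocation <- function(model = c("eau", "aua", "cpg"),
                              arm = c("original", "redistributed")) {
  model <- match.arg(model)
  arm <- match.arg(arm)
  path <- system.file("extdata", paste0("population_allocation_", arm, ".csv"),
                      package = "progshift", mustWork = TRUE)
  read_group_allocation(path, model = model)
}
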
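# Synthetic diagnostic cohort generator. The published study reports only
# the marginal distributions of the paired clinical/MRI characterisations
# (stage, Grade Group and risk group counts); the joint clinical-by-MRI
# transition structure is not published. The default joint table below is a
# minimal-movement feasible solution - stage moves are upgrades only, grade
# moves are upgrades plus the benign-to-cancer transitions of the 16
# systematic-benign cases - constructed so that every published margin is
# reproduced exactly. It is synthetic: any per-patient transition detail it
# implies beyond the margins is a modelling construct, not an observation.

#' Default joint clinical-by-MRI cell table
#'
#' One row per cell of the joint distribution over (PSA band, clinical T
#' group, systematic-biopsy Grade Group) x (radiological T group,
#' combined-biopsy Grade Group), with cell counts summing to 370. Both
#' margins reproduce the published diagnostic-cohort counts exactly:
#' clinical stage 263/107 (T1-T2/T3), radiological 234/136; systematic
#' grades 101/123/60/13/57 plus 16 benign, combined 96/133/63/17/61; and the
#' implied risk-group margins under [classify_all()] for all three systems.
#'
#' @return A tibble with columns `n`, `psa_band`, `clinical_t`,
#'   `gg_systematic`, `radiological_t`, `gg_combined`.
#' @examples
#' sum(build_default_joint_table()$n)  # 370
#' @export
build_default_joint_table <- function() {
  tab <- tibble::tribble(
    ~n, ~psa_band, ~clinical_t, ~gg_systematic, ~radiological_t, ~gg_combined,
    17L, "lt10", "T1", 1L, "T1", 1L,   # MRI-invisible, systematic-only
    44L, "lt10", "T1", 1L, "T2", 1L,
     6L, "lt10", "T1", 1L, "T3", 1L,
    14L, "mid",  "T2", 1L, "T2", 1L,
     4L, "mid",  "T2", 1L, "T2", 2L,
     2L, "mid",  "T2", 1L, "T3", 1L,
     8L, "lt10", "T3", 1L, "T3", 1L,
     6L, "lt10", "T3", 1L, "T3", 2L,
    58L, "lt10", "T2", 2L, "T2", 2L,
     4L, "lt10", "T2", 2L, "T2", 3L,
     2L, "lt10", "T2", 2L, "T3", 3L,
     2L, "lt10", "T2", 2L, "T3", 2L,
    36L, "mid",  "T2", 2L, "T2", 2L,
     4L, "mid",  "T2", 2L, "T3", 2L,
    10L, "lt10", "T3", 2L, "T3", 2L,
     3L, "gt20", "T2", 2L, "T2", 2L,
     2L, "gt20", "T2", 2L, "T3", 2L,
     2L, "gt20", "T3", 2L, "T3", 2L,
    20L, "lt10", "T2", 3L, "T2", 3L,
     2L, "lt10", "T2", 3L, "T2", 4L,
     3L, "lt10", "T2", 3L, "T2", 5L,
     4L, "lt10", "T2", 3L, "T3", 3L,
    20L, "lt10", "T3", 3L, "T3", 3L,
     7L, "gt20", "T2", 3L, "T2", 3L,
     2L, "gt20", "T2", 3L, "T3", 3L,
     2L, "gt20", "T3", 3L, "T3", 3L,
     5L, "lt10", "T2", 4L, "T2", 4L,
     1L, "lt10", "T2", 4L, "T3", 4L,
     7L, "lt10", "T3", 4L, "T3", 4L,
     3L, "lt10", "T2", 5L, "T2", 5L,
     4L, "lt10", "T2", 5L, "T3", 5L,
    50L, "lt10", "T3", 5L, "T3", 5L,
    # benign systematic biopsies, cancer found on targeted cores
     5L, "lt10", "T1", 0L, "T2", 1L,
     6L, "lt10", "T1", 0L, "T2", 2L,
     1L, "lt10", "T1", 0L, "T2", 3L,
     1L, "lt10", "T3", 0L, "T3", 3L,
     1L, "lt10", "T1", 0L, "T2", 4L,
     1L, "lt10", "T3", 0L, "T3", 4L,
     1L, "lt10", "T1", 0L, "T2", 5L
  )
  tab
}

psa_band_range <- function(band) {
  switch(band,
         lt10 = c(1.2, 9.9),
         mid = c(10, 20),
         gt20 = c(21, 108),
         abort(sprintf("Unknown PSA band '%s'", band),
               class = "progshift_validation_error"))
}

#' Diagnostic cohort generator configuration
#'
#' @param n Cohort size (deterministic mode requires the joint table counts
#'   to sum to `n`).
#' @param joint_table Joint cell table (see [build_default_joint_table()]).
#' @param age_range,volume_range Sampling ranges for age (years) and
#'   prostate volume (ml).
#' @return A `diagnostic_config` list.
#' @export
diagnostic_config <- function(n = 370L,
                              joint_table = build_default_joint_table(),
                              age_range = c(45, 80),
                              volume_range = c(17.9, 191)) {
  structure(list(n = as.integer(n), joint_table = as_tibble(joint_table),
                 age_range = age_range, volume_range = volume_range),
            class = "diagnostic_config")
}

check_joint_table <- function(tab, n, mode) {
  required <- c("n", "psa_band", "clinical_t", "gg_systematic",
                "radiological_t", "gg_combined")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("Joint table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "progshift_schema_error")
  }
  if (any(tab$n < 0)) {
    abort("Joint table cell counts must be non-negative",
          class = "progshift_validation_error")
  }
  if (mode == "deterministic" && sum(tab$n) != n) {
    abort(sprintf("Infeasible margin: joint table cells sum to %d, not n = %d",
                  sum(tab$n), n),
          class = "progshift_validation_error")
  }
  invisible(tab)
}

# Deterministic within-range value grids: evenly spaced, reproducible, and
# spanning the published range endpoints.
grid_values <- function(range, n) {
  if (n == 1) return(mean(range))
  seq(range[1], range[2], length.out = n)
}

#' Generate a synthetic diagnostic cohort
#'
#' Expands the configured joint cell table into one record per patient.
#' Deterministic mode emits exactly the configured cell counts (and with the
#' default table reproduces every published margin exactly under
#' [classify_all()]); multinomial mode draws `n` cells with seeded sampling,
#' so margins match in expectation and converge as `n` grows. PSA values are
#' placed on a deterministic grid within each record's band (spanning the
#' published 1.2-108 ng/ml range), ages within 45-80 and volumes within
#' 17.9-191 ml; Likert scores follow the published distribution (17 negative
#' MRIs staged rT1, 29/79/193 scored 3/4/5, 52 not stated).
#'
#' @param config A [diagnostic_config()].
#' @param mode `"deterministic"` or `"multinomial"`.
#' @param seed Integer seed (multinomial mode).
#' @return A validated diagnostic cohort tibble
#'   (schema of [read_diagnostic_cohort()]).
#' @examples
#' cohort <- gen_diagnostic_cohort()
#' nrow(cohort)  # 370
#' @export
gen_diagnostic_cohort <- function(config = diagnostic_config(),
                                  mode = c("deterministic", "multinomial"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  tab <- config$joint_table
  check_joint_table(tab, config$n, mode)
  if (mode == "deterministic") {
    rows <- rep(seq_len(nrow(tab)), tab$n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rows <- sample.int(nrow(tab), config$n, replace = TRUE,
                       prob = tab$n / sum(tab$n))
  }
  cells <- tab[rows, c("psa_band", "clinical_t", "gg_systematic",
                       "radiological_t", "gg_combined")]
  n <- nrow(cells)
  out <- cells %>%
    mutate(patient_id = sprintf("P%04d", seq_len(n))) %>%
    group_by(.data$psa_band) %>%
    mutate(psa = grid_values(psa_band_range(.data$psa_band[1]), dplyr::n())) %>%
    ungroup() %>%
    mutate(age = round(grid_values(config$age_range, n)[rank_cycle(n)]),
           prostate_volume = round(grid_values(config$volume_range, n)[rank_cycle(n, 7L)], 1),
           likert = assign_likert(.data$radiological_t, .data$gg_systematic))
  validate_diagnostic_cohort(
    out[, c("patient_id", "age", "psa", "prostate_volume", "likert",
            "clinical_t", "radiological_t", "gg_systematic", "gg_combined")])
}

# Deterministic permutation used to decorrelate grid-assigned covariates
# from row (hence cell) order.
rank_cycle <- function(n, stride = 3L) {
  order((seq_len(n) * stride) %% n, seq_len(n))
}

# Published Likert margin: rT1 records are the MRI-negative (Likert 1-2)
# systematic-only biopsies; visible lesions score 3-5 or are unrecorded.
assign_likert <- function(rad_t, gg_sys) {
  n <- length(rad_t)
  likert <- rep(NA_integer_, n)
  invisible_idx <- which(rad_t == "T1" & gg_sys > 0)
  likert[invisible_idx] <- rep(c(1L, 2L), length.out = length(invisible_idx))
  visible_idx <- which(is.na(likert))
  pool <- rep(c(3L, 4L, 5L, NA_integer_),
              times = pmax(0, round(length(visible_idx) *
                                      c(29, 79, 193, 52) / 353)))
  pool <- rep(pool, length.out = length(visible_idx))
  likert[visible_idx] <- pool
  likert
}
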
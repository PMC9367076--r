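# Shift tables contrasting the clinical characterisation (DRE stage +
# systematic biopsies) with the MRI-enhanced characterisation (radiological
# stage + combined targeted/systematic biopsies) of the same patients.
#
# Rounding convention: percentages are reported to 1 decimal place,
# round-half-away-from-zero. The percentage-point delta is the exact
# net-count percentage when both characterisations share a denominator
# (stage and grade tables), and the difference of the 1-dp percentages when
# denominators differ (risk tables: cancers-only clinical denominator vs all
# combined-biopsy cancers). See the vignette for why.

round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

make_shift_table <- function(category, n_clinical, n_mri,
                             denom_clinical, denom_mri, model = NA_character_) {
  pct_clin <- round1(100 * n_clinical / denom_clinical)
  pct_mri <- round1(100 * n_mri / denom_mri)
  delta <- if (denom_clinical == denom_mri) {
    round1(100 * (n_mri - n_clinical) / denom_mri)
  } else {
    round1(pct_mri - pct_clin)
  }
  out <- tibble(category = category,
                n_clinical = as.integer(n_clinical), pct_clinical = pct_clin,
                n_mri = as.integer(n_mri), pct_mri = pct_mri,
                delta_pp = delta)
  structure(out,
            class = c("shift_table", class(out)),
            denom_clinical = as.integer(denom_clinical),
            denom_mri = as.integer(denom_mri),
            model = model)
}

check_cohort_complete <- function(cohort, cols) {
  for (col in cols) {
    missing <- is.na(cohort[[col]])
    if (any(missing)) {
      abort(sprintf("Missing %s for patient_id(s): %s", col,
                    paste(cohort$patient_id[missing], collapse = ", ")),
            class = "progshift_validation_error")
    }
  }
  invisible(cohort)
}

#' Stage shift table (T1-T2 vs T3)
#'
#' Net marginal shift between DRE-based and MRI-based T staging on the
#' two-category whole-T-group margin, over all biopsied patients (benign
#' systematic biopsies included). Per-patient transitions are available via
#' [risk_crosstab()].
#'
#' @param cohort Diagnostic cohort tibble.
#' @return A `shift_table` tibble over categories `T1-T2` and `T3`.
#' @examples
#' stage_shift(gen_diagnostic_cohort())
#' @export
stage_shift <- function(cohort) {
  cohort <- as_tibble(cohort)
  check_cohort_complete(cohort, c("clinical_t", "radiological_t"))
  n <- nrow(cohort)
  t3_clin <- sum(t_group(cohort$clinical_t) >= "T3")
  t3_mri <- sum(t_group(cohort$radiological_t) >= "T3")
  make_shift_table(c("T1-T2", "T3"),
                   n_clinical = c(n - t3_clin, t3_clin),
                   n_mri = c(n - t3_mri, t3_mri),
                   denom_clinical = n, denom_mri = n)
}

#' Grade Group shift table
#'
#' Distribution of histological Grade Group under systematic biopsies only
#' versus combined systematic + targeted biopsies, over all biopsied
#' patients. The `benign` category counts systematic-benign biopsies; it is
#' zero on the combined side for cohorts of diagnosed cancers.
#'
#' @param cohort Diagnostic cohort tibble.
#' @return A `shift_table` tibble over `GG1`..`GG5` and `benign`.
#' @export
grade_shift <- function(cohort) {
  cohort <- as_tibble(cohort)
  check_cohort_complete(cohort, c("gg_systematic", "gg_combined"))
  n <- nrow(cohort)
  lev <- c(1:5, 0)
  n_clin <- vapply(lev, function(g) sum(cohort$gg_systematic == g), integer(1))
  n_mri <- vapply(lev, function(g) sum(cohort$gg_combined == g), integer(1))
  make_shift_table(c(paste0("GG", 1:5), "benign"),
                   n_clinical = n_clin, n_mri = n_mri,
                   denom_clinical = n, denom_mri = n)
}

#' Risk group shift table
#'
#' Risk/prognostic group distribution under clinical versus MRI-enhanced
#' characterisation. Denominators differ by design: the clinical side covers
#' cancers diagnosed on systematic biopsy only (`gg_systematic >= 1`), the
#' MRI side all combined-biopsy cancers, so patients whose systematic cores
#' were benign enter the MRI column only.
#'
#' @param cohort Diagnostic cohort tibble.
#' @param model `"eau"`, `"aua"` or `"cpg"`.
#' @return A `shift_table` tibble over the model's groups.
#' @examples
#' risk_shift(gen_diagnostic_cohort(), "cpg")
#' @export
risk_shift <- function(cohort, model = c("eau", "aua", "cpg")) {
  model <- match.arg(model)
  cohort <- as_tibble(cohort)
  check_cohort_complete(cohort, c("psa", "gg_systematic", "gg_combined",
                                  "clinical_t", "radiological_t"))
  lev <- risk_group_levels(model)
  clin <- cohort[cohort$gg_systematic >= 1, ]
  lab_clin <- classify_risk(clin, "clinical")[[model]]
  lab_mri <- classify_risk(cohort, "mri")[[model]]
  make_shift_table(lev,
                   n_clinical = as.integer(table(lab_clin)[lev]),
                   n_mri = as.integer(table(lab_mri)[lev]),
                   denom_clinical = nrow(clin), denom_mri = nrow(cohort),
                   model = model)
}

#' Clinical-by-MRI risk group cross-tabulation
#'
#' Per-patient transition counts between clinical and MRI-enhanced risk
#' groups. Patients with benign systematic biopsies form an extra `benign`
#' clinical row. Row sums equal the clinical counts of [risk_shift()] (plus
#' the benign row) and column sums the MRI counts; the diagonal counts
#' unchanged patients.
#'
#' @param cohort Diagnostic cohort tibble.
#' @param model `"eau"`, `"aua"` or `"cpg"`.
#' @return A tibble with columns `clinical`, `mri`, `n` covering the full
#'   grid of category pairs.
#' @examples
#' risk_crosstab(gen_diagnostic_cohort(), "eau")
#' @export
risk_crosstab <- function(cohort, model = c("eau", "aua", "cpg")) {
  model <- match.arg(model)
  cohort <- as_tibble(cohort)
  lev <- risk_group_levels(model)
  clin_lab <- as.character(classify_risk(cohort, "clinical")[[model]])
  clin_lab[cohort$gg_systematic == 0L] <- "benign"
  mri_lab <- as.character(classify_risk(cohort, "mri")[[model]])
  out <- tidyr::expand_grid(clinical = c(lev, "benign"), mri = lev) %>%
    left_join(count(tibble(clinical = clin_lab, mri = mri_lab),
                    .data$clinical, .data$mri),
              by = c("clinical", "mri")) %>%
    mutate(n = as.integer(dplyr::coalesce(.data$n, 0L)),
           clinical = factor(.data$clinical, c(lev, "benign")),
           mri = factor(.data$mri, lev)) %>%
    arrange(.data$clinical, .data$mri)
  structure(out, class = c("risk_crosstab", class(out)), model = model)
}

#' @export
print.shift_table <- function(x, ...) {
  model <- attr(x, "model")
  header <- if (!is.na(model %||% NA_character_)) {
    sprintf("Shift table (%s): clinical n = %d, MRI-enhanced n = %d",
            toupper(model), attr(x, "denom_clinical"), attr(x, "denom_mri"))
  } else {
    sprintf("Shift table: clinical n = %d, MRI-enhanced n = %d",
            attr(x, "denom_clinical"), attr(x, "denom_mri"))
  }
  cat(header, "\n")
  NextMethod()
}

#' @rdname tidy.shift_table
#' @method tidy shift_table
#' @export
tidy.shift_table <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy and summarise shift tables
#'
#' `tidy()` returns the table as a plain tibble; `glance()` returns the two
#' denominators and the total absolute percentage-point movement.
#'
#' @param x A `shift_table`.
#' @param ... Unused.
#' @return A tibble.
#' @method glance shift_table
#' @export
glance.shift_table <- function(x, ...) {
  tibble(model = attr(x, "model"),
         denom_clinical = attr(x, "denom_clinical"),
         denom_mri = attr(x, "denom_mri"),
         total_abs_shift_pp = sum(abs(x$delta_pp)))
}
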
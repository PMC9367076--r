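# Deterministic pre-treatment risk/prognostic group assignment from
# (Grade Group, PSA, whole T group). All three systems are operationalised
# on whole T groups only: T2 substage information (T2a/b/c) is deliberately
# ignored, following the 2017 TNM (v8) abandonment of T2 substages, so the
# EAU and AUA tiers become exact collapses of the 5-tier CPG model.

#' Canonical risk group levels
#'
#' Ordered category labels (best to worst prognosis) for each of the three
#' supported risk/prognostic classification systems.
#'
#' @param model One of `"eau"`, `"aua"`, `"cpg"` (case-insensitive).
#' @return Character vector of ordered group labels.
#' @examples
#' risk_group_levels("cpg")
#' @export
risk_group_levels <- function(model) {
  switch(tolower(model),
    eau = c("low", "intermediate", "high"),
    aua = c("low", "favourable_intermediate", "unfavourable_intermediate", "high"),
    cpg = paste0("CPG", 1:5),
    abort(sprintf("Unknown risk model '%s' (expected eau, aua or cpg)", model),
          class = "progshift_validation_error")
  )
}

risk_models <- function() c("eau", "aua", "cpg")

#' Normalise a tumour T stage to its whole T group
#'
#' Accepts stages with or without substage detail (`"T3b"`, `"T2c"`, ...) and
#' returns the whole group (`"T1"`..`"T4"`). Classification never branches on
#' substages; detail is retained elsewhere for display only.
#'
#' @param t Character vector of T stages.
#' @return Character vector with values in `T1`..`T4`.
#' @examples
#' t_group(c("T3b", "T2", "t1"))
#' @export
t_group <- function(t) {
  out <- toupper(sub("^(t[1-4]).*$", "\\1", tolower(trimws(as.character(t)))))
  bad <- !is.na(t) & !out %in% paste0("T", 1:4)
  if (any(bad)) {
    abort(sprintf("Invalid T stage value(s): %s",
                  paste(unique(t[bad]), collapse = ", ")),
          class = "progshift_validation_error")
  }
  out[is.na(t)] <- NA_character_
  out
}

#' PSA band used by the risk classifiers
#'
#' Bands PSA (ng/ml) into the conventional `<10`, `10-20` (boundaries
#' inclusive) and `>20` intervals shared by the EAU, AUA and CPG systems.
#'
#' @param psa Numeric vector of PSA values in ng/ml; must be finite and > 0.
#' @return Factor with levels `lt10`, `mid`, `gt20`.
#' @examples
#' psa_band(c(4, 10, 20, 20.1))
#' @export
psa_band <- function(psa) {
  check_psa(psa)
  band <- ifelse(psa < 10, "lt10", ifelse(psa <= 20, "mid", "gt20"))
  factor(band, levels = c("lt10", "mid", "gt20"))
}

check_psa <- function(psa) {
  bad <- !is.na(psa) & (!is.finite(psa) | psa <= 0)
  if (any(bad) || anyNA(psa)) {
    abort("PSA must be finite and > 0 ng/ml for risk classification",
          class = "progshift_validation_error")
  }
  invisible(psa)
}

check_gg <- function(gg, allow_benign = FALSE) {
  lo <- if (allow_benign) 0L else 1L
  ok <- !is.na(gg) & gg == as.integer(gg) & gg >= lo & gg <= 5
  if (!all(ok)) {
    if (!allow_benign && any(gg == 0, na.rm = TRUE)) {
      abort("Benign records (Grade Group 0) have no risk group",
            class = "progshift_benign_error")
    }
    abort(sprintf("Grade Group must be an integer in %d-5", lo),
          class = "progshift_validation_error")
  }
  invisible(as.integer(gg))
}

#' Radiological T group from MRI findings
#'
#' Staging rule for diagnosed cancers: biopsy-proven but MRI-invisible
#' lesions are radiologically rT1; MRI-visible organ-confined lesions rT2;
#' extracapsular extension rT3 (detail T3a); seminal vesicle invasion rT3
#' (detail T3b). rT4 is never produced.
#'
#' @param lesion_visible Logical; was a lesion seen on MRI?
#' @param biopsy_positive Logical; staging applies to diagnosed cancers only.
#' @param mri_extent One of `"organ_confined"`, `"extracapsular"`,
#'   `"seminal_vesicle"`.
#' @return A tibble with columns `t` (whole T group) and `detail`
#'   (substage for display, `NA` when none).
#' @examples
#' mri_stage(FALSE, TRUE, "organ_confined")
#' mri_stage(TRUE, TRUE, "seminal_vesicle")
#' @export
mri_stage <- function(lesion_visible, biopsy_positive,
                      mri_extent = c("organ_confined", "extracapsular",
                                     "seminal_vesicle")) {
  n <- max(length(lesion_visible), length(biopsy_positive), length(mri_extent))
  lesion_visible <- rep_len(lesion_visible, n)
  biopsy_positive <- rep_len(biopsy_positive, n)
  mri_extent <- rep_len(match.arg(mri_extent, several.ok = TRUE), n)
  if (!all(biopsy_positive)) {
    abort("Radiological staging applies to biopsy-proven cancers only",
          class = "progshift_validation_error")
  }
  if (any(!lesion_visible & mri_extent != "organ_confined")) {
    abort("MRI-invisible lesions cannot have extraprostatic MRI extent",
          class = "progshift_validation_error")
  }
  t <- ifelse(!lesion_visible, "T1",
       ifelse(mri_extent == "organ_confined", "T2", "T3"))
  detail <- ifelse(mri_extent == "extracapsular", "T3a",
            ifelse(mri_extent == "seminal_vesicle", "T3b", NA_character_))
  tibble(t = t, detail = detail)
}

# Count of adverse features {GG4, PSA > 20, T3} used by the CPG4/CPG5 split.
adverse_count <- function(gg, psa, t) {
  (gg == 4L) + (psa > 20) + (t == "T3")
}

#' Cambridge Prognostic Group (CPG) assignment
#'
#' Five-tier prognostic grouping from Grade Group, PSA and whole T group:
#' \describe{
#'   \item{CPG1}{GG1, PSA < 10, T1-T2}
#'   \item{CPG2}{T1-T2 and exactly one of \{GG2, PSA 10-20\} (GG1 or GG2)}
#'   \item{CPG3}{T1-T2 and (GG2 with PSA 10-20, or GG3 with PSA <= 20)}
#'   \item{CPG4}{exactly one of \{GG4, PSA > 20, T3\}, GG < 5}
#'   \item{CPG5}{two or more of \{GG4, PSA > 20, T3\}, or GG5, or T4}
#' }
#'
#' @param gg Integer Grade Group 1-5 (0 = benign is an error).
#' @param psa PSA in ng/ml.
#' @param t T stage (substages tolerated, ignored).
#' @return Factor with levels `CPG1`..`CPG5`.
#' @examples
#' classify_cpg(3, 19, "T2")   # CPG3
#' classify_cpg(5, 19, "T3b")  # CPG5
#' @export
classify_cpg <- function(gg, psa, t) {
  gg <- check_gg(gg)
  check_psa(psa)
  t <- t_group(t)
  n <- max(length(gg), length(psa), length(t))
  gg <- rep_len(gg, n); psa <- rep_len(psa, n); t <- rep_len(t, n)
  mid <- psa >= 10 & psa <= 20
  k <- adverse_count(gg, psa, t)
  lab <- ifelse(gg == 5L | t == "T4" | k >= 2, "CPG5",
         ifelse(k == 1, "CPG4",
         ifelse(gg == 3L | (gg == 2L & mid), "CPG3",
         ifelse(gg == 2L | mid, "CPG2", "CPG1"))))
  factor(lab, levels = risk_group_levels("cpg"))
}

#' EAU three-tier risk group assignment
#'
#' Low: GG1, PSA < 10, T1-T2. High: GG >= 4, PSA > 20 or T >= 3.
#' Intermediate otherwise. Equivalent to collapsing CPG2/CPG3 into
#' intermediate and CPG4/CPG5 into high.
#'
#' @inheritParams classify_cpg
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
classify_eau <- function(gg, psa, t) {
  collapse_cpg(classify_cpg(gg, psa, t), "eau")
}

#' AUA four-tier risk group assignment
#'
#' Low and high coincide with the EAU tiers; the intermediate tier is split
#' into favourable (one intermediate factor, i.e. the CPG2 condition) and
#' unfavourable (the CPG3 condition). Percent-positive-core criteria are not
#' applied (see the package vignette).
#'
#' @inheritParams classify_cpg
#' @return Factor with levels `low`, `favourable_intermediate`,
#'   `unfavourable_intermediate`, `high`.
#' @export
classify_aua <- function(gg, psa, t) {
  collapse_cpg(classify_cpg(gg, psa, t), "aua")
}

#' Collapse CPG labels into the coarser EAU or AUA tiers
#'
#' The whole-T-group operationalisation makes the 3-tier EAU and 4-tier AUA
#' systems deterministic functions of the CPG label; this mapping is the
#' "collapse property" asserted throughout the package tests.
#'
#' @param cpg Factor or character vector of `CPG1`..`CPG5` labels.
#' @param to Target system, `"eau"` or `"aua"`.
#' @return Factor of collapsed labels.
#' @examples
#' collapse_cpg(c("CPG2", "CPG5"), "eau")
#' @export
collapse_cpg <- function(cpg, to = c("eau", "aua")) {
  to <- match.arg(to)
  cpg <- as.character(cpg)
  bad <- !is.na(cpg) & !cpg %in% risk_group_levels("cpg")
  if (any(bad)) {
    abort(sprintf("Unknown CPG label(s): %s", paste(unique(cpg[bad]), collapse = ", ")),
          class = "progshift_validation_error")
  }
  map <- if (to == "eau") {
    c(CPG1 = "low", CPG2 = "intermediate", CPG3 = "intermediate",
      CPG4 = "high", CPG5 = "high")
  } else {
    c(CPG1 = "low", CPG2 = "favourable_intermediate",
      CPG3 = "unfavourable_intermediate", CPG4 = "high", CPG5 = "high")
  }
  factor(unname(map[cpg]), levels = risk_group_levels(to))
}

#' Assign all three risk systems jointly
#'
#' @inheritParams classify_cpg
#' @return A tibble with columns `eau`, `aua`, `cpg` (factors); the EAU and
#'   AUA columns are collapses of the CPG column by construction.
#' @examples
#' classify_all(2, 16.4, "T2")
#' @export
classify_all <- function(gg, psa, t) {
  cpg <- classify_cpg(gg, psa, t)
  tibble(eau = collapse_cpg(cpg, "eau"),
         aua = collapse_cpg(cpg, "aua"),
         cpg = cpg)
}

#' Append risk group columns to a diagnostic cohort
#'
#' Data-frame front end to [classify_all()]: classifies one characterisation
#' of every record and appends `eau`, `aua` and `cpg` columns. The clinical
#' characterisation uses (DRE T stage, systematic-biopsy Grade Group); the
#' MRI-enhanced characterisation uses (radiological T stage, combined-biopsy
#' Grade Group). Benign-on-systematic records (`gg_systematic == 0`) have no
#' clinical risk group and receive `NA` labels under
#' `characterisation = "clinical"`.
#'
#' @param data Diagnostic cohort data frame
#'   (see [read_diagnostic_cohort()] for the schema).
#' @param characterisation `"clinical"` or `"mri"`.
#' @return `data` as a tibble with `eau`, `aua`, `cpg` columns appended.
#' @examples
#' cohort <- gen_diagnostic_cohort()
#' dplyr::count(classify_risk(cohort, "mri"), cpg)
#' @export
classify_risk <- function(data, characterisation = c("clinical", "mri")) {
  characterisation <- match.arg(characterisation)
  data <- as_tibble(data)
  if (characterisation == "clinical") {
    gg <- data$gg_systematic
    t <- data$clinical_t
  } else {
    gg <- data$gg_combined
    t <- data$radiological_t
  }
  benign <- !is.na(gg) & gg == 0L
  out <- tibble(eau = factor(NA, risk_group_levels("eau")),
                aua = factor(NA, risk_group_levels("aua")),
                cpg = factor(NA, risk_group_levels("cpg")),
                .rows = nrow(data))
  if (any(!benign)) {
    out[!benign, ] <- classify_all(gg[!benign], data$psa[!benign], t[!benign])
  }
  bind_cols(data, out)
}
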
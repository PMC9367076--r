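# The three classification systems on the whole-T-group operationalisation,
# including the exemplar patients whose characterisations are described in
# the source cohort.

test_that("radiological staging rules map MRI findings to whole T groups", {
  expect_equal(mri_stage(FALSE, TRUE, "organ_confined")$t, "T1")
  expect_equal(mri_stage(TRUE, TRUE, "organ_confined")$t, "T2")
  ecs <- mri_stage(TRUE, TRUE, "extracapsular")
  expect_equal(ecs$t, "T3")
  expect_equal(ecs$detail, "T3a")
  svi <- mri_stage(TRUE, TRUE, "seminal_vesicle")
  expect_equal(svi$t, "T3")
  expect_equal(svi$detail, "T3b")
  expect_error(mri_stage(FALSE, TRUE, "seminal_vesicle"),
               class = "progshift_validation_error")
  expect_error(mri_stage(TRUE, FALSE, "organ_confined"),
               class = "progshift_validation_error")
})

test_that("CPG assignment matches exemplar and derived cases", {
  # upgraded exemplar: systematic GG3 / PSA 19 / T2, targeted GG5 / T3b
  expect_equal(as.character(classify_cpg(3, 19, "T2")), "CPG3")
  expect_equal(as.character(classify_cpg(5, 19, "T3b")), "CPG5")
  # GG2 with intermediate-band PSA carries two intermediate factors
  expect_equal(as.character(classify_cpg(2, 16.4, "T2")), "CPG3")
  expect_equal(as.character(classify_cpg(2, 8, "T2")), "CPG2")
  expect_equal(as.character(classify_cpg(1, 5, "T1")), "CPG1")
  # exactly one adverse feature (PSA > 20)
  expect_equal(as.character(classify_cpg(3, 25, "T2")), "CPG4")
  expect_error(classify_cpg(0, 5, "T1"), class = "progshift_benign_error")
})

test_that("EAU and AUA tiers follow their rule definitions", {
  expect_equal(as.character(classify_eau(1, 9, "T2")), "low")
  expect_equal(as.character(classify_eau(3, 19, "T2")), "intermediate")
  expect_equal(as.character(classify_eau(2, 8, "T3")), "high")
  expect_equal(as.character(classify_aua(2, 8, "T2")), "favourable_intermediate")
  expect_equal(as.character(classify_aua(2, 15, "T2")), "unfavourable_intermediate")
  expect_equal(as.character(classify_aua(5, 4, "T1")), "high")
})

test_that("PSA banding is exhaustive with inclusive 10-20 boundaries", {
  expect_equal(as.character(psa_band(c(9.99, 10, 20, 20.01))),
               c("lt10", "mid", "mid", "gt20"))
  expect_error(psa_band(0), class = "progshift_validation_error")
  expect_error(psa_band(NA_real_), class = "progshift_validation_error")
})

rule_grid <- local({
  tidyr::expand_grid(gg = 1:5, psa = c(5, 15, 25), t = paste0("T", 1:4))
})

test_that("classification is total over the full rule grid, with no gaps", {
  labs <- classify_all(rule_grid$gg, rule_grid$psa, rule_grid$t)
  expect_false(anyNA(labs$eau))
  expect_false(anyNA(labs$aua))
  expect_false(anyNA(labs$cpg))
  # every tier of every system is reachable
  expect_setequal(as.character(unique(labs$cpg)), risk_group_levels("cpg"))
  expect_setequal(as.character(unique(labs$eau)), risk_group_levels("eau"))
  expect_setequal(as.character(unique(labs$aua)), risk_group_levels("aua"))
})

test_that("EAU and AUA labels are exact collapses of the CPG label", {
  labs <- classify_all(rule_grid$gg, rule_grid$psa, rule_grid$t)
  expect_equal(labs$eau, collapse_cpg(labs$cpg, "eau"))
  expect_equal(labs$aua, collapse_cpg(labs$cpg, "aua"))
  expect_equal(as.character(labs$aua) == "low", as.character(labs$eau) == "low")
})

test_that("worsening a single feature never improves any label", {
  worse_psa <- c(`5` = 15, `15` = 25, `25` = 25)
  worse_t <- c(T1 = "T2", T2 = "T3", T3 = "T4", T4 = "T4")
  base <- classify_all(rule_grid$gg, rule_grid$psa, rule_grid$t)
  steps <- list(
    classify_all(pmin(rule_grid$gg + 1, 5), rule_grid$psa, rule_grid$t),
    classify_all(rule_grid$gg, unname(worse_psa[as.character(rule_grid$psa)]), rule_grid$t),
    classify_all(rule_grid$gg, rule_grid$psa, unname(worse_t[rule_grid$t]))
  )
  for (stepped in steps) {
    for (col in c("eau", "aua", "cpg")) {
      expect_true(all(as.integer(stepped[[col]]) >= as.integer(base[[col]])))
    }
  }
})

test_that("T2 substage detail never changes a label", {
  for (sub in c("T2a", "T2b", "T2c")) {
    expect_equal(classify_all(2, 15, sub), classify_all(2, 15, "T2"))
  }
  expect_equal(classify_all(4, 5, "T3a"), classify_all(4, 5, "T3b"))
})
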
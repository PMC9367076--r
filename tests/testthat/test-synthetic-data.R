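# Generators: the deterministic diagnostic cohort must reproduce every
# published margin exactly; the population generator must hit its
# calibration targets in expectation.

test_that("default joint table satisfies every published margin", {
  tab <- build_default_joint_table()
  expect_equal(sum(tab$n), 370L)
  # clinical margins
  expect_equal(sum(tab$n[tab$clinical_t == "T3"]), 107L)
  gg_clin <- tapply(tab$n, factor(tab$gg_systematic, 0:5), sum)
  expect_equal(unname(c(gg_clin)), c(16L, 101L, 123L, 60L, 13L, 57L))
  # radiological margins
  expect_equal(sum(tab$n[tab$radiological_t == "T3"]), 136L)
  gg_mri <- tapply(tab$n, factor(tab$gg_combined, 1:5), sum)
  expect_equal(unname(c(gg_mri)), c(96L, 133L, 63L, 17L, 61L))
})

test_that("deterministic cohort reproduces the published risk-group counts", {
  cohort <- gen_diagnostic_cohort()
  clin <- classify_risk(cohort[cohort$gg_systematic >= 1, ], "clinical")
  mri <- classify_risk(cohort, "mri")
  expect_equal(unname(c(table(clin$eau))), c(67L, 155L, 132L))
  expect_equal(unname(c(table(mri$eau))), c(66L, 143L, 161L))
  expect_equal(unname(c(table(clin$aua))), c(67L, 86L, 69L, 132L))
  expect_equal(unname(c(table(mri$aua))), c(66L, 78L, 65L, 161L))
  expect_equal(unname(c(table(clin$cpg))), c(67L, 86L, 69L, 64L, 68L))
  expect_equal(unname(c(table(mri$cpg))), c(66L, 78L, 65L, 83L, 78L))
})

test_that("cohort covariates respect published ranges and Likert margin", {
  cohort <- gen_diagnostic_cohort()
  expect_true(all(cohort$psa >= 1.2 & cohort$psa <= 108))
  expect_true(all(cohort$age >= 45 & cohort$age <= 80))
  expect_equal(sum(cohort$likert %in% 1:2, na.rm = TRUE), 17)
  expect_equal(sum(is.na(cohort$likert)), 52)
  # MRI-negative (Likert 1-2) cancers are the radiological T1 records
  expect_true(all(cohort$radiological_t[which(cohort$likert <= 2)] == "T1"))
})

test_that("infeasible joint tables are rejected naming the margin", {
  tab <- build_default_joint_table()
  tab$n[1] <- tab$n[1] + 1L
  expect_error(gen_diagnostic_cohort(diagnostic_config(joint_table = tab)),
               "371", class = "progshift_validation_error")
  tab$n[1] <- -1L
  expect_error(gen_diagnostic_cohort(diagnostic_config(joint_table = tab)),
               class = "progshift_validation_error")
})

test_that("multinomial mode is seed-reproducible and margin-consistent", {
  cfg <- diagnostic_config()
  a <- gen_diagnostic_cohort(cfg, mode = "multinomial", seed = 31)
  b <- gen_diagnostic_cohort(cfg, mode = "multinomial", seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))

  big <- gen_diagnostic_cohort(diagnostic_config(n = 14800),
                               mode = "multinomial", seed = 8)
  p_hat <- mean(big$radiological_t == "T3")
  p <- 136 / 370
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / nrow(big)))
})

test_that("population generator emits exact sizes and honours zero targets", {
  alloc <- table3_allocation("eau")
  pop <- gen_population_cohort(alloc, seed = 2)
  expect_equal(unname(c(table(pop$group_eau))), alloc$n_total)

  none <- tibble::tibble(model = "eau", group = c("low", "high"),
                         n_alive = c(300, 300), n_dead = c(0, 30))
  p0 <- gen_population_cohort(none, seed = 5)
  expect_equal(sum(p0$event == "pc_death" & p0$group_eau == "low"), 0)
  expect_error(calibrate_pc_hazard(10, 11), class = "progshift_validation_error")
})

test_that("calibrated hazards hit death targets in expectation", {
  alloc <- table3_allocation("eau")
  deaths <- vapply(1:150, function(s) {
    pop <- gen_population_cohort(alloc, seed = s)
    vapply(split(pop$event == "pc_death", pop$group_eau), sum, numeric(1))
  }, numeric(3))
  p <- alloc$n_dead / alloc$n_total
  se_mean <- sqrt(alloc$n_total * p * (1 - p) / 150)
  expect_true(all(abs(rowMeans(deaths) - alloc$n_dead) <= 3 * se_mean))
})

test_that("expansion yields exact death counts and seeded determinism", {
  alloc <- table3_allocation("cpg")
  pop <- expand_allocation(alloc, seed = 9)
  expect_equal(sum(pop$event == "pc_death"), 789)
  by_grp <- tapply(pop$event == "pc_death", pop$group_cpg, sum)
  expect_equal(unname(c(by_grp)), alloc$n_dead)

  expect_identical(as.data.frame(expand_allocation(alloc, seed = 9)),
                   as.data.frame(pop))

  quiet <- tibble::tibble(model = "eau", group = c("low", "high"),
                          n_alive = c(40, 40), n_dead = c(0, 0))
  pq <- expand_allocation(quiet, seed = 1)
  expect_true(all(pq$event %in% c("censored", "other_death")))
})

test_that("collapsed group labels accompany CPG-generated cohorts", {
  pop <- expand_allocation(table3_allocation("cpg"), seed = 13)
  expect_equal(as.character(pop$group_eau),
               as.character(collapse_cpg(pop$group_cpg, "eau")))
  expect_equal(as.character(pop$group_aua),
               as.character(collapse_cpg(pop$group_cpg, "aua")))
})
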
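test_that("diagnostic cohort round-trips through CSV unchanged", {
  cohort <- gen_diagnostic_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagnostic_cohort(cohort, path)
  back <- read_diagnostic_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})

test_that("reading the default synthetic cohort reproduces its structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagnostic_cohort(gen_diagnostic_cohort(), path)
  cohort <- read_diagnostic_cohort(path)
  expect_equal(nrow(cohort), 370)
  expect_equal(sum(cohort$gg_systematic == 0), 16)
  expect_true(all(cohort$gg_combined >= 1))
  # psa_density present iff volume present
  expect_equal(is.na(cohort$psa_density), is.na(cohort$prostate_volume))
})

test_that("an empty file with a header yields an empty cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("patient_id,age,psa,prostate_volume,likert,clinical_t,",
                   "radiological_t,gg_systematic,gg_combined", sep = ""), path)
  cohort <- read_diagnostic_cohort(path)
  expect_equal(nrow(cohort), 0)
})

test_that("schema and row-level violations are reported precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,age,psa", "P1,66,9"), path)
  expect_error(read_diagnostic_cohort(path), "clinical_t",
               class = "progshift_schema_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,age,psa,prostate_volume,likert,clinical_t,radiological_t,gg_systematic,gg_combined",
    "P001,66,abc,40,4,T2,T2,2,2"), path2)
  err <- expect_error(read_diagnostic_cohort(path2, strict = TRUE),
                      class = "progshift_validation_error")
  expect_match(conditionMessage(err), "psa")
  expect_match(conditionMessage(err), "P001")
})

test_that("lenient mode drops invalid rows with a message", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,age,psa,prostate_volume,likert,clinical_t,radiological_t,gg_systematic,gg_combined",
    "P001,66,9,40,4,T2,T2,2,2",
    "P002,66,abc,40,4,T2,T2,2,2",
    "P003,66,9,40,4,T2,T2,2,0"), path)  # gg_combined 0 invalid
  expect_message(cohort <- read_diagnostic_cohort(path, strict = FALSE),
                 "2 invalid row")
  expect_equal(cohort$patient_id, "P001")
})

test_that("group allocation fixtures load with published totals", {
  eau <- table3_allocation("eau")
  expect_equal(sum(eau$n_total), 10139)
  expect_equal(sum(eau$n_dead), 789)
  expect_equal(as.character(eau$group), risk_group_levels("eau"))
  cpg <- table3_allocation("cpg")
  expect_equal(sum(cpg$n_total), 10139)
  expect_equal(sum(cpg$n_dead), 789)
  # redistributed arm: printed simulation output, totals conserved
  red <- table3_allocation("cpg", "redistributed")
  expect_equal(sum(red$n_total), 10139)
})

test_that("allocation validation rejects bad labels and counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("model,group,n_alive,n_dead", "cpg,CPG6,10,1"), path)
  expect_error(read_group_allocation(path), "CPG6",
               class = "progshift_validation_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("model,group,n_alive,n_dead", "nccn,low,10,1"), path2)
  expect_error(read_group_allocation(path2), class = "progshift_validation_error")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("model,group,n_alive,n_dead", "eau,low,-1,1"), path3)
  expect_error(read_group_allocation(path3), class = "progshift_validation_error")

  # single group with no deaths is a valid degenerate allocation
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("model,group,n_alive,n_dead", "eau,low,25,0"), path4)
  alloc <- read_group_allocation(path4)
  expect_equal(alloc$n_total, 25)
})

test_that("population cohorts round-trip and validate events", {
  pop <- expand_allocation(table3_allocation("cpg"), seed = 4)[1:50, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_population_cohort(pop, path)
  back <- read_population_cohort(path)
  expect_equal(back$time_years, pop$time_years)
  expect_equal(back$event, pop$event)
  expect_equal(as.character(back$group_cpg), as.character(pop$group_cpg))

  bad <- pop
  bad$event[1] <- "vanished"
  expect_error(validate_population_cohort(bad), class = "progshift_validation_error")
})
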
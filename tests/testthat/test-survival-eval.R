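# Kaplan-Meier, Cox and concordance machinery, checked against hand
# calculations and the independent oracles in helper-oracles.R.

test_that("Kaplan-Meier estimates match hand product-limit values", {
  # no events: survival stays at 1
  r0 <- pop_records(1:5, rep("censored", 5), rep("low", 5))
  k0 <- km_estimate(r0, "eau")
  expect_true(all(k0$survival == 1))

  # one event among four: S = 3/4
  r1 <- pop_records(c(2, 3, 4, 5), c("pc_death", rep("censored", 3)), rep("low", 4))
  k1 <- km_estimate(r1, "eau")
  expect_equal(k1$survival[k1$time == 2], 0.75)

  # events at 1 and 3 with a censoring between: 3/4 * 1/2
  r2 <- pop_records(1:4, c("pc_death", "censored", "pc_death", "censored"),
                    rep("low", 4))
  k2 <- km_estimate(r2, "eau")
  expect_equal(k2$survival[k2$time == 1], 0.75)
  expect_equal(k2$survival[k2$time == 3], 0.375)

  expect_error(km_estimate(r2[0, ], "eau"), class = "progshift_validation_error")
})

test_that("other-cause deaths are censored in cancer-specific curves", {
  r <- pop_records(1:4, c("other_death", "other_death", "pc_death", "censored"),
                   rep("low", 4))
  k <- km_estimate(r, "eau")
  expect_equal(min(k$survival), 0.5)  # one event among 2 still at risk
})

test_that("concordance matches the 3-subject hand calculation", {
  c3 <- concordance_index(c(1, 2, 3), c(1, 1, 0), c(2, 2, 1))
  expect_equal(as.numeric(c3), 2.5 / 3)
  expect_equal(attr(c3, "usable"), 3)
})

test_that("perfect and uninformative scores give C = 1 and C = 0.5", {
  t <- c(1, 2, 3, 4, 5)
  expect_equal(as.numeric(concordance_index(t, rep(1, 5), 6 - t)), 1)
  expect_equal(as.numeric(concordance_index(t, rep(1, 5), rep(2, 5))), 0.5)
  expect_error(concordance_index(c(1, 1), c(1, 1), c(1, 2)),
               class = "progshift_numerical_error")
})

test_that("concordance sweep equals the exhaustive all-pairs oracle", {
  set.seed(2024)
  for (i in seq_len(200)) {
    n <- sample(3:50, 1)
    time <- sample(1:25, n, replace = TRUE)      # deliberate time ties
    status <- rbinom(n, 1, 0.6)
    score <- sample(1:5, n, replace = TRUE)
    if (sum(status) == 0) status[sample(n, 1)] <- 1
    oracle <- tryCatch(concordance_oracle(time, status, score),
                       error = function(e) NaN)
    if (!is.finite(oracle)) {
      expect_error(concordance_index(time, status, score),
                   class = "progshift_numerical_error")
    } else {
      expect_equal(as.numeric(concordance_index(time, status, score)), oracle)
    }
  }
})

test_that("concordance is invariant to monotone score transformations", {
  set.seed(7)
  time <- rexp(60); status <- rbinom(60, 1, 0.5); score <- sample(1:5, 60, TRUE)
  base <- as.numeric(concordance_index(time, status, score))
  for (f in list(function(x) 2 * x + 3, exp, function(x) x^3)) {
    expect_equal(as.numeric(concordance_index(time, status, f(score))), base)
  }
})

test_that("Cox fits agree with brute-force partial likelihood maximisation", {
  set.seed(11)
  checked <- 0
  while (checked < 25) {
    n <- sample(8:20, 1)
    k <- sample(2:3, 1)
    group <- factor(sample(risk_group_levels("eau")[seq_len(k)], n, TRUE),
                    risk_group_levels("eau")[seq_len(k)])
    time <- round(rexp(n, 0.2), 6)   # continuous, no ties
    status <- rbinom(n, 1, 0.7)
    if (any(tapply(status, group, function(x) sum(x) < 1 || length(x) < 2))) next
    rec <- pop_records(time, ifelse(status == 1, "pc_death", "censored"),
                       as.character(group))
    fit <- tryCatch(suppressWarnings(cox_fit(rec, "eau")), error = function(e) NULL)
    if (is.null(fit)) next
    if (max(abs(log(fit$hazard_ratios$hazard_ratio))) > 3) next  # near-separation
    brute <- cox_brute(time, status, droplevels(group))
    expect_equal(unname(log(fit$hazard_ratios$hazard_ratio)), unname(brute),
                 tolerance = 1e-3)
    checked <- checked + 1
  }
  expect_equal(checked, 25)
})

test_that("Cox HRs are near 1 for exchangeable groups and scale-invariant", {
  set.seed(5)
  n <- 4000
  rec <- pop_records(rexp(n, 0.1),
                     ifelse(rbinom(n, 1, 0.4) == 1, "pc_death", "censored"),
                     sample(c("low", "high"), n, TRUE))
  fit <- cox_fit(rec, "eau")
  expect_lt(abs(log(fit$hazard_ratios$hazard_ratio)), 0.15)

  rec10 <- rec
  rec10$time_years <- rec10$time_years * 10
  fit10 <- cox_fit(rec10, "eau")
  expect_equal(fit10$hazard_ratios$hazard_ratio, fit$hazard_ratios$hazard_ratio)
})

test_that("groups without events are flagged, not silently fitted", {
  rec <- pop_records(c(1, 2, 3, 4), c("pc_death", "pc_death", "censored", "censored"),
                     c("low", "low", "high", "high"))
  expect_error(cox_fit(rec, "eau"), "high", class = "progshift_numerical_error")
})

test_that("harrell_c bootstrap CIs are seeded and bracket the estimate", {
  pop <- expand_allocation(table3_allocation("cpg"), seed = 3)
  a <- harrell_c(pop, "cpg", boot = 50, seed = 21)
  b <- harrell_c(pop, "cpg", boot = 50, seed = 21)
  expect_equal(a, b)
  expect_lte(a$c_ci_low, a$c_index)
  expect_gte(a$c_ci_high, a$c_index)
})

test_that("worse tiers carry hazard ratios above 1 on calibrated cohorts", {
  ok <- vapply(1:10, function(s) {
    fit <- evaluate_allocation(table3_allocation("cpg"), "cpg", boot = 0, seed = s)
    all(fit$hazard_ratios$hazard_ratio > 1)
  }, logical(1))
  expect_true(all(ok))
})

test_that("evaluating a single-group allocation is an error", {
  alloc <- tibble::tibble(model = "eau", group = "low", n_alive = 50, n_dead = 5)
  expect_error(evaluate_allocation(alloc, "eau", boot = 0, seed = 1),
               class = "progshift_validation_error")
})
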
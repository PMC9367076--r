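# Discrimination and effect-size evaluation of grouped risk predictors on
# censored survival data. Cox models and Kaplan-Meier estimates go through
# the survival package (Breslow tie handling, matching common statistical
# software defaults); Harrell's C is implemented here with the exact
# usable-pair definition asserted by the package tests: a pair is usable
# when the subject with the strictly shorter observed time has an event;
# pairs tied on time are excluded; score ties count 1/2.

pc_event <- function(event) {
  as.integer(event == "pc_death")
}

group_score <- function(records, model) {
  col <- paste0("group_", tolower(model))
  g <- records[[col]]
  if (is.null(g)) {
    abort(sprintf("Column %s not found in population records", col),
          class = "progshift_schema_error")
  }
  g <- factor(as.character(g), levels = risk_group_levels(model))
  if (anyNA(g)) {
    abort(sprintf("Missing or invalid %s label(s)", col),
          class = "progshift_validation_error")
  }
  as.integer(g)
}

#' Harrell's concordance index for a numeric risk score
#'
#' `C = (concordant + 0.5 * score-tied) / usable pairs`, where a usable pair
#' has strictly different observed times and an event for the shorter one;
#' a pair is concordant when the higher score dies first. Runs in
#' `O(n log n + n k)` for `k` distinct score values by sweeping event times.
#'
#' @param time Observed times.
#' @param status Event indicator (1 = event of interest, 0 = censored;
#'   other-cause deaths must already be coded 0).
#' @param score Numeric risk score (higher = worse prognosis). For grouped
#'   predictors use the tier's ordinal rank.
#' @return The concordance index, with attributes `concordant`, `tied` and
#'   `usable` (pair counts).
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 1, 0), c(2, 2, 1))  # 2.5 / 3
#' @export
concordance_index <- function(time, status, score) {
  stopifnot(length(time) == length(status), length(time) == length(score))
  if (anyNA(time) || anyNA(status) || anyNA(score)) {
    abort("time, status and score must be complete",
          class = "progshift_validation_error")
  }
  sc <- as.integer(factor(score))       # rank-compress scores
  k <- max(sc)
  ord <- order(time, decreasing = TRUE)
  time <- time[ord]; status <- status[ord]; sc <- sc[ord]
  # block boundaries of tied times, scanning from latest to earliest
  block <- cumsum(!duplicated(time))
  nb <- block[length(block)]
  # per-block score counts: all subjects (later set) and events (current)
  fb <- factor(block, levels = seq_len(nb))
  fs <- factor(sc, levels = seq_len(k))
  all_m <- unclass(table(fb, fs))
  ev_m <- unclass(table(fb[status == 1], fs[status == 1]))
  later <- apply(all_m, 2, cumsum) - all_m     # strictly later than block
  later <- matrix(later, nb, k)
  n_later <- rowSums(later)
  # lower[b, s]: later subjects with score < s; later[b, s] itself: ties
  lower <- t(apply(cbind(0, later), 1, cumsum))[, seq_len(k), drop = FALSE]
  concordant <- sum(ev_m * lower)
  tied <- sum(ev_m * later)
  usable <- sum(rowSums(ev_m) * n_later)
  if (usable == 0) {
    abort("No usable pairs: need an event with a strictly later comparator",
          class = "progshift_numerical_error")
  }
  structure((concordant + 0.5 * tied) / usable,
            concordant = concordant, tied = tied, usable = usable)
}

#' Harrell's C for a grouped risk model, with bootstrap CI
#'
#' Scores each subject by the ordinal rank of their risk tier (no
#' within-tier ordering is invented) and computes [concordance_index()] on
#' prostate-cancer-specific survival (other-cause deaths censored). The
#' confidence interval is a seeded nonparametric bootstrap over subjects
#' (percentile method).
#'
#' @param records Population cohort tibble (see [read_population_cohort()]).
#' @param model `"eau"`, `"aua"` or `"cpg"`.
#' @param boot Number of bootstrap replicates for the CI; `0` skips the CI.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `model`, `c_index`, `c_ci_low`, `c_ci_high`,
#'   `n`, `events`, `boot`.
#' @export
harrell_c <- function(records, model = c("eau", "aua", "cpg"),
                      boot = 1000, seed = NULL, conf_level = 0.95) {
  model <- match.arg(model)
  records <- as_tibble(records)
  time <- records$time_years
  status <- pc_event(records$event)
  score <- group_score(records, model)
  c_hat <- concordance_index(time, status, score)
  lo <- hi <- NA_real_
  if (boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(time)
    reps <- vapply(seq_len(boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(concordance_index(time[idx], status[idx], score[idx])),
               error = function(e) NA_real_)
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    qs <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble(model = model, c_index = as.numeric(c_hat),
         c_ci_low = lo, c_ci_high = hi,
         n = length(time), events = sum(status), boot = as.integer(boot))
}

#' Median follow-up of a population cohort
#'
#' Reverse Kaplan-Meier estimate (the standard follow-up estimator: deaths
#' of any cause are censored and censoring is the "event", so the estimate
#' describes the follow-up the cohort would have had without deaths).
#' `method = "observed"` returns the plain median of observed times.
#'
#' @param records Population cohort tibble.
#' @param method `"reverse_km"` (default) or `"observed"`.
#' @return Median follow-up in years.
#' @export
median_followup <- function(records, method = c("reverse_km", "observed")) {
  method <- match.arg(method)
  records <- as_tibble(records)
  if (method == "observed") return(median(records$time_years))
  cens <- as.integer(records$event == "censored")
  fit <- survival::survfit(survival::Surv(records$time_years, cens) ~ 1)
  unname(summary(fit)$table["median"])
}

#' Kaplan-Meier curves for prostate-cancer-specific survival by risk group
#'
#' Product-limit estimates per risk tier, with other-cause deaths treated as
#' censoring and simultaneous handling of tied event times.
#'
#' @inheritParams harrell_c
#' @return A `km_curves` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_estimate <- function(records, model = c("eau", "aua", "cpg")) {
  model <- match.arg(model)
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    abort("No records to estimate from", class = "progshift_validation_error")
  }
  col <- paste0("group_", model)
  grp <- factor(as.character(records[[col]]), risk_group_levels(model))
  grp <- droplevels(grp)
  fit <- survival::survfit(
    survival::Surv(records$time_years, pc_event(records$event)) ~ grp)
  strata <- if (is.null(fit$strata)) {
    rep(levels(grp)[1], length(fit$time))
  } else {
    rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(group = factor(strata, risk_group_levels(model)),
                time = fit$time,
                n_risk = fit$n.risk,
                n_event = fit$n.event,
                survival = fit$surv)
  structure(out, class = c("km_curves", class(out)), model = model)
}

#' Cox proportional hazards fit for a grouped risk predictor
#'
#' Fits a proportional-hazards model with group indicators (best tier as
#' reference) to prostate-cancer-specific survival, using Breslow handling
#' of tied event times, and reports hazard ratios with Wald 95% confidence
#' intervals and p-values together with Harrell's C.
#'
#' @inheritParams harrell_c
#' @param boot Bootstrap replicates for the C-index CI (0 = none).
#' @return A `prognostic_fit` object; see [tidy.prognostic_fit()] and
#'   [glance.prognostic_fit()].
#' @export
cox_fit <- function(records, model = c("eau", "aua", "cpg"),
                    boot = 0, seed = NULL) {
  model <- match.arg(model)
  records <- as_tibble(records)
  grp <- factor(as.character(records[[paste0("group_", model)]]),
                risk_group_levels(model))
  grp <- droplevels(grp)
  status <- pc_event(records$event)
  if (nlevels(grp) < 2) {
    abort("Need at least two occupied risk groups to fit hazard ratios",
          class = "progshift_validation_error")
  }
  if (sum(status) == 0) {
    abort("No prostate-cancer deaths: hazard ratios undefined",
          class = "progshift_numerical_error")
  }
  ev_by_grp <- tapply(status, grp, sum)
  if (any(ev_by_grp == 0)) {
    empty <- names(ev_by_grp)[ev_by_grp == 0]
    abort(sprintf(
      "Hazard ratios are not estimable: group(s) without events: %s",
      paste(empty, collapse = ", ")),
      class = "progshift_numerical_error")
  }
  fit <- survival::coxph(survival::Surv(records$time_years, status) ~ grp,
                         ties = "breslow")
  if (any(is.na(coef(fit)))) {
    abort("Cox fit did not converge to finite hazard ratios",
          class = "progshift_numerical_error")
  }
  s <- summary(fit)
  hr <- tibble(
    model = model,
    group = sub("^grp", "", rownames(s$coefficients)),
    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
    ci_low = unname(s$conf.int[, "lower .95"]),
    ci_high = unname(s$conf.int[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"])
  )
  cc <- harrell_c(records, model, boot = boot, seed = seed)
  structure(
    list(model = model,
         reference_group = levels(grp)[1],
         hazard_ratios = hr,
         c_index = cc$c_index, c_ci_low = cc$c_ci_low, c_ci_high = cc$c_ci_high,
         n = nrow(records), events = sum(status),
         ties = "breslow", boot = boot, seed = seed,
         coxph = fit),
    class = "prognostic_fit")
}

#' Evaluate a risk model on a population cohort or grouped allocation
#'
#' Accepts either individual-level population records or a grouped
#' allocation; an allocation is first expanded to individual records via
#' [expand_allocation()] (survival times simulated under the generator
#' configuration, seed recorded in the result).
#'
#' @param x Population records tibble or a group allocation tibble.
#' @param model `"eau"`, `"aua"` or `"cpg"`.
#' @param config Population generator configuration for the expansion
#'   (see [population_config()]); defaults match the published cohort's
#'   accrual and follow-up structure.
#' @param boot Bootstrap replicates for the C-index CI.
#' @param seed Integer seed (expansion and bootstrap).
#' @return A `prognostic_fit` object.
#' @examples
#' fit <- evaluate_allocation(table3_allocation("eau"), "eau", boot = 0, seed = 1)
#' glance(fit)
#' @export
evaluate_allocation <- function(x, model = c("eau", "aua", "cpg"),
                                config = population_config(),
                                boot = 1000, seed = NULL) {
  model <- match.arg(model)
  x <- as_tibble(x)
  if (all(c("n_alive", "n_dead") %in% names(x))) {
    x <- expand_allocation(x, config = config, seed = seed)
  }
  fit <- cox_fit(x, model, boot = boot, seed = seed)
  fit$generator <- list(config = config, seed = seed)
  fit
}

#' @export
print.prognostic_fit <- function(x, ...) {
  cat(sprintf("Prognostic fit: %s model, n = %d, %d prostate-cancer deaths\n",
              toupper(x$model), x$n, x$events))
  cat(sprintf("Reference group: %s (Breslow ties)\n", x$reference_group))
  print(x$hazard_ratios, ...)
  if (is.na(x$c_ci_low)) {
    cat(sprintf("Harrell's C = %.3f\n", x$c_index))
  } else {
    cat(sprintf("Harrell's C = %.3f (95%% CI %.3f-%.3f, %d bootstrap reps)\n",
                x$c_index, x$c_ci_low, x$c_ci_high, x$boot))
  }
  invisible(x)
}

#' Tidy a prognostic fit
#'
#' One row per non-reference risk tier with hazard ratio, Wald 95% CI and
#' p-value.
#'
#' @param x A `prognostic_fit` from [cox_fit()] or [evaluate_allocation()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy prognostic_fit
#' @export
tidy.prognostic_fit <- function(x, ...) {
  x$hazard_ratios
}

#' Summarise a prognostic fit
#'
#' One row with the model, reference group, Harrell's C (and CI when
#' bootstrapped), sample size and event count.
#'
#' @inheritParams tidy.prognostic_fit
#' @return A one-row tibble.
#' @method glance prognostic_fit
#' @export
glance.prognostic_fit <- function(x, ...) {
  tibble(model = x$model, reference_group = x$reference_group,
         c_index = x$c_index, c_ci_low = x$c_ci_low, c_ci_high = x$c_ci_high,
         n = x$n, events = x$events)
}
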
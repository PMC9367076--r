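# Independent oracles used to verify the package's survival machinery.
# These deliberately share no code with the implementations they check.

# Exhaustive all-pairs Harrell's C: a pair is usable when the times differ
# strictly and the earlier subject has an event; concordant when that
# subject also has the higher score; score ties count one half.
concordance_oracle <- function(time, status, score) {
  conc <- tied <- usable <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || time[i] >= time[j] || status[i] != 1) next
      usable <- usable + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) tied <- tied + 0.5
    }
  }
  (conc + tied) / usable
}

# Breslow partial log-likelihood for a categorical predictor (reference =
# first factor level), written directly from the definition: every event
# contributes its linear predictor minus the log of the summed risk-set
# hazards at its event time, tied events sharing the same risk set.
breslow_loglik <- function(beta, time, status, group) {
  x <- stats::model.matrix(~group)[, -1, drop = FALSE]
  eta <- drop(x %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

cox_brute <- function(time, status, group) {
  k <- nlevels(group) - 1
  fit <- stats::optim(rep(0, k), function(b) -breslow_loglik(b, time, status, group),
                      method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  fit$par
}

# Small population-record builder for survival tests.
pop_records <- function(time, event, group, model = "eau") {
  out <- tibble::tibble(subject_id = sprintf("S%03d", seq_along(time)),
                        group_eau = factor(NA, progshift::risk_group_levels("eau")),
                        group_aua = factor(NA, progshift::risk_group_levels("aua")),
                        group_cpg = factor(NA, progshift::risk_group_levels("cpg")),
                        time_years = time, event = event)
  out[[paste0("group_", model)]] <- factor(group, progshift::risk_group_levels(model))
  out
}

# Strip a redistributed allocation back to plain allocation columns.
as_allocation <- function(redistributed) {
  redistributed[, c("model", "group", "n_alive", "n_dead", "n_total")]
}
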
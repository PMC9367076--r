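# Stratified redistribution simulation: retrofit the percentage-point risk
# group shifts observed in a diagnostic cohort onto a grouped population
# cohort with long-term prostate-cancer mortality, and reassign deaths to
# the resized groups at each group's original death rate. This emulates the
# published stratified-random reallocation at the level of group margins;
# no individual covariates move between cohorts.

shift_vector <- function(shifts, alloc) {
  lev <- as.character(alloc$group)
  if (inherits(shifts, "shift_table")) {
    model <- attr(shifts, "model")
    if (!is.na(model %||% NA_character_) && !is.null(alloc$model) &&
        !all(alloc$model == model)) {
      abort(sprintf("Shift table is for model %s but allocation is for %s",
                    model, alloc$model[1]),
            class = "progshift_validation_error")
    }
    shifts <- setNames(shifts$delta_pp, shifts$category)
  }
  if (is.null(names(shifts))) {
    if (length(shifts) != length(lev)) {
      abort("Unnamed shifts must have one value per allocation group",
            class = "progshift_validation_error")
    }
    names(shifts) <- lev
  }
  missing_g <- setdiff(lev, names(shifts))
  if (length(missing_g)) {
    abort(sprintf("No shift supplied for group(s): %s",
                  paste(missing_g, collapse = ", ")),
          class = "progshift_validation_error")
  }
  s <- unname(shifts[lev])
  if (abs(sum(s)) > 0.1 * max(1, length(s) - 1)) {
    abort(sprintf("Percentage-point shifts must sum to ~0 (got %.2f)", sum(s)),
          class = "progshift_validation_error")
  }
  s
}

#' Resize population groups by percentage-point shifts
#'
#' Expected mode: the target size of each group is `N * (original proportion
#' + shift/100)`; fractional targets are resolved by largest-remainder
#' rounding so the total is conserved exactly.
#'
#' @param alloc Group allocation tibble for one model
#'   (see [read_group_allocation()]).
#' @param shifts Percentage-point shifts: a named numeric vector (names =
#'   group labels), an unnamed vector in group order, or a `shift_table`
#'   from [risk_shift()].
#' @return Integer vector of new group sizes, named by group, summing to the
#'   original total.
#' @examples
#' redistribute_sizes(table3_allocation("eau"), c(-1.1, -5.1, 6.2))
#' @export
redistribute_sizes <- function(alloc, shifts) {
  alloc <- validate_group_allocation(alloc)
  s <- shift_vector(shifts, alloc)
  n_total <- sum(alloc$n_total)
  target <- n_total * (alloc$n_total / n_total + s / 100)
  if (any(target < 0)) {
    bad <- as.character(alloc$group)[target < 0][1]
    abort(sprintf("Shift produces a negative size for group %s", bad),
          class = "progshift_validation_error")
  }
  # shifts may carry up to the tolerated rounding drift; rescale targets so
  # they sum to the population before integerising
  target <- target * n_total / sum(target)
  sizes <- largest_remainder(target, n_total)
  setNames(sizes, as.character(alloc$group))
}

# Round non-negative targets to integers summing to `total`, assigning the
# leftover units to the largest fractional remainders (ties: first wins).
largest_remainder <- function(target, total) {
  base <- floor(target)
  rem <- target - base
  short <- as.integer(round(total - sum(base)))
  stopifnot(short >= 0, short <= length(target))
  add <- integer(length(target))
  if (short > 0) {
    add[order(rem, decreasing = TRUE)[seq_len(short)]] <- 1L
  }
  as.integer(base + add)
}

#' Expected prostate-cancer deaths in a resized group
#'
#' Applies the group's original death proportion `orig_dead / (orig_alive +
#' orig_dead)` to a new group size. Expected mode returns the rounded
#' expectation (round-half-to-even); stochastic mode draws a seeded binomial
#' count with that probability.
#'
#' @param new_size New group size(s), non-negative.
#' @param orig_alive,orig_dead Original alive / prostate-cancer-death counts.
#' @param mode `"expected"` (default) or `"stochastic"`.
#' @param seed Integer seed for stochastic mode.
#' @return Integer vector of death counts.
#' @examples
#' assign_events(5308, 4083, 601)  # 681
#' @export
assign_events <- function(new_size, orig_alive, orig_dead,
                          mode = c("expected", "stochastic"), seed = NULL) {
  mode <- match.arg(mode)
  if (any(new_size < 0)) {
    abort("new_size must be non-negative", class = "progshift_validation_error")
  }
  if (any(orig_alive + orig_dead <= 0)) {
    abort("Original group must be non-empty", class = "progshift_validation_error")
  }
  p <- orig_dead / (orig_alive + orig_dead)
  if (mode == "expected") {
    as.integer(round(new_size * p))
  } else {
    if (!is.null(seed)) set.seed(seed)
    as.integer(rbinom(length(new_size), size = as.integer(new_size), prob = p))
  }
}

#' Redistribute a grouped population allocation
#'
#' Composes [redistribute_sizes()] and [assign_events()]: group sizes move
#' by the observed percentage-point shifts (net flow towards the adjacent
#' worse group), and prostate-cancer deaths are reassigned to the resized
#' groups at each group's original death rate. Expected mode is fully
#' deterministic; stochastic mode keeps the deterministic target sizes but
#' draws each group's death count as a seeded binomial, and is reproducible
#' under a fixed seed. Total population size is conserved exactly in both
#' modes; total deaths are not (by design: mass moving into high-rate groups
#' is assigned their higher death rate).
#'
#' @inheritParams redistribute_sizes
#' @param mode `"expected"` or `"stochastic"`.
#' @param seed Integer seed used in stochastic mode.
#' @return A `redistributed_allocation` tibble with columns `model`,
#'   `group`, `n_alive`, `n_dead`, `n_total` (the redistributed allocation)
#'   plus `n_total_orig`, `n_dead_orig` and `size_change`.
#' @examples
#' redistribute(table3_allocation("eau"), risk_shift(gen_diagnostic_cohort(), "eau"))
#' @export
redistribute <- function(alloc, shifts, mode = c("expected", "stochastic"),
                         seed = NULL) {
  mode <- match.arg(mode)
  alloc <- validate_group_allocation(alloc)
  sizes <- redistribute_sizes(alloc, shifts)
  dead <- assign_events(sizes, alloc$n_alive, alloc$n_dead,
                        mode = mode, seed = seed)
  out <- tibble(model = alloc$model,
                group = alloc$group,
                n_alive = as.integer(sizes - dead),
                n_dead = dead,
                n_total = as.integer(sizes),
                n_total_orig = as.integer(alloc$n_total),
                n_dead_orig = as.integer(alloc$n_dead),
                size_change = as.integer(sizes - alloc$n_total))
  structure(out, class = c("redistributed_allocation", class(out)),
            mode = mode, seed = seed)
}
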
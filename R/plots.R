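# ggplot2 front ends for the main result types.

#' Plot Kaplan-Meier curves
#'
#' Step curves of prostate-cancer-specific survival per risk tier.
#'
#' @param object A `km_curves` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curves
#' @export
autoplot.km_curves <- function(object, ...) {
  model <- attr(object, "model")
  ggplot2::ggplot(as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since diagnosis",
                  y = "Prostate-cancer-specific survival",
                  colour = toupper(model %||% "group"),
                  title = sprintf("Simulated survival by %s risk group",
                                  toupper(model %||% ""))) +
    ggplot2::theme_minimal()
}

#' Plot a shift table
#'
#' Diverging bar chart of the percentage-point change per category between
#' the clinical and MRI-enhanced characterisations.
#'
#' @param object A `shift_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot shift_table
#' @export
autoplot.shift_table <- function(object, ...) {
  d <- as_tibble(unclass(object)) %>%
    mutate(category = factor(.data$category, .data$category))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$delta_pp,
                                  fill = .data$delta_pp > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Shift (percentage points, MRI - clinical)") +
    ggplot2::theme_minimal()
}

#' Plot a risk-group transition matrix
#'
#' Tile heat map of per-patient transitions between clinical and
#' MRI-enhanced risk groups (diagonal = unchanged assignments).
#'
#' @param crosstab A `risk_crosstab` from [risk_crosstab()].
#' @return A ggplot.
#' @export
plot_crosstab <- function(crosstab) {
  d <- as_tibble(unclass(crosstab))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mri, y = .data$clinical,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "MRI-enhanced group", y = "Clinical group", fill = "n") +
    ggplot2::theme_minimal()
}
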
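# ggplot2 visualisations for the fitted objects and summary tables.

#' Plot a degree-distribution power-law fit
#'
#' Log-log scatter of the degree histogram with the fitted
#' `P(k) = a * k^b` line.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linetype = 2,
                       colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree k", y = "node count P(k)",
      title = sprintf("P(k) = %.3f k^%.3f,  R² = %.3f",
                      object$a, object$b, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an SC-cutoff scan
#'
#' Power-law R-squared against the sensitivity-correlation cutoff, with
#' the selected cutoff highlighted.
#'
#' @param object An `sc_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sc_scan
#' @export
autoplot.sc_scan <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cutoff, y = .data$r_squared)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "SC cutoff", y = expression(R^2),
                  title = sprintf("selected SC cutoff: %.2f", object$selected)) +
    ggplot2::theme_minimal()
}

#' Plot a method-validation benchmark table
#'
#' Validated-interaction counts per method, faceted by the top-K cutoff —
#' the comparison used to choose the best prediction method.
#'
#' @param validation A [validate_methods()] table.
#' @return A ggplot.
#' @export
plot_validation <- function(validation) {
  dat <- validation |>
    group_by(.data$method, .data$k) |>
    summarise(n_validated = sum(.data$n_validated), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$method, -.data$n_validated),
    y = .data$n_validated
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~k, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "validated interactions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
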
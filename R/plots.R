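#' Plot a two-segment VPD-response fit
#'
#' Observed (VPD, TR) points with the fitted segments and the breakpoint.
#'
#' @param object A `segmented_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmented_fit <- function(object, ...) {
  grid <- tibble::tibble(
    vpd = seq(min(object$data$vpd), max(object$data$vpd), length.out = 200)
  )
  grid$tr <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$vpd, y = .data$tr)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$bp, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "VPD (kPa)", y = expression(TR ~ (mg ~ m^-2 ~ s^-1)),
      title = sprintf("Two-segment response, BP = %.2f kPa", object$bp)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an envelope fit
#'
#' Environment mean yields against water input, the fitted envelope and the
#' water-limited band around it.
#'
#' @param object An `envelope_fit`.
#' @param band Band half-width shown around the curve (default 0.20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.envelope_fit <- function(object, band = 0.20, ...) {
  grid <- tibble::tibble(
    water_input = seq(min(object$data$water_input),
                      max(object$data$water_input), length.out = 200)
  )
  grid$yield <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$water_input, y = .data$mean_yield)) +
    ggplot2::geom_ribbon(
      data = grid,
      ggplot2::aes(x = .data$water_input, ymin = (1 - band) * .data$yield,
                   ymax = (1 + band) * .data$yield),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$water_input, y = .data$yield),
                       inherit.aes = FALSE, colour = "#b2182b",
                       linewidth = 0.8) +
    ggplot2::labs(
      x = "Water input (mm)", y = expression(Yield ~ (kg ~ ha^-1)),
      title = sprintf("Envelope fit: a = %.0f, fraction below = %.2f",
                      object$a, object$fraction_below)
    ) +
    ggplot2::theme_minimal()
}

#' Efficiency scatter of the selection framework
#'
#' Determination coefficient of each trait-vs-target regression against its
#' relative phenotyping cost, with the significance and ratio screens drawn
#' in, mirroring how the framework's audit table is usually inspected.
#'
#' @param rows Audit table from [efficiency_table()] or [select_traits()].
#' @param config A [selection_config()] supplying the thresholds drawn.
#' @return A ggplot object.
#' @export
plot_efficiency <- function(rows, config = selection_config()) {
  rows <- dplyr::filter(rows, !is.na(.data$r2))
  rows$significant <- rows$p_value <= config$alpha
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$relative_cost, y = .data$r2,
                                     colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = config$ratio_min, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "Relative phenotyping cost",
                  y = expression(R^2 ~ "vs target trait"),
                  colour = "Significant") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-genotype drought susceptibility indices
#'
#' @param dsi_tbl Output of [dsi_table()] (or any tibble with `genotype` and
#'   `dsi` columns).
#' @return A ggplot object.
#' @export
plot_dsi <- function(dsi_tbl) {
  ggplot2::ggplot(dsi_tbl,
                  ggplot2::aes(x = stats::reorder(.data$genotype, .data$dsi),
                               y = .data$dsi)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "Drought susceptibility index") +
    ggplot2::theme_minimal()
}
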
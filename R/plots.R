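#' Trajectory curves with confidence ribbons
#'
#' Mean percent weight change per 30-day bin with its confidence band,
#' drawn per outcome group (colour) and per drug (facet) when those columns
#' are present in the bin table.
#'
#' @param object A `"trajectory_bins"` tibble from [aggregate_bins()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajectory_bins
#' @export
autoplot.trajectory_bins <- function(object, ...) {
  has_label <- "label" %in% names(object)
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$bin_index,
                 y = .data$mean_pct,
                 colour = if (has_label) .data$label else NULL,
                 fill = if (has_label) .data$label else NULL)
  ) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low_pct,
                                      ymax = .data$ci_high_pct),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "30-day bin relative to index date",
                  y = "Weight change from baseline (%)",
                  colour = "Outcome", fill = "Outcome") +
    ggplot2::theme_minimal()
  if ("drug" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$drug))
  }
  p
}

#' @rdname autoplot.trajectory_bins
#' @param bins A `"trajectory_bins"` tibble.
#' @export
plot_trajectory_bins <- function(bins, ...) autoplot(bins, ...)

#' @rdname followup_histogram
#' @param object A `"followup_hist"` object.
#' @method autoplot followup_hist
#' @export
autoplot.followup_hist <- function(object, ...) {
  bins <- object$bins
  finite <- is.finite(bins$bin_low) & is.finite(bins$bin_high)
  ggplot2::ggplot(bins[finite, ],
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(x = "Follow-up weight change (%)", y = "Patients") +
    ggplot2::theme_minimal()
}
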
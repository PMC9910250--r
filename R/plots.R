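# Approximate 2-D head-plan coordinates of the montage (10-20 layout,
# nose up): used only for drawing, never for analysis.
electrode_positions <- function() {
  tibble::tibble(
    node = FBN_CHANNELS,
    x = c(-0.38, 0.38, -0.33, 0.33, -0.26, 0.26, -0.70, 0.70),
    y = c(0.00, 0.00, -0.45, -0.45, -0.82, -0.82, -0.48, -0.48)
  )
}

#' Plot a functional brain network
#'
#' Draws the network on the electrode layout with edge thickness
#' proportional to weight (red edges, the stronger the correlation the
#' thicker the line) and labelled nodes.
#'
#' @param object An [fbn()].
#' @param min_weight Edges below this weight are not drawn (display only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fbn <- function(object, min_weight = 0, ...) {
  pos <- electrode_positions()
  if (!all(object$node_labels %in% pos$node)) {
    pos <- tibble::tibble(
      node = object$node_labels,
      x = cos(2 * pi * seq_along(object$node_labels) /
                length(object$node_labels)),
      y = sin(2 * pi * seq_along(object$node_labels) /
                length(object$node_labels))
    )
  }
  edges <- tidy(object) |>
    dplyr::filter(.data$weight > min_weight) |>
    dplyr::left_join(dplyr::rename(pos, from = "node", x0 = "x", y0 = "y"),
                     by = "from") |>
    dplyr::left_join(dplyr::rename(pos, to = "node", x1 = "x", y1 = "y"),
                     by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$weight),
      colour = "red3", alpha = 0.8
    ) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y),
                        size = 9, shape = 21, fill = "white") +
    ggplot2::geom_text(data = pos, ggplot2::aes(.data$x, .data$y,
                                                label = .data$node),
                       size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5), limits = c(0, 1)) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1.1, 0.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = paste0(object$subject_id %||% "", " ",
                     object$timepoint %||% ""),
      linewidth = "|PCC|"
    )
}

#' Metric trajectories across timepoints by arm
#'
#' Group mean +/- standard error of each network metric over the
#' assessment timepoints, one panel per metric.
#'
#' @param metrics Metrics tibble as produced by [run_pipeline()] (columns
#'   `arm`, `timepoint`, and the metric columns).
#' @param metrics_cols Which metric columns to plot.
#' @return A ggplot object.
#' @export
plot_metric_trajectories <- function(metrics,
                                     metrics_cols = c("D", "C", "L", "E",
                                                      "BNE")) {
  long <- tidyr::pivot_longer(metrics, dplyr::all_of(metrics_cols),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = metrics_cols)
  long$timepoint <- factor(long$timepoint,
                           levels = unique(metrics$timepoint))
  summ <- long |>
    dplyr::group_by(.data$arm, .data$timepoint, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(.data$timepoint, .data$mean,
                                     colour = .data$arm,
                                     group = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.15
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL)
}

#' @export
autoplot.fbn_pipeline_result <- function(object, ...) {
  plot_metric_trajectories(object$metrics)
}
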
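#' Plot a FLIP diameter topography
#'
#' Diameter topography as a time-by-channel raster (the panometry view:
#' proximal channels on top, warm colours = wide lumen), with fill-step
#' boundaries marked.
#'
#' @param object A [flip_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flip_study <- function(object, ...) {
  long <- as_tibble.flip_study(object)
  steps <- object$time[which(diff(object$fill_volume) > 0) + 1]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$channel,
                                     fill = .data$diameter)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = steps, linetype = "dashed",
                        colour = "white", linewidth = 0.3) +
    ggplot2::scale_y_reverse(breaks = c(1, 4, 8, 12, 16)) +
    ggplot2::scale_fill_viridis_c(option = "turbo", name = "diameter (mm)") +
    ggplot2::labs(x = "time (s)", y = "channel (proximal → distal)") +
    ggplot2::theme_minimal()
}

#' Plot a contingency table
#'
#' Tile map of the counts with labels, rows and columns in canonical order.
#'
#' @param object A [build_crosstab()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contingency_table <- function(object, ...) {
  long <- tidy(object)
  rv <- attr(object, "row_var")
  cv <- attr(object, "col_var")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[cv]], y = .data[[rv]],
                                     fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Stacked distribution of HRM diagnoses across FLIP classes
#'
#' Stacked bar chart of the proportion of each HRM/CCv4.0 diagnosis within
#' every FLIP motility class, the standard view for scheme-versus-HRM
#' concordance.
#'
#' @param cohort Data frame with the two columns.
#' @param class_col FLIP class column (x axis).
#' @param fill_col Diagnosis column (fill).
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(cohort, class_col = "flip_v2",
                                    fill_col = "ccv4_label") {
  check_columns(cohort, c(class_col, fill_col), "plot_class_distribution")
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data[[class_col]],
                                       fill = .data[[fill_col]])) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(p) paste0(100 * p, "%")) +
    ggplot2::labs(y = "proportion", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
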
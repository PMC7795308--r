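#' Plot feature coordinates of an error PCA
#'
#' Scatter of the first two principal-component coordinates, one point per
#' feature, colored by distance to the origin; re-constructible features
#' cluster near (0, 0) and outliers drift away.
#'
#' @param object an [build_error_pca()] result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.error_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$PCA1, .data$PCA2, colour = .data$dist)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "distance") +
    ggplot2::labs(
      title = "Reconstruction-error PCA",
      x = "PCA1", y = "PCA2"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a recall table
#'
#' Grouped bars of per-class recall by method, the usual reading of the
#' benchmark tables.
#'
#' @param object a [build_recall_table()] result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.recall_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$recall,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      title = if (!is.null(object$cutoff)) {
        sprintf("Recall at top %g%%", 100 * object$cutoff)
      } else "Recall by activity class",
      x = "activity class", y = "recall (%)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot training error trajectories
#'
#' Per-round mean reconstruction error of an iterative feature-learning run.
#'
#' @param history the `history` tibble of [iterative_feature_learning()].
#' @return a ggplot.
#' @export
plot_training_history <- function(history) {
  ggplot2::ggplot(history, ggplot2::aes(.data$round, .data$mean_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_features), show.legend = TRUE) +
    ggplot2::labs(x = "round", y = "mean per-molecule error",
                  size = "features") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
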
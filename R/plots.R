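# ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a feature ranking as a horizontal importance bar chart
#'
#' @param object A `feature_ranking`.
#' @param top_n Number of top taxa shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_ranking <- function(object, top_n = 20, ...) {
  d <- utils::head(tidy(object), top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$taxon, .data$importance)
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      x = "Normalized importance (mean decrease in impurity)", y = NULL,
      title = sprintf("Top %d taxa for encoded oil type", nrow(d))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-split hold-out test performance
#'
#' @param object A `holdout_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.holdout_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$split, y = .data$test_r2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(colour = "#d95f02") +
    ggplot2::geom_hline(yintercept = object$summary$mean, colour = "#d95f02") +
    ggplot2::labs(
      x = "Split", y = expression(R^2 ~ "(held-out bottles)"),
      title = sprintf(
        "Bottle-level hold-out: mean test R² = %.3f over %d splits",
        object$summary$mean, object$n_splits
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a feature-count sweep (the four pipeline R-squared curves)
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"k",
    names_to = "metric", values_to = "r2"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$k, y = .data$r2,
    colour = .data$metric, group = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Number of selected taxa (k)", y = expression(R^2),
      colour = NULL, title = "Pipeline performance across feature counts"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a 2-D embedding of samples
#'
#' Convenience scatter for [pca_2d()] / [tsne_2d()] coordinates.
#'
#' @param coords Tibble of 2-D coordinates.
#' @param colour_by Optional vector (e.g. site or oil label) to colour by.
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, colour_by = NULL) {
  nm <- names(coords)[1:2]
  d <- tibble::tibble(x = coords[[1]], y = coords[[2]])
  if (!is.null(colour_by)) d$group <- colour_by
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = nm[1], y = nm[2]) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
}
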
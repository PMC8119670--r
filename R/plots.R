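# ggplot2 visualisations for the main result types.

#' @describeIn fit_mixture Histogram of per-patch means with the fitted
#'   component densities and, optionally, the derived labeling thresholds.
#' @param object A `mixture_model`.
#' @param means Optional numeric vector of the per-patch means the model was
#'   fitted to (drawn as a histogram underlay).
#' @param thresholds Optional [derive_thresholds()] result (vertical
#'   cut-off lines).
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mixture_model <- function(object, means = NULL, thresholds = NULL, ...) {
  lo <- min(object$mu - 4 * object$sigma, means)
  hi <- max(object$mu + 4 * object$sigma, means)
  grid <- seq(lo, hi, length.out = 512)
  dens <- dplyr::bind_rows(lapply(seq_along(object$mu), function(j) {
    tibble::tibble(x = grid,
                   density = object$weight[j] * dnorm(grid, object$mu[j],
                                                      object$sigma[j]),
                   component = if (length(object$mu) == 2) {
                     c("live", "dead")[j]
                   } else paste0("comp", j))
  }))
  p <- ggplot2::ggplot()
  if (!is.null(means)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(m = means),
      ggplot2::aes(x = .data$m, y = ggplot2::after_stat(density)),
      bins = 60, fill = "grey80", colour = "grey60")
  }
  p <- p + ggplot2::geom_line(
    data = dens,
    ggplot2::aes(x = .data$x, y = .data$density, colour = .data$component),
    linewidth = 0.8)
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(thresholds$live_max, thresholds$dead_min),
      linetype = "dashed")
  }
  p + ggplot2::labs(x = "mean fluorescence (raw intensity)", y = "density",
                    colour = NULL)
}

#' @describeIn roc_auc ROC curve with the chance diagonal.
#' @param object A `roc_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc))
}

#' @describeIn evaluate_classifier ROC curve of the report.
#' @param object An `eval_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(subtitle = sprintf("balanced accuracy %.3f, r = %.3f",
                                     object$balanced_accuracy,
                                     object$pearson_r))
}

#' Scatter plot of a 2-D embedding projection
#'
#' Points are coloured by label; when both truth and predicted labels are
#' present, misclassified patches (the cluster-boundary confusions) are
#' overplotted as white dots.
#'
#' @param projection A [project_2d()] tibble.
#' @param colour_by Column to colour by (default `label`, falling back to
#'   `predicted`).
#' @return A ggplot object.
#' @export
plot_projection <- function(projection, colour_by = NULL) {
  if (is.null(colour_by)) {
    colour_by <- if ("label" %in% names(projection)) "label"
    else if ("predicted" %in% names(projection)) "predicted"
    else NULL
  }
  p <- ggplot2::ggplot(projection,
                       ggplot2::aes(x = .data$dim1, y = .data$dim2))
  p <- if (is.null(colour_by)) {
    p + ggplot2::geom_point(size = 1.2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                            size = 1.2)
  }
  if (all(c("label", "predicted") %in% names(projection))) {
    mis <- dplyr::filter(projection, .data$label != .data$predicted)
    if (nrow(mis) > 0) {
      p <- p + ggplot2::geom_point(data = mis, colour = "white", size = 0.6)
    }
  }
  p + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL)
}

#' Overlay an activation map on its bright-field patch
#'
#' @param map An [grad_cam()] result.
#' @param patch The 8-bit bright-field patch the map was computed for.
#' @param alpha Maximum opacity of the heat overlay.
#' @return A ggplot object.
#' @export
plot_activation_map <- function(map, patch, alpha = 0.6) {
  stopifnot(inherits(map, "activation_map"))
  h <- nrow(patch)
  df <- tidyr::expand_grid(y = seq_len(h), x = seq_len(h))
  df$intensity <- as.numeric(patch)[df$y + (df$x - 1L) * h]
  df$heat <- as.numeric(map$heatmap)[df$y + (df$x - 1L) * h]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$heat), fill = "red") +
    ggplot2::scale_alpha(range = c(0, alpha), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Grad-CAM: %s (p = %.2f)",
                                  as.character(map$target_class),
                                  map$probability),
                  x = NULL, y = NULL)
}
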
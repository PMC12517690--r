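#' Scree and scatter plot of a gradient set
#'
#' Left panel: explained variance against gradient number (the scree used
#' for elbow selection). Right panel: voxels in the space of the first two
#' gradients (or a strip plot for a single gradient).
#'
#' @param object A `gradient_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gradient_set
#' @export
autoplot.gradient_set <- function(object, ...) {
  ev <- tibble::tibble(gradient = seq_along(object$explained_variance),
                       explained_variance = object$explained_variance)
  ggplot2::ggplot(ev, ggplot2::aes(.data$gradient,
                                   .data$explained_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = ev$gradient) +
    ggplot2::labs(x = "gradient", y = "explained variance",
                  title = paste0("Diffusion embedding scree",
                                 if (!is.null(object$modality)) {
                                   paste0(" (", object$modality, ")")
                                 })) +
    ggplot2::theme_minimal()
}

#' Silhouette curve for a k-means sweep
#'
#' @param solutions List of `cluster_solution`s from [kmeans_sweep()].
#' @return A ggplot of mean silhouette against k, with the selected k
#'   highlighted.
#' @export
plot_silhouette_curve <- function(solutions) {
  df <- tibble::tibble(
    k = vapply(solutions, function(s) s$k, integer(1)),
    silhouette = vapply(solutions, function(s) s$silhouette, numeric(1))
  )
  best <- select_k(solutions)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette") +
    ggplot2::theme_minimal()
}

#' Violin plot of a labelled summary
#'
#' Distribution of (gradient or gradient-weighted connectivity) values per
#' network or nucleus label.
#'
#' @param object A `labeled_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot labeled_summary
#' @export
autoplot.labeled_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$label, .data$value,
                                       fill = .data$label)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' Stability curve across gradients
#'
#' Median split-half correlation per gradient with IQR ribbon.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$gradient, .data$median_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$median_r - .data$iqr_r / 2,
      ymax = pmin(1, .data$median_r + .data$iqr_r / 2)
    ), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$gradient) +
    ggplot2::labs(x = "gradient", y = "split-half |r| (median, IQR)") +
    ggplot2::theme_minimal()
}
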
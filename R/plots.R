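#' Plot an enclosed-volume breathing signal
#'
#' Volume trace with the detected end-expiratory and end-inspiratory
#' instants overlaid when an endpoint set is supplied.
#'
#' @param object A `breath_signal` tibble from [volume_signal()].
#' @param endpoints Optional `endpoint_set` from [detect_endpoints()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot breath_signal
#' @export
autoplot.breath_signal <- function(object, endpoints = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$volume_mm3 / 1e6)) +
    ggplot2::geom_line(colour = "grey30", na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "enclosed volume (L)",
                  title = sprintf("%s — %s", object$subject_id[1], object$condition[1])) +
    ggplot2::theme_minimal()
  if (!is.null(endpoints)) {
    p <- p + ggplot2::geom_point(
      data = endpoints,
      ggplot2::aes(x = .data$time_s, y = .data$volume_mm3 / 1e6, colour = .data$instant),
      size = 3) +
      ggplot2::scale_colour_manual(values = c(EX = "#2166ac", IN = "#b2182b"))
  }
  p
}

#' Shape-space scatter plot of PC scores
#'
#' The standard morphospace view: configurations in the plane of two PCs,
#' coloured by breathing condition and shaped by instant, with axis labels
#' carrying the explained variance fractions.
#'
#' @param object A `shape_pca`.
#' @param pcs Length-2 integer vector (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, pcs = c(1, 2), ...) {
  sc <- object$scores
  xcol <- paste0("PC", pcs[1]); ycol <- paste0("PC", pcs[2])
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition, shape = .data$instant),
                        size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.2f%%)", xcol, 100 * object$variance_fraction[pcs[1]]),
      y = sprintf("%s (%.2f%%)", ycol, 100 * object$variance_fraction[pcs[2]])) +
    ggplot2::theme_minimal()
}

#' Violin plots of functional size / shape by condition
#'
#' @param functional Output of [functional_size()] joined with
#'   [functional_shape()] (columns `posture`, `condition`, `FS` and/or
#'   `FSh`).
#' @param metric `"FS"` or `"FSh"`.
#' @return A ggplot object.
#' @export
plot_functional <- function(functional, metric = c("FS", "FSh")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(functional,
                  ggplot2::aes(x = .data$condition, y = .data[[metric]],
                               fill = .data$condition)) +
    ggplot2::geom_violin(alpha = 0.5, colour = NA) +
    ggplot2::geom_boxplot(width = 0.2, outlier.shape = NA, fill = "white") +
    ggplot2::geom_jitter(width = 0.08, size = 1, alpha = 0.6) +
    ggplot2::facet_wrap(~posture) +
    ggplot2::labs(y = if (metric == "FS") "functional size (mm)" else "functional shape") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
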
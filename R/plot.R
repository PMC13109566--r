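#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a point cloud projection
#'
#' A 2-D orthographic projection of the cloud, coloured by its labels (or
#' predicted labels when present).
#'
#' @param object A point-cloud tibble.
#' @param axes Which coordinate pair to draw, e.g. `c("x", "z")`.
#' @param colour Column to colour by; defaults to `pred_label` if present,
#'   else `label`, else none.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stemleaf_cloud <- function(object, axes = c("x", "z"),
                                    colour = NULL, ...) {
  if (is.null(colour)) {
    colour <- if ("pred_label" %in% names(object)) "pred_label"
              else if ("label" %in% names(object)) "label" else NULL
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[axes[1]]],
                                            y = .data[[axes[2]]]))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(
      .data[[colour]], levels = c(0, 1), labels = c("leaf", "stem"))),
      size = 0.3, alpha = 0.7) +
      ggplot2::scale_colour_manual(values = c(leaf = "#2E7D32",
                                              stem = "#FF8F00"),
                                   name = NULL)
  } else {
    p <- p + ggplot2::geom_point(size = 0.3, alpha = 0.7)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = paste(axes[1], "(m)"), y = paste(axes[2], "(m)"),
                  title = attr(object, "name"))
}

#' Plot a training history
#'
#' Loss curves (training and validation) over epochs.
#'
#' @param object A trained `seg_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seg_model <- function(object, ...) {
  h <- object$history
  if (is.null(h) || !nrow(h)) stop("model has no training history", call. = FALSE)
  long <- tidyr::pivot_longer(h[, c("epoch", "train_loss", "val_loss")],
                              -"epoch", names_to = "series",
                              values_to = "loss")
  long <- dplyr::filter(long, !is.na(.data$loss))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy", colour = NULL)
}

#' Plot a sampler benchmark
#'
#' Mean keypoint retention with one standard deviation per sampling method.
#'
#' @param report A [benchmark_samplers()] tibble.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$method,
                                       y = .data$retention_mean)) +
    ggplot2::geom_col(fill = "#4472A8", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$retention_mean - .data$retention_sd,
      ymax = .data$retention_mean + .data$retention_sd), width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) + ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "ISS keypoint retention")
}
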
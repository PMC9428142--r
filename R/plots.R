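#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall curve
#'
#' @param object A [pr_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object (one line per class).
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision,
                                       colour = .data$class)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "Class") +
    ggplot2::theme_minimal()
}

#' Plot a detection evaluation
#'
#' PR curves annotated with the per-class AP and the mAP.
#'
#' @param object A `detection_eval` from [evaluate_detections()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.detection_eval <- function(object, ...) {
  lab <- paste0(object$summary$class, " (AP = ",
                sprintf("%.3f", object$summary$ap), ")")
  curve <- object$curve
  curve$class <- lab[match(curve$class, object$summary$class)]
  autoplot(curve) +
    ggplot2::ggtitle(sprintf("mAP = %.3f (IoU > %.2f, %s)",
                             object$map, object$iou_threshold, object$mode))
}

#' Plot a phantom sample
#'
#' Image raster with the ground-truth boxes overlaid.
#'
#' @param object A `phantom_sample` from [generate_phantom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_sample <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(y = seq_len(nrow(img)) - 1L, x = seq_len(ncol(img)) - 1L)
  df$value <- as.vector(t(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "Intensity") +
    ggplot2::theme_void()
  if (nrow(object$boxes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$boxes, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max),
      colour = if (object$lesion_class == "malignant") "red" else "green",
      fill = NA, linewidth = 0.4)
  }
  p
}

#' Plot a segmenter training history
#'
#' @param object A `seg_fit` from [train_segmentation()].
#' @param ... Unused.
#' @return A ggplot object of loss (and recorded Dice) against epoch.
#' @export
autoplot.seg_fit <- function(object, ...) {
  hist <- tidyr::pivot_longer(object$history, c("loss", "train_dice"),
                              names_to = "metric", values_to = "value")
  hist <- hist[!is.na(hist$value), ]
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}
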
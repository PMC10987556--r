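raster_to_df <- function(img) {
  tibble::tibble(
    x = rep(seq_len(ncol(img)) - 0.5, each = nrow(img)),
    y = rep(seq_len(nrow(img)) - 0.5, times = ncol(img)),
    value = as.vector(img))
}

#' Plot a hand phantom with its joint annotations
#'
#' @param object A `hand_phantom`.
#' @param boxes Optional detection tibble overlaid in a second colour.
#' @param ... Ignored.
#' @return A ggplot object (y axis points down, as in image coordinates).
#' @export
autoplot.hand_phantom <- function(object, boxes = NULL, ...) {
  stopifnot(!is.null(object$image))
  gt <- box_corners(object$joints)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = raster_to_df(object$image),
                         ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::geom_rect(data = gt,
                       ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y0, ymax = .data$y1),
                       colour = "cyan", fill = NA, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(boxes) && nrow(boxes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = box_corners(boxes),
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = .data$y0, ymax = .data$y1),
      colour = "orange", fill = NA, linewidth = 0.4)
  }
  p
}

#' Plot a Grad-CAM contribution map
#'
#' @param object A `joint_gradcam`.
#' @param window Optional underlying window raster for overlay.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.joint_gradcam <- function(object, window = NULL, ...) {
  up <- gradcam_upsample(object)
  df <- raster_to_df(up / max(up, 1e-12))
  p <- ggplot2::ggplot()
  if (!is.null(window)) {
    p <- p + ggplot2::geom_raster(data = raster_to_df(window),
                                  ggplot2::aes(.data$x, .data$y,
                                               alpha = .data$value),
                                  fill = "white") +
      ggplot2::scale_alpha_identity()
  }
  p + ggplot2::geom_raster(data = df,
                           ggplot2::aes(.data$x, .data$y, fill = .data$value),
                           alpha = 0.6) +
    ggplot2::scale_fill_gradient(low = "transparent", high = "red",
                                 name = "contribution") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Grad-CAM %s / class %s",
                                  object$layer, object$class)) +
    ggplot2::theme_void()
}

#' Plot the training loss curve of a detector
#'
#' @param object A trained `joint_detector`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.joint_detector <- function(object, ...) {
  ggplot2::ggplot(object$loss_log, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "mean multibox loss",
                  title = sprintf("%s detector training", object$task)) +
    ggplot2::theme_minimal()
}
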
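#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained joint detector
#'
#' @param x A `joint_detector`.
#' @param ... Ignored.
#' @return The per-epoch training loss log as a tibble (`epoch`, `loss`).
#' @export
tidy.joint_detector <- function(x, ...) x$loss_log

#' One-row summary of a trained joint detector
#'
#' @param x A `joint_detector`.
#' @param ... Ignored.
#' @return A tibble with `task`, `window`, `n_default_boxes`,
#'   `n_parameters`, `epochs`, `initial_loss`, `final_loss`, `seed`.
#' @export
glance.joint_detector <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  tibble::tibble(
    task = x$task,
    window = x$config$window,
    n_default_boxes = nrow(x$grid),
    n_parameters = npar,
    epochs = x$epochs_trained,
    initial_loss = if (nrow(x$loss_log)) x$loss_log$loss[1] else NA_real_,
    final_loss = if (nrow(x$loss_log)) {
      x$loss_log$loss[nrow(x$loss_log)]
    } else NA_real_,
    seed = x$seed)
}

#' @export
print.joint_detector <- function(x, ...) {
  cat(sprintf("<joint_detector: %s task, %dx%d window, %d default boxes, %d epochs>\n",
              x$task, x$config$window, x$config$window, nrow(x$grid),
              x$epochs_trained))
  invisible(x)
}

#' @export
print.hand_phantom <- function(x, ...) {
  cat(sprintf("<hand_phantom %dx%d, %d joints, %d ankylosis+, %d subluxation+%s>\n",
              x$width, x$height, nrow(x$joints),
              sum(x$joints$ankylosis), sum(x$joints$subluxation, na.rm = TRUE),
              if (is.null(x$image)) ", annotations only" else ""))
  invisible(x)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  jt <- dataset_joints(x)
  cat(sprintf(
    "<phantom_dataset: %d images / %d patients, %d joint annotations (%d ankylosis+, %d subluxation+)>\n",
    length(x$images), length(x$images) / 2, nrow(jt),
    sum(jt$ankylosis), sum(jt$subluxation, na.rm = TRUE)))
  invisible(x)
}
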
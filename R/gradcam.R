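#' Grad-CAM contribution map from activations and gradients
#'
#' The core gradient-weighted class-activation computation: for a feature
#' map `A` with channels `k` and the gradient `dA` of a class score with
#' respect to it, each channel weight is the spatial mean of its gradient,
#' \deqn{\alpha_k = \frac{1}{Z} \sum_i \sum_j \frac{\partial y_c}{\partial A^k_{ij}},}
#' and the contribution map is the rectified weighted channel sum
#' \deqn{G_c = \mathrm{ReLU}\big(\sum_k \alpha_k A^k\big).}
#'
#' @param activations Numeric H x W x K array (a matrix is treated as K=1).
#' @param gradients Array of the same shape: class-score gradient w.r.t.
#'   `activations`.
#' @return A list with `map` (H x W non-negative matrix), `alpha` (per
#'   channel weights), and `pre_relu` (the unrectified weighted sum).
#' @export
gradcam_map <- function(activations, gradients) {
  if (is.matrix(activations)) dim(activations) <- c(dim(activations), 1L)
  if (is.matrix(gradients)) dim(gradients) <- c(dim(gradients), 1L)
  stopifnot(identical(dim(activations), dim(gradients)))
  k <- dim(activations)[3]
  alpha <- apply(gradients, 3, mean)
  pre <- matrix(0, dim(activations)[1], dim(activations)[2])
  for (ch in seq_len(k)) pre <- pre + alpha[ch] * activations[, , ch]
  list(map = pmax(pre, 0), alpha = alpha, pre_relu = pre)
}

#' Grad-CAM heatmap for a detector layer and class
#'
#' Defines the class score `y_c` of the multi-box detector as the summed
#' class-`c` logit over the boxes surviving the confidence filter (falling
#' back to the single highest-confidence box when none survives), sets the
#' gradients of all other classes to zero, backpropagates to the requested
#' backbone layer, and applies [gradcam_map()].
#'
#' @param det A `joint_detector`.
#' @param window Square grayscale matrix of the configured window size.
#' @param layer Backbone layer name whose activation map is visualised
#'   (e.g. `"relu3"`); must name a layer the detection heads depend on.
#' @param class `"present"`, `"absent"` or `"background"`.
#' @param t_conf Confidence filter defining the contributing box set.
#' @return A `joint_gradcam` object: `map` (non-negative matrix at feature
#'   map resolution), `alpha`, `layer`, `class`, `boxes_used`, `window_size`.
#' @export
gradcam <- function(det, window, layer = "relu3",
                    class = c("present", "absent", "background"),
                    t_conf = 0.9) {
  class <- match.arg(class)
  cidx <- match(class, class_levels)
  x <- windows_to_input(window, det$config$window)
  raw <- detector_forward_raw(det, x)
  if (is.null(raw$fw$acts[[layer]])) {
    stop(sprintf("unknown layer '%s'", layer), call. = FALSE)
  }
  pr <- softmax_rows(raw$logits[, , 1])
  conf <- pmax(pr[, 1], pr[, 2])
  sel <- which(conf > t_conf)
  if (length(sel) == 0) sel <- which.max(conf)
  nb_tot <- nrow(det$grid)
  dlogits <- array(0, c(nb_tot, n_classes, 1L))
  dlogits[sel, cidx, 1L] <- 1  # d y_c / d logit; other classes zeroed
  doffsets <- array(0, c(nb_tot, 4L, 1L))
  bk <- multibox_backward(det, raw, dlogits, doffsets)
  dact <- bk$dacts[[layer]]
  if (is.null(dact)) {
    stop(sprintf("layer '%s' does not feed the detection heads", layer),
         call. = FALSE)
  }
  act <- raw$fw$acts[[layer]]
  a3 <- act[, , 1, ]; dim(a3) <- dim(act)[c(1, 2, 4)]
  d3 <- dact[, , 1, ]; dim(d3) <- dim(dact)[c(1, 2, 4)]
  gc <- gradcam_map(a3, d3)
  structure(list(map = gc$map, alpha = gc$alpha, layer = layer,
                 class = class, boxes_used = sel,
                 window_size = det$config$window),
            class = "joint_gradcam")
}

#' Upsample a Grad-CAM map to window resolution
#'
#' Bilinear interpolation for overlay rendering; the raw map is kept on the
#' feature-map grid.
#'
#' @param x A `joint_gradcam`.
#' @param size Output side in pixels (defaults to the detector window).
#' @return A numeric matrix.
#' @export
gradcam_upsample <- function(x, size = x$window_size) {
  resize_bilinear(x$map, size, size)
}
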
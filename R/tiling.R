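#' Plan the sliding-window scan of a whole radiograph
#'
#' Window origins form a regular grid starting at 0 with the given stride;
#' origins are generated while they lie strictly inside the image, so the
#' union of windows covers every pixel and the last row/column of windows
#' extends past the image (that area is zero-padded at crop time).
#'
#' @param image_w,image_h Image extent in pixels.
#' @param window Square window side (default 300).
#' @param stride Shift between windows (default 150); `window >= stride > 0`.
#' @return A `window_plan`: tibble of `origin_x`, `origin_y` plus attributes
#'   `window`, `stride`, `image_w`, `image_h`.
#' @examples
#' nrow(plan_windows(1005, 835)) # 42 windows (7 x 6)
#' @export
plan_windows <- function(image_w, image_h, window = 300L, stride = 150L) {
  if (image_w <= 0 || image_h <= 0) stop("non-positive image dimensions",
                                         call. = FALSE)
  if (!(window >= stride && stride > 0)) stop("need window >= stride > 0",
                                              call. = FALSE)
  ox <- seq.int(0L, by = stride, length.out = max(1L, ceiling(image_w / stride)))
  oy <- seq.int(0L, by = stride, length.out = max(1L, ceiling(image_h / stride)))
  plan <- tidyr::expand_grid(origin_y = oy, origin_x = ox)[, c("origin_x", "origin_y")]
  structure(plan, window = window, stride = stride,
            image_w = image_w, image_h = image_h, class = c("window_plan",
                                                            class(plan)))
}

#' Scan a whole image with a trained detector
#'
#' Runs the detector on every planned window (zero-padded at the image
#' boundary), decodes the per-default-box offsets against the window's
#' default-box grid, and translates the decoded boxes by the window origin
#' into full-image coordinates. No confidence filtering is applied here.
#'
#' @param image Grayscale matrix in \[0, 1\] (already resized/preprocessed).
#' @param det A `joint_detector`.
#' @param plan A `window_plan`; defaults to the detector's window size with
#'   stride `window / 2`.
#' @return A detection tibble in full-image coordinates with class
#'   probabilities, `confidence` and `detector`, plus the emitting
#'   `origin_x`, `origin_y`.
#' @export
scan_image <- function(image, det, plan = NULL) {
  win <- det$config$window
  if (is.null(plan)) {
    plan <- plan_windows(ncol(image), nrow(image), win, win %/% 2L)
  }
  stopifnot(attr(plan, "window") == win)
  grid <- det$grid
  res <- purrr::pmap_dfr(plan, function(origin_x, origin_y) {
    crop <- crop_with_pad(image, origin_x, origin_y, win, win)
    out <- detector_forward(det, crop)
    dec <- decode_boxes(out[, c("t_cx", "t_cy", "t_w", "t_h")], grid)
    tibble::tibble(
      cx = dec$cx + origin_x, cy = dec$cy + origin_y, w = dec$w, h = dec$h,
      p_present = out$p_present, p_absent = out$p_absent,
      p_background = out$p_background, confidence = out$confidence,
      detector = det$task, origin_x = origin_x, origin_y = origin_y)
  })
  res
}

#' Confidence filtering, non-maximum suppression and top-M selection
#'
#' `filter_confidence()` keeps detections with confidence strictly above
#' `t_conf` (order preserved). `nms()` performs greedy non-maximum
#' suppression: detections are visited in descending confidence (ties keep
#' the earlier row, for determinism) and a detection is removed when its
#' IoU with an already kept detection is greater than or equal to `t_iou`.
#' `select_top_m()` keeps the `m` highest-confidence detections in
#' descending order.
#'
#' @param dets A detection tibble (columns `cx`, `cy`, `w`, `h`,
#'   `confidence`, ...).
#' @param t_conf Confidence threshold (strict `>`).
#' @param t_iou NMS threshold (inclusive `>=`); the pipeline default 0.15 is
#'   deliberately strict because finger-joint boxes barely overlap.
#' @param m Maximum number of detections kept (20 for the ankylosis task,
#'   18 for subluxation).
#' @return A filtered detection tibble.
#' @export
filter_confidence <- function(dets, t_conf = 0.9) {
  dplyr::filter(dets, .data$confidence > t_conf)
}

#' @rdname filter_confidence
#' @export
nms <- function(dets, t_iou = 0.15) {
  n <- nrow(dets)
  if (n <= 1) return(dets)
  ord <- order(-dets$confidence)  # stable: ties keep scan order
  keep <- logical(n)
  iou <- box_iou(dets, dets)
  for (i in ord) {
    if (any(keep & iou[, i] >= t_iou)) next
    keep[i] <- TRUE
  }
  dets[keep, , drop = FALSE]
}

#' @rdname filter_confidence
#' @export
select_top_m <- function(dets, m) {
  if (m < 0) stop("m must be non-negative", call. = FALSE)
  ord <- order(-dets$confidence)
  dets[ord[seq_len(min(m, nrow(dets)))], , drop = FALSE]
}

#' Whole-image prediction with one detector
#'
#' The composition scan -> confidence filter -> NMS -> top-M that produces
#' one detector's output for the ensemble. With a `joint_detector` the image
#' is scanned per `plan`; an `oracle_spec` (see [oracle_predictor()])
#' shortcuts the scan and emits its controlled detections directly.
#'
#' @param image A `hand_phantom` or grayscale matrix.
#' @param det A `joint_detector` or `oracle_spec`.
#' @param params Pipeline parameter list, see [run_config()]; uses
#'   `t_conf`, `t_iou1`, and `m1`/`m2` according to the detector task.
#' @param plan Optional `window_plan`.
#' @return A detection tibble with at most M rows, confidence-descending.
#' @export
predict_single <- function(image, det, params = run_config(), plan = NULL) {
  raster <- if (inherits(image, "hand_phantom")) image$image else image
  dets <- if (inherits(det, "oracle_spec")) {
    stopifnot(inherits(image, "hand_phantom"))
    rlang::exec(oracle_detector, img = image, !!!det$args)
  } else {
    scan_image(raster, det, plan)
  }
  m <- if (det$task == "ankylosis") params$m1 else params$m2
  dets |>
    filter_confidence(params$t_conf) |>
    nms(params$t_iou1) |>
    select_top_m(m)
}

#' Package an oracle detector as a pipeline-compatible predictor
#'
#' @param task `"ankylosis"` or `"subluxation"`.
#' @param ... Arguments passed on to [oracle_detector()] (`box_jitter`,
#'   `dropout_rate`, `label_flip`, `conf_model`, `seed`).
#' @return An `oracle_spec` usable as the detector in [predict_single()]
#'   and [predict_ensemble()].
#' @export
oracle_predictor <- function(task = c("ankylosis", "subluxation"), ...) {
  task <- match.arg(task)
  structure(list(task = task, args = c(list(task = task), list(...))),
            class = "oracle_spec")
}
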
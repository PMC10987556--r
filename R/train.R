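#' Stochastic training-time augmentation of a window
#'
#' Applies four transforms, each independently with probability 0.5, to a
#' square training window and its box annotations: intensity jitter
#' ("colouring": random gain and offset), crop-resize (random sub-window of
#' 80-100% side, resized back), rotation by a random multiple of 90 degrees,
#' and horizontal flip. Box annotations are transformed consistently; under
#' crop-resize, boxes whose center leaves the crop are dropped.
#'
#' @param window Square grayscale matrix in \[0, 1\].
#' @param boxes Box tibble in window coordinates (extra columns preserved).
#' @param p Per-transform application probability.
#' @return A list with elements `window` and `boxes`. Uses the current RNG
#'   stream; seed externally for reproducibility.
#' @export
augment_window <- function(window, boxes, p = 0.5) {
  win <- nrow(window)
  if (stats::runif(1) < p) {  # colouring: brightness/contrast jitter
    gain <- stats::runif(1, 0.8, 1.2)
    off <- stats::runif(1, -0.1, 0.1)
    window <- clip01(window * gain + off)
  }
  if (stats::runif(1) < p && nrow(boxes) > 0) {  # crop-resize
    f <- stats::runif(1, 0.8, 1)
    side <- floor(f * win)
    ox <- sample.int(win - side + 1L, 1L) - 1L
    oy <- sample.int(win - side + 1L, 1L) - 1L
    window <- resize_bilinear(window[(oy + 1):(oy + side),
                                     (ox + 1):(ox + side), drop = FALSE],
                              win, win)
    s <- win / side
    boxes$cx <- (boxes$cx - ox) * s; boxes$cy <- (boxes$cy - oy) * s
    boxes$w <- boxes$w * s; boxes$h <- boxes$h * s
    boxes <- boxes[boxes$cx > 0 & boxes$cx < win &
                     boxes$cy > 0 & boxes$cy < win, , drop = FALSE]
  }
  if (stats::runif(1) < p) {  # rotate by k * 90 degrees
    k <- sample(1:3, 1)
    for (r in seq_len(k)) {
      window <- rot90_cw(window)
      boxes <- rot90_boxes_cw(boxes, win)
    }
  }
  if (stats::runif(1) < p) {  # horizontal flip
    window <- window[, ncol(window):1, drop = FALSE]
    boxes$cx <- win - boxes$cx
  }
  list(window = window, boxes = boxes)
}

# One random training crop around a target joint: a window-sized crop whose
# extent fully contains the joint box, origin uniform over admissible
# positions (zero-padded beyond the image). Ground truth for the crop is
# every task-eligible joint whose box lies fully inside the window.
crop_around_joint <- function(img, joints, target_row, win) {
  tb <- joints[target_row, ]
  # admissible origins keep the whole target box inside the window
  lo_x <- ceiling(tb$cx + tb$w / 2) - win; hi_x <- floor(tb$cx - tb$w / 2)
  lo_y <- ceiling(tb$cy + tb$h / 2) - win; hi_y <- floor(tb$cy - tb$h / 2)
  ox <- if (hi_x > lo_x) sample(lo_x:hi_x, 1L) else lo_x
  oy <- if (hi_y > lo_y) sample(lo_y:hi_y, 1L) else lo_y
  window <- crop_with_pad(img, ox, oy, win, win)
  lb <- joints
  lb$cx <- lb$cx - ox; lb$cy <- lb$cy - oy
  keep <- lb$cx - lb$w / 2 >= 0 & lb$cx + lb$w / 2 <= win &
    lb$cy - lb$h / 2 >= 0 & lb$cy + lb$h / 2 <= win
  list(window = window, boxes = lb[keep, , drop = FALSE])
}

task_joints <- function(joints, task) {
  if (task == "subluxation") {
    joints <- dplyr::filter(joints, .data$joint_type != "IP")
  }
  dplyr::mutate(joints, positive = if (task == "ankylosis") {
    .data$ankylosis
  } else .data$subluxation)
}

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

adam_step <- function(params, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 5e-4) {
  for (nm in names(grads)) {
    for (f in c("W", "b")) {
      g <- grads[[nm]][[f]] + weight_decay * params[[nm]][[f]]
      st <- state[[nm]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[f]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train a joint detector on an annotated dataset
#'
#' Each epoch draws one fresh random crop per task-eligible joint per image
#' (so an image contributes 20 crops for the ankylosis task and 18 for the
#' subluxation task), augments each crop, and minimises the combined
#' multibox confidence + localisation loss with the Adam optimiser.
#' Deterministic given `seed`.
#'
#' @param dataset A phantom dataset from [generate_dataset()] or any list of
#'   annotated images (elements with `$image` and `$joints`).
#' @param task `"ankylosis"` or `"subluxation"`.
#' @param config Detector configuration, see [detector_config_tiny()].
#' @param epochs Training epochs.
#' @param batch_size Crops per optimiser step.
#' @param lr,beta1,beta2,weight_decay Adam hyper-parameters (defaults:
#'   alpha 0.001, beta1 0.9, beta2 0.999, weight decay 0.0005).
#' @param augment_p Per-transform augmentation probability.
#' @param seed Integer seed controlling initialisation, cropping,
#'   augmentation and batch order.
#' @return A trained `joint_detector` carrying a per-epoch `loss_log`.
#' @export
train_detector <- function(dataset, task = c("ankylosis", "subluxation"),
                           config = detector_config_tiny(), epochs = 30L,
                           batch_size = 16L, lr = 1e-3, beta1 = 0.9,
                           beta2 = 0.999, weight_decay = 5e-4,
                           augment_p = 0.5, seed = 1L) {
  task <- match.arg(task)
  imgs <- dataset_images(dataset)
  if (length(imgs) == 0) stop("empty training dataset", call. = FALSE)
  det <- new_joint_detector(task, config, seed)
  win <- config$window
  state <- adam_init(det$params)
  t_step <- 0L
  log <- tibble::tibble(epoch = integer(), loss = numeric())
  local_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      crops <- list()
      for (im in imgs) {
        jt <- task_joints(im$joints, task)
        for (r in seq_len(nrow(jt))) {
          cr <- crop_around_joint(im$image, jt, r, win)
          cr <- augment_window(cr$window, cr$boxes, augment_p)
          crops[[length(crops) + 1L]] <- cr
        }
      }
      crops <- crops[sample.int(length(crops))]
      ep_loss <- 0; ep_n <- 0L
      for (b0 in seq(1L, length(crops), by = batch_size)) {
        idx <- b0:min(b0 + batch_size - 1L, length(crops))
        x <- windows_to_input(lapply(crops[idx], `[[`, "window"), win)
        gt <- lapply(crops[idx], `[[`, "boxes")
        res <- multibox_batch_loss(det, x, gt)
        t_step <- t_step + 1L
        upd <- adam_step(det$params, res$grads, state, t_step, lr,
                         beta1, beta2, weight_decay = weight_decay)
        det$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + res$loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      log <- dplyr::bind_rows(log,
        tibble::tibble(epoch = ep, loss = ep_loss / ep_n))
    }
  })
  det$loss_log <- log
  det$epochs_trained <- as.integer(epochs)
  det
}

#' Per-window detection recall of a trained detector
#'
#' For every task-eligible joint of the given images, crops one random
#' window containing the joint, runs the detector, decodes and
#' NMS-filters its detections, and checks whether any surviving box
#' overlaps the target joint with IoU above `iou_success`. This isolates
#' window-level localisation quality from whole-image tiling.
#'
#' @param det A trained `joint_detector`.
#' @param images List of annotated images (`hand_phantom`).
#' @param t_conf Confidence filter applied to window detections.
#' @param t_iou1 NMS threshold.
#' @param iou_success Detection success threshold (strict `>`).
#' @param seed Integer seed for crop placement.
#' @return Recall in \[0, 1\].
#' @export
per_window_recall <- function(det, images, t_conf = 0.5, t_iou1 = 0.15,
                              iou_success = 0.45, seed = 1L) {
  win <- det$config$window
  local_seed(seed, {
    hits <- integer(0)
    for (im in images) {
      jt <- task_joints(im$joints, det$task)
      for (r in seq_len(nrow(jt))) {
        cr <- crop_around_joint(im$image, jt, r, win)
        out <- detector_forward(det, cr$window)
        dec <- decode_boxes(out[, c("t_cx", "t_cy", "t_w", "t_h")], det$grid)
        dec$confidence <- out$confidence
        dets <- nms(filter_confidence(dec, t_conf), t_iou1)
        # target joint in window coordinates comes from the crop itself
        tb <- cr$boxes[cr$boxes$joint_id == jt$joint_id[r], , drop = FALSE]
        hit <- nrow(dets) > 0 && nrow(tb) == 1 &&
          max(box_iou(dets, tb)) > iou_success
        hits <- c(hits, as.integer(hit))
      }
    }
    mean(hits)
  })
}

dataset_images <- function(dataset) {
  if (inherits(dataset, "hand_phantom")) return(list(dataset))
  if (!is.null(dataset$images)) dataset$images else dataset
}
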
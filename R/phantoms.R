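#' Parameters for the synthetic hand-phantom generator
#'
#' The phantom emulates the study conditions of the clinical dataset the
#' pipeline was designed for: grayscale both-hand radiographs (the 50%%
#' resized originals are 1005 x 835 px), 20 annotated PIP/IP and MP joints
#' per image (18 for the subluxation task, the thumb IP carries no
#' subluxation label), ankylosis prevalence 157/5200 and
#' subluxation/dislocation prevalence 60/4680 per joint, two images per
#' patient. Rendering is deliberately minimal: bright phalanx segments over
#' a soft-tissue band, darker joint-space gaps, ankylosis as a gap filled
#' to bone intensity, subluxation as a lateral offset of the distal
#' segments, plus additive Gaussian noise.
#'
#' @param image_width,image_height Raster size in pixels.
#' @param finger_width Phalanx width in pixels.
#' @param gap_height Joint-space height in pixels.
#' @param box_scale Joint box side as a multiple of `finger_width`.
#' @param bone_intensity,tissue_intensity,background_intensity Gray levels
#'   in \[0, 1\].
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param prev_ankylosis,prev_subluxation Per-joint finding prevalences.
#' @param subluxation_offset Lateral displacement of subluxed segments as a
#'   fraction of `finger_width` (kept >= 0.4 so the finding is visible).
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(image_width = 1005, image_height = 835,
                           finger_width = 40, gap_height = 10,
                           box_scale = 1.6, bone_intensity = 0.75,
                           tissue_intensity = 0.35,
                           background_intensity = 0.10, noise_sd = 0.03,
                           prev_ankylosis = 157 / 5200,
                           prev_subluxation = 60 / 4680,
                           subluxation_offset = 0.45) {
  stopifnot(prev_ankylosis >= 0, prev_ankylosis <= 1,
            prev_subluxation >= 0, prev_subluxation <= 1)
  p <- as.list(environment())
  class(p) <- "phantom_params"
  p
}

#' @rdname phantom_params
#' @details `phantom_params_small()` is the desk-scale preset used for
#'   training and testing the tiny 64x64-window detector: a 320 x 256
#'   raster with 13-px fingers, giving ~21-px joint boxes that match the
#'   tiny default-box scales and stay well under window minus stride.
#' @export
phantom_params_small <- function(...) {
  args <- utils::modifyList(
    list(image_width = 320, image_height = 256, finger_width = 13,
         gap_height = 4, noise_sd = 0.02),
    list(...))
  rlang::exec(phantom_params, !!!args)
}

# Per-finger layout: 2 hands x 5 fingers. Finger 1 is the thumb (outermost
# column of each hand); its distal joint is the IP, all others are PIPs.
sample_hand_geometry <- function(params) {
  W <- params$image_width; H <- params$image_height
  fw <- params$finger_width
  pitch <- (W / 2) / 5
  if (pitch < fw * 1.3 || H < 24 * params$gap_height) {
    stop("raster too small for the phantom hand geometry", call. = FALSE)
  }
  tip_frac <- c(0.30, 0.16, 0.10, 0.14, 0.22)  # thumb .. pinky
  purrr::map_dfr(c("L", "R"), function(hand) {
    finger <- 1:5
    is_thumb <- finger == 1
    # thumbs sit at the outer edge of each hand's five-column block
    col_pos <- if (hand == "L") finger - 0.5 else 10.5 - finger
    tibble::tibble(
      hand = hand,
      finger = finger,
      is_thumb = is_thumb,
      x_center = col_pos * pitch + stats::runif(5, -0.08, 0.08) * pitch,
      tip_y = (tip_frac + stats::runif(5, -0.02, 0.02)) * H,
      j1_y = (ifelse(is_thumb, 0.50, 0.40) + stats::runif(5, -0.03, 0.03)) * H,
      j2_y = (ifelse(is_thumb, 0.70, 0.64) + stats::runif(5, -0.03, 0.03)) * H,
      palm_y = 0.88 * H)
  })
}

# Finding flags for one patient: Bernoulli draws at the stated prevalences;
# the thumb IP has no subluxation annotation slot (NA).
sample_finding_flags <- function(params) {
  tidyr::expand_grid(hand = c("L", "R"), finger = 1:5, row = 1:2) |>
    dplyr::mutate(
      joint_type = ifelse(.data$row == 2, "MP",
                          ifelse(.data$finger == 1, "IP", "PIP")),
      ankylosis = stats::runif(dplyr::n()) < params$prev_ankylosis,
      subluxation = ifelse(.data$joint_type == "IP", NA,
                           stats::runif(dplyr::n()) < params$prev_subluxation))
}

fill_rect <- function(img, x0, x1, y0, y1, value) {
  r0 <- max(1L, floor(y0) + 1L); r1 <- min(nrow(img), ceiling(y1))
  c0 <- max(1L, floor(x0) + 1L); c1 <- min(ncol(img), ceiling(x1))
  if (r1 >= r0 && c1 >= c0) img[r0:r1, c0:c1] <- value
  img
}

render_hand <- function(geom, flags, params, noise_seed = NULL) {
  W <- params$image_width; H <- params$image_height
  fw <- params$finger_width
  gap <- params$gap_height
  img <- matrix(params$background_intensity, H, W)
  out <- list()
  for (i in seq_len(nrow(geom))) {
    g <- geom[i, ]
    jf <- dplyr::filter(flags, .data$hand == g$hand, .data$finger == g$finger)
    j1 <- jf[jf$row == 1, ]; j2 <- jf[jf$row == 2, ]
    # lateral shifts: a subluxed joint displaces everything distal to it
    sh2 <- if (isTRUE(j2$subluxation)) params$subluxation_offset * fw else 0
    sh1 <- sh2 + if (isTRUE(j1$subluxation)) params$subluxation_offset * fw else 0
    xc <- c(distal = g$x_center + sh1, middle = g$x_center + sh2,
            proximal = g$x_center)
    seg <- tibble::tibble(
      x = xc,
      y0 = c(g$tip_y, g$j1_y + gap / 2, g$j2_y + gap / 2),
      y1 = c(g$j1_y - gap / 2, g$j2_y - gap / 2, g$palm_y))
    img <- fill_rect(img, min(seg$x) - fw * 0.75, max(seg$x) + fw * 0.75,
                     g$tip_y - fw / 2, g$palm_y, params$tissue_intensity)
    for (s in seq_len(3)) {
      img <- fill_rect(img, seg$x[s] - fw / 2, seg$x[s] + fw / 2,
                       seg$y0[s], seg$y1[s], params$bone_intensity)
    }
    # ankylosis: the joint space is ossified - bridge the gap at bone level
    for (r in 1:2) {
      jr <- if (r == 1) j1 else j2
      if (isTRUE(jr$ankylosis)) {
        xa <- (xc[r] + xc[r + 1]) / 2
        img <- fill_rect(img, xa - fw / 2, xa + fw / 2,
                         (if (r == 1) g$j1_y else g$j2_y) - gap,
                         (if (r == 1) g$j1_y else g$j2_y) + gap,
                         params$bone_intensity)
      }
    }
    side <- params$box_scale * fw
    out[[i]] <- jf |>
      dplyr::mutate(
        cx = ifelse(.data$row == 1, (xc[1] + xc[2]) / 2, (xc[2] + xc[3]) / 2),
        cy = ifelse(.data$row == 1, g$j1_y, g$j2_y),
        w = side, h = side)
  }
  joints <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$hand, .data$finger, .data$row) |>
    dplyr::mutate(joint_id = dplyr::row_number()) |>
    dplyr::select("joint_id", "hand", "finger", "joint_type",
                  "cx", "cy", "w", "h", "ankylosis", "subluxation")
  if (params$noise_sd > 0) {
    img <- clip01(img + matrix(stats::rnorm(H * W, 0, params$noise_sd), H, W))
  }
  list(image = img, joints = joints)
}

#' Generate one synthetic hand radiograph with joint annotations
#'
#' @param params A [phantom_params()] list.
#' @param seed Integer seed; the raster and annotations are byte-identical
#'   across calls with the same seed and parameters.
#' @param flags Optional precomputed finding flags (used internally so both
#'   timepoints of a patient share findings).
#' @param render If `FALSE`, skip rasterisation and return annotations only
#'   (the annotation stream is drawn before rendering, so annotations are
#'   identical either way).
#' @return A `hand_phantom`: list with `image` (matrix or `NULL`), `joints`
#'   (20-row tibble with box coordinates, joint tags and finding flags),
#'   `width`, `height`, `patient_id`, `timepoint`.
#' @export
generate_hand <- function(params = phantom_params(), seed = 1L, flags = NULL,
                          render = TRUE) {
  local_seed(seed, {
    if (is.null(flags)) flags <- sample_finding_flags(params)
    geom <- sample_hand_geometry(params)
    if (render) {
      r <- render_hand(geom, flags, params)
    } else {
      r <- render_hand(geom, flags,
                       utils::modifyList(params, list(noise_sd = 0),
                                         keep.null = TRUE))
      r["image"] <- list(NULL)
    }
    structure(list(image = r$image, joints = r$joints,
                   width = params$image_width, height = params$image_height,
                   patient_id = NA_integer_, timepoint = NA_integer_),
              class = "hand_phantom")
  })
}

#' Generate a phantom dataset emulating the study cohort
#'
#' `n_images / 2` synthetic patients, each contributing a pair of images at
#' two timepoints. Finding flags are drawn once per patient and shared by
#' both timepoints; the second timepoint re-draws the hand geometry, giving
#' a small positional drift. The default `n_images = 260` yields 5200
#' ankylosis-task and 4680 subluxation-task joint annotations.
#'
#' @param n_images Even number of images.
#' @param params A [phantom_params()] list.
#' @param seed Integer seed.
#' @param render If `FALSE`, annotations only (fast).
#' @return A `phantom_dataset`: list with `images` (list of `hand_phantom`),
#'   `params`, `seed`.
#' @export
generate_dataset <- function(n_images = 260L, params = phantom_params(),
                             seed = 1L, render = TRUE) {
  if (n_images %% 2 != 0) stop("n_images must be even (two images per patient)",
                               call. = FALSE)
  n_pat <- n_images %/% 2
  images <- vector("list", n_images)
  for (p in seq_len(n_pat)) {
    flags <- local_seed(((seed * 1000003) %% 2147483629) + p,
                        sample_finding_flags(params))
    for (tp in 1:2) {
      ph <- generate_hand(params,
                          seed = (((seed + 7) * 9973) %% 2147480000) +
                            2 * p + tp,
                          flags = flags, render = render)
      ph$patient_id <- p
      ph$timepoint <- tp
      images[[2L * (p - 1L) + tp]] <- ph
    }
  }
  structure(list(images = images, params = params, seed = seed),
            class = "phantom_dataset")
}

#' Collect all joint annotations of a dataset into one tibble
#'
#' @param dataset A `phantom_dataset` (or plain list of annotated images).
#' @return A tibble with one row per joint annotation, with `image_id`,
#'   `patient_id`, `timepoint` prepended to the per-joint columns.
#' @export
dataset_joints <- function(dataset) {
  imgs <- dataset_images(dataset)
  purrr::imap_dfr(imgs, function(im, i) {
    dplyr::mutate(im$joints, image_id = i,
                  patient_id = im$patient_id, timepoint = im$timepoint,
                  .before = 1)
  })
}

#' Oracle detector: a controllable stand-in for a trained detector
#'
#' Emits the ground-truth joint boxes of a phantom (task-eligible joints
#' only), each perturbed by a relative jitter, scored by a confidence model,
#' and omitted with a dropout probability. The output feeds the same tiled
#' inference, NMS and ensemble stages as a trained detector, which lets the
#' pipeline machinery be tested independently of training.
#'
#' @param img A `hand_phantom`.
#' @param task `"ankylosis"` or `"subluxation"`.
#' @param box_jitter Relative center/size perturbation in \[0, 1): centers
#'   move by up to `box_jitter` of the box side, log-sizes by up to
#'   `box_jitter`.
#' @param conf_model Function `n -> confidences`; defaults to
#'   `runif(n, 0.92, 0.995)` (above the pipeline's confidence threshold).
#' @param dropout_rate Probability of omitting each joint.
#' @param label_flip Probability of flipping the predicted finding label
#'   (for constructing classification errors in tests).
#' @param seed Integer seed.
#' @return A detection tibble (columns `cx`, `cy`, `w`, `h`, `p_present`,
#'   `p_absent`, `p_background`, `confidence`, `detector`), sorted by
#'   descending confidence.
#' @export
oracle_detector <- function(img, task = c("ankylosis", "subluxation"),
                            box_jitter = 0, conf_model = NULL,
                            dropout_rate = 0, label_flip = 0, seed = 1L) {
  task <- match.arg(task)
  stopifnot(box_jitter >= 0, box_jitter < 1,
            dropout_rate >= 0, dropout_rate <= 1)
  if (is.null(conf_model)) conf_model <- function(n) stats::runif(n, 0.92, 0.995)
  jt <- task_joints(img$joints, task)
  local_seed(seed, {
    keep <- stats::runif(nrow(jt)) >= dropout_rate
    jt <- jt[keep, , drop = FALSE]
    n <- nrow(jt)
    conf <- conf_model(n)
    pos <- xor(jt$positive, stats::runif(n) < label_flip)
    p_target <- conf
    p_other <- (1 - conf) * 0.7
    dets <- tibble::tibble(
      cx = jt$cx + stats::runif(n, -1, 1) * box_jitter * jt$w,
      cy = jt$cy + stats::runif(n, -1, 1) * box_jitter * jt$h,
      w = jt$w * exp(stats::runif(n, -1, 1) * box_jitter),
      h = jt$h * exp(stats::runif(n, -1, 1) * box_jitter),
      p_present = ifelse(pos, p_target, p_other),
      p_absent = ifelse(pos, p_other, p_target),
      p_background = 1 - p_target - p_other,
      confidence = conf,
      detector = task)
    dplyr::arrange(dets, dplyr::desc(.data$confidence))
  })
}
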
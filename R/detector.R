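#' Tiny multibox detector configuration
#'
#' The detector is a small fully-convolutional anchor-box network: a
#' backbone of 3x3 convolutions with ReLU and 2x2 max pooling, and one
#' detection head per source feature map. Each head is a 3x3 convolution
#' emitting, per default box of its map, 3 class logits (finding present,
#' finding absent, background) and 4 box offsets. The desk-scale
#' configuration takes a 64x64 window and taps two source maps (8x8 and
#' 4x4, 320 default boxes); the same machinery expresses the classic
#' 300x300 six-source layout via [grid_config_reference()].
#'
#' @param window Square input window side in pixels (multiple of 16).
#' @return A detector configuration list with `window`, `layers`, `sources`
#'   (layer names tapped by heads), `source_channels`, and `grid` (the
#'   default-box grid configuration).
#' @export
detector_config_tiny <- function(window = 64) {
  stopifnot(window %% 16 == 0)
  list(
    window = window,
    channels_in = 3L,
    layers = list(
      list(type = "conv", name = "conv1", cin = 3L, cout = 8L, k = 3L,
           stride = 1L, pad = 1L),
      list(type = "relu", name = "relu1"),
      list(type = "pool", name = "pool1"),
      list(type = "conv", name = "conv2", cin = 8L, cout = 16L, k = 3L,
           stride = 1L, pad = 1L),
      list(type = "relu", name = "relu2"),
      list(type = "pool", name = "pool2"),
      list(type = "conv", name = "conv3", cin = 16L, cout = 32L, k = 3L,
           stride = 1L, pad = 1L),
      list(type = "relu", name = "relu3"),
      list(type = "pool", name = "pool3"),
      list(type = "conv", name = "conv4", cin = 32L, cout = 32L, k = 3L,
           stride = 2L, pad = 1L),
      list(type = "relu", name = "relu4")),
    sources = c("pool3", "relu4"),
    source_channels = c(32L, 32L),
    grid = grid_config_tiny(window))
}

n_classes <- 3L
class_levels <- c("present", "absent", "background")

#' Initialise an untrained joint detector
#'
#' @param task Finding task the detector is trained for: `"ankylosis"`
#'   (all 20 joints) or `"subluxation"` (18 joints, thumb IP excluded).
#' @param config Detector configuration, see [detector_config_tiny()].
#' @param seed Integer seed for weight initialisation (He-normal).
#' @return An object of class `joint_detector`.
#' @export
new_joint_detector <- function(task = c("ankylosis", "subluxation"),
                               config = detector_config_tiny(), seed = 1L) {
  task <- match.arg(task)
  grid <- default_box_grid(config$grid)
  nb_per_map <- vapply(config$grid$maps, boxes_per_cell, integer(1))
  params <- local_seed(seed, {
    p <- list()
    for (ly in config$layers) {
      if (ly$type == "conv") p[[ly$name]] <- init_conv_params(ly$k, ly$cin, ly$cout)
    }
    for (si in seq_along(config$sources)) {
      p[[paste0("head", si)]] <- init_conv_params(
        3L, config$source_channels[si], nb_per_map[si] * (n_classes + 4L))
    }
    p
  })
  structure(
    list(task = task, config = config, grid = grid, params = params,
         nb_per_map = nb_per_map, seed = seed, epochs_trained = 0L,
         loss_log = tibble::tibble(epoch = integer(), loss = numeric())),
    class = "joint_detector")
}

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Windows enter as H x W grayscale matrices in [0, 1]; the single channel is
# replicated into three (the detector design expects colour input).
windows_to_input <- function(windows, window) {
  if (is.matrix(windows)) windows <- list(windows)
  n <- length(windows)
  x <- array(0, c(window, window, n, 3L))
  for (i in seq_len(n)) {
    wi <- windows[[i]]
    if (!is.matrix(wi) || nrow(wi) != window || ncol(wi) != window) {
      stop(sprintf("window %d is not a %dx%d matrix", i, window, window),
           call. = FALSE)
    }
    x[, , i, 1L] <- wi
  }
  x[, , , 2L] <- x[, , , 1L]
  x[, , , 3L] <- x[, , , 1L]
  x
}

# Raw forward pass on a [H, W, N, 3] input array. Returns backbone forward
# state plus per-source head output arrays and per-image (logits, offsets)
# matrices in default-box grid order.
detector_forward_raw <- function(det, x) {
  cfg <- det$config
  fw <- backbone_forward(det$params, cfg$layers, x)
  n <- dim(x)[3]
  nb_tot <- nrow(det$grid)
  logits <- array(0, c(nb_tot, n_classes, n))
  offsets <- array(0, c(nb_tot, 4L, n))
  head_fw <- list()
  ofs <- 0L
  for (si in seq_along(cfg$sources)) {
    hp <- det$params[[paste0("head", si)]]
    hf <- conv_forward(fw$acts[[cfg$sources[si]]], hp$W, hp$b, 1L, 1L)
    head_fw[[si]] <- hf
    hd <- dim(hf$out)  # Hs x Ws x N x nb*(3+4)
    nb <- det$nb_per_map[si]
    nmap <- hd[1] * hd[2] * nb
    for (i in seq_len(n)) {
      per <- head_to_box_order(hf$out[, , i, , drop = TRUE], hd[1], hd[2], nb)
      logits[ofs + seq_len(nmap), , i] <- per[, seq_len(n_classes)]
      offsets[ofs + seq_len(nmap), , i] <- per[, n_classes + seq_len(4L)]
    }
    ofs <- ofs + nmap
  }
  list(fw = fw, head_fw = head_fw, logits = logits, offsets = offsets)
}

# Head channel layout: channel c = (f - 1) * nb + b for field f in
# (logit_present, logit_absent, logit_background, t_cx, t_cy, t_w, t_h)
# and box-in-cell b. Rows of the result follow default-box grid order
# (cell row outer, cell column, box-in-cell innermost).
head_to_box_order <- function(a, hs, ws, nb) {
  dim(a) <- c(hs, ws, nb, n_classes + 4L)
  a <- aperm(a, c(3L, 2L, 1L, 4L))
  dim(a) <- c(nb * ws * hs, n_classes + 4L)
  a
}

box_order_to_head <- function(m, hs, ws, nb) {
  dim(m) <- c(nb, ws, hs, n_classes + 4L)
  m <- aperm(m, c(3L, 2L, 1L, 4L))
  dim(m) <- c(hs, ws, nb * (n_classes + 4L))
  m
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Run the detector on one input window
#'
#' @param det A `joint_detector`.
#' @param window A square grayscale matrix in \[0, 1\] of the configured
#'   window size.
#' @return A tibble with one row per default box, in grid order: class
#'   logits, softmax probabilities `p_present`, `p_absent`, `p_background`,
#'   `confidence` (the maximum over the two finding classes, background
#'   excluded), and the regressed offsets `t_cx`, `t_cy`, `t_w`, `t_h`.
#' @export
detector_forward <- function(det, window) {
  x <- windows_to_input(window, det$config$window)
  if (dim(x)[3] != 1L) stop("detector_forward() takes a single window")
  raw <- detector_forward_raw(det, x)
  lg <- raw$logits[, , 1]
  pr <- softmax_rows(lg)
  of <- raw$offsets[, , 1]
  tibble::tibble(
    logit_present = lg[, 1], logit_absent = lg[, 2], logit_background = lg[, 3],
    p_present = pr[, 1], p_absent = pr[, 2], p_background = pr[, 3],
    confidence = pmax(pr[, 1], pr[, 2]),
    t_cx = of[, 1], t_cy = of[, 2], t_w = of[, 3], t_h = of[, 4])
}
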
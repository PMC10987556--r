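# Shared fixtures: all synthetic, generated in code at test time.

tiny_params <- function(...) phantom_params_small(...)

# A small phantom with guaranteed positive findings for label plumbing tests.
positive_phantom <- function(seed = 11) {
  generate_hand(tiny_params(prev_ankylosis = 0.3, prev_subluxation = 0.2),
                seed = seed)
}

# Random valid boxes for property tests.
random_boxes <- function(n, range = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  boxes(cx = runif(n, 0, range), cy = runif(n, 0, range),
        w = runif(n, 0.5, range / 2), h = runif(n, 0.5, range / 2))
}

# Brute-force IoU via pixel rasterisation on integer boxes (independent
# oracle; O(area) counting instead of rectangle arithmetic).
raster_iou <- function(a, b) {
  grid_w <- ceiling(max(a$cx + a$w, b$cx + b$w)) + 2
  grid_h <- ceiling(max(a$cy + a$h, b$cy + b$h)) + 2
  fill <- function(bx) {
    m <- matrix(FALSE, grid_h, grid_w)
    xs <- seq(ceiling(bx$cx - bx$w / 2 + 0.5), floor(bx$cx + bx$w / 2 - 0.5) + 1)
    ys <- seq(ceiling(bx$cy - bx$h / 2 + 0.5), floor(bx$cy + bx$h / 2 - 0.5) + 1)
    m[ys, xs] <- TRUE
    m
  }
  ma <- fill(a); mb <- fill(b)
  sum(ma & mb) / sum(ma | mb)
}

# Greedy NMS oracle: independent quadratic implementation over all pairs.
nms_oracle <- function(dets, t_iou) {
  ord <- order(-dets$confidence)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (box_iou(dets[i, ], dets[j, ])[1, 1] >= t_iou) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  dets[sort(kept), , drop = FALSE]
}

# Greedy assignment oracle: repeatedly take the global max-IoU pair.
match_oracle <- function(preds, gts, iou_success) {
  iou <- box_iou(preds, gts)
  res <- data.frame(gt = seq_len(nrow(gts)), pred = NA_integer_, iou = 0)
  while (any(iou > 0)) {
    ij <- arrayInd(which.max(iou), dim(iou))
    res$pred[ij[2]] <- ij[1]
    res$iou[ij[2]] <- iou[ij[1], ij[2]]
    iou[ij[1], ] <- -1
    iou[, ij[2]] <- -1
  }
  res$detected <- res$iou > iou_success
  res
}
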
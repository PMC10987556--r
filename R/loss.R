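#' Match ground-truth boxes to a default-box grid
#'
#' Implements the standard multibox matching rule: every default box whose
#' best IoU against the ground truth reaches `match_iou` is assigned to its
#' argmax ground-truth box, and in addition each ground-truth box always
#' claims its own argmax-IoU default box (so every annotated joint has at
#' least one positive anchor). Forced best-match assignments take precedence.
#'
#' @param gt Ground-truth box tibble; an optional logical column `positive`
#'   marks the finding-present class (defaults to absent).
#' @param grid Default-box tibble from [default_box_grid()], in window
#'   coordinates.
#' @param match_iou Matching threshold (default 0.5).
#' @return A list of class `multibox_match`: `gt_index` (integer per default
#'   box, NA for unmatched), `class` (integer per default box: 1 present,
#'   2 absent, 3 background), `pos`/`neg` index vectors, and `n_matched`.
#' @export
match_defaults <- function(gt, grid, match_iou = 0.5) {
  if (nrow(grid) == 0) stop("empty default-box grid", call. = FALSE)
  nb <- nrow(grid)
  gt_index <- rep(NA_integer_, nb)
  if (nrow(gt) > 0) {
    iou <- box_iou(grid, gt)
    best <- max.col(iou, ties.method = "first")
    best_iou <- iou[cbind(seq_len(nb), best)]
    gt_index[best_iou >= match_iou] <- best[best_iou >= match_iou]
    for (j in seq_len(nrow(gt))) {
      gt_index[which.max(iou[, j])] <- j
    }
  }
  positive <- if ("positive" %in% names(gt)) gt$positive else rep(FALSE, nrow(gt))
  cls <- rep(3L, nb)
  matched <- !is.na(gt_index)
  cls[matched] <- ifelse(positive[gt_index[matched]], 1L, 2L)
  structure(list(gt_index = gt_index, class = cls,
                 pos = which(matched), neg = which(!matched),
                 n_matched = sum(matched)),
            class = "multibox_match")
}

#' Smooth L1 (Huber) penalty
#'
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise; continuous with
#' continuous first derivative at `|x| = 1`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of penalties.
#' @export
smooth_l1 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, 0.5 * x^2, ax - 0.5)
}

smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

#' Multibox localisation loss
#'
#' Sum of smooth-L1 penalties over the four offset coordinates of every
#' matched (positive) default box, comparing predicted offsets with the
#' encoded ground-truth offsets. Unnormalised; see [total_loss()].
#'
#' @param assign A `multibox_match` from [match_defaults()].
#' @param predicted_offsets Numeric n_default x 4 matrix in grid order.
#' @param encoded_targets Numeric n_default x 4 matrix; only rows of matched
#'   boxes are read.
#' @return Non-negative scalar.
#' @export
localization_loss <- function(assign, predicted_offsets, encoded_targets) {
  if (!identical(dim(predicted_offsets), dim(encoded_targets))) {
    stop("offset matrices must have identical shape", call. = FALSE)
  }
  if (length(assign$pos) == 0) return(0)
  d <- predicted_offsets[assign$pos, , drop = FALSE] -
    encoded_targets[assign$pos, , drop = FALSE]
  sum(smooth_l1(d))
}

#' Multibox confidence loss with hard negative mining
#'
#' Softmax cross-entropy summed over positive boxes (against their
#' finding class) plus the hardest negative boxes (against the background
#' class). Negatives are ranked by background cross-entropy and at most
#' `neg_pos_ratio` times the number of positives are kept; when there are
#' no positives the `n_neg_floor` hardest negatives are still counted so a
#' background-only window contributes a signal.
#'
#' @param assign A `multibox_match`.
#' @param logits Numeric n_default x 3 matrix (present, absent, background).
#' @param neg_pos_ratio Negative:positive counting ratio (default 3).
#' @param n_neg_floor Negatives counted when no box is matched.
#' @return Non-negative scalar (unnormalised; see [total_loss()]).
#' @export
confidence_loss <- function(assign, logits, neg_pos_ratio = 3,
                            n_neg_floor = 0L) {
  logp <- log_softmax_rows(logits)
  pos_loss <- if (length(assign$pos)) {
    -sum(logp[cbind(assign$pos, assign$class[assign$pos])])
  } else 0
  neg <- assign$neg
  n_neg <- min(length(neg),
               max(neg_pos_ratio * length(assign$pos), n_neg_floor))
  neg_loss <- 0
  if (n_neg > 0) {
    ce_bg <- -logp[neg, 3L]
    keep <- neg[order(ce_bg, decreasing = TRUE)[seq_len(n_neg)]]
    neg_loss <- -sum(logp[keep, 3L])
  }
  pos_loss + neg_loss
}

log_softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  z - log(rowSums(exp(z)))
}

#' Combine confidence and localisation losses
#'
#' The combined multibox objective `(L_conf + L_loc) / N` where `N` is the
#' number of matched default boxes; defined as 0 when nothing matches.
#'
#' @param conf,loc Unnormalised loss terms.
#' @param n Number of matched default boxes.
#' @return Scalar loss.
#' @export
total_loss <- function(conf, loc, n) {
  stopifnot(n >= 0)
  if (n == 0) return(0)
  (conf + loc) / n
}

# Full loss + analytic gradients for a batch. `x` is a [H,W,N,3] input,
# `gt_list` a list of N ground-truth tibbles in window coordinates (columns
# cx, cy, w, h, positive). The batch loss is the mean of per-image total
# losses. Returns parameter gradients when `grads = TRUE`.
multibox_batch_loss <- function(det, x, gt_list, match_iou = 0.5,
                                neg_pos_ratio = 3, grads = TRUE,
                                n_neg_floor = 8L) {
  raw <- detector_forward_raw(det, x)
  n <- dim(x)[3]
  nb_tot <- nrow(det$grid)
  dlogits <- array(0, c(nb_tot, n_classes, n))
  doffsets <- array(0, c(nb_tot, 4L, n))
  losses <- numeric(n)
  for (i in seq_len(n)) {
    gt <- gt_list[[i]]
    assign <- match_defaults(gt, det$grid, match_iou)
    lg <- raw$logits[, , i]
    of <- raw$offsets[, , i]
    targets <- matrix(0, nb_tot, 4L)
    if (length(assign$pos)) {
      enc <- encode_boxes(gt[assign$gt_index[assign$pos], ],
                          det$grid[assign$pos, ])
      targets[assign$pos, ] <- as.matrix(enc)
    }
    conf <- confidence_loss(assign, lg, neg_pos_ratio, n_neg_floor)
    loc <- localization_loss(assign, of, targets)
    nm <- max(assign$n_matched, if (n_neg_floor > 0) 1L else 0L)
    losses[i] <- total_loss(conf, loc, nm)
    if (grads && nm > 0) {
      sc <- 1 / (nm * n)
      # counted boxes for the confidence term (same selection as the loss)
      logp <- log_softmax_rows(lg)
      counted <- assign$pos
      tgt_cls <- assign$class[assign$pos]
      n_neg <- min(length(assign$neg),
                   max(neg_pos_ratio * length(assign$pos), n_neg_floor))
      if (n_neg > 0) {
        ce_bg <- -logp[assign$neg, 3L]
        keep <- assign$neg[order(ce_bg, decreasing = TRUE)[seq_len(n_neg)]]
        counted <- c(counted, keep)
        tgt_cls <- c(tgt_cls, rep(3L, n_neg))
      }
      if (length(counted)) {
        sm <- exp(logp[counted, , drop = FALSE])
        sm[cbind(seq_along(counted), tgt_cls)] <-
          sm[cbind(seq_along(counted), tgt_cls)] - 1
        dlogits[counted, , i] <- sc * sm
      }
      if (length(assign$pos)) {
        dd <- smooth_l1_grad(of[assign$pos, , drop = FALSE] -
                               targets[assign$pos, , drop = FALSE])
        doffsets[assign$pos, , i] <- sc * dd
      }
    }
  }
  loss <- mean(losses)
  if (!grads) return(list(loss = loss))
  list(loss = loss,
       grads = multibox_backward(det, raw, dlogits, doffsets)$grads)
}

# Push per-box gradients back through heads and backbone. Returns parameter
# gradients and gradients w.r.t. every backbone activation (for Grad-CAM).
multibox_backward <- function(det, raw, dlogits, doffsets) {
  cfg <- det$config
  n <- dim(dlogits)[3]
  grads <- list()
  dacts <- list()
  ofs <- 0L
  for (si in seq_along(cfg$sources)) {
    hf <- raw$head_fw[[si]]
    hd <- dim(hf$out)
    nb <- det$nb_per_map[si]
    nmap <- hd[1] * hd[2] * nb
    dhead <- array(0, hd)
    for (i in seq_len(n)) {
      m <- cbind(dlogits[ofs + seq_len(nmap), , i],
                 doffsets[ofs + seq_len(nmap), , i])
      dhead[, , i, ] <- box_order_to_head(m, hd[1], hd[2], nb)
    }
    bk <- conv_backward(dhead, hf, det$params[[paste0("head", si)]]$W)
    grads[[paste0("head", si)]] <- list(W = bk$dW, b = bk$db)
    src <- cfg$sources[si]
    dacts[[src]] <- if (is.null(dacts[[src]])) bk$dx else dacts[[src]] + bk$dx
    ofs <- ofs + nmap
  }
  bb <- backbone_backward(det$params, cfg$layers, raw$fw, dacts)
  list(grads = c(grads, bb$grads), dacts = bb$dacts)
}
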
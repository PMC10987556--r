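#' Construct a tibble of bounding boxes
#'
#' Boxes are axis-aligned rectangles in continuous pixel coordinates
#' (origin top-left, x rightward, y downward), stored in center/size form:
#' horizontal center `cx`, vertical center `cy`, width `w`, height `h`.
#' This is the native annotation convention of the pipeline; every function
#' that consumes boxes expects these four columns and ignores (but preserves)
#' any others.
#'
#' @param cx,cy Box center coordinates in pixels.
#' @param w,h Box side lengths in pixels (must be positive for valid boxes).
#' @param ... Further columns carried along (labels, confidences, ids).
#' @return A tibble with columns `cx`, `cy`, `w`, `h` plus any extras.
#' @examples
#' boxes(cx = c(100, 200), cy = 50, w = 30, h = 40)
#' @export
boxes <- function(cx, cy, w, h, ...) {
  tibble::tibble(cx = as.numeric(cx), cy = as.numeric(cy),
                 w = as.numeric(w), h = as.numeric(h), ...)
}

box_cols <- c("cx", "cy", "w", "h")

check_boxes <- function(x, allow_zero = FALSE, arg = deparse(substitute(x))) {
  if (!is.data.frame(x) || !all(box_cols %in% names(x))) {
    stop(sprintf("`%s` must be a data frame with columns cx, cy, w, h", arg),
         call. = FALSE)
  }
  bad <- if (allow_zero) x$w < 0 | x$h < 0 else x$w <= 0 | x$h <= 0
  if (any(bad, na.rm = TRUE) || anyNA(x$w) || anyNA(x$h)) {
    stop(sprintf("invalid box in `%s`: width and height must be %s",
                 arg, if (allow_zero) "non-negative" else "positive"),
         call. = FALSE)
  }
  invisible(x)
}

#' Convert between center/size and corner form
#'
#' @param x A box tibble (see [boxes()]).
#' @return For `box_corners()`, the input with columns `x0`, `y0`, `x1`, `y1`
#'   appended (top-left and bottom-right corners). For `corners_to_boxes()`,
#'   a box tibble computed from corner columns.
#' @export
box_corners <- function(x) {
  check_boxes(x, allow_zero = TRUE)
  dplyr::mutate(x,
    x0 = .data$cx - .data$w / 2, y0 = .data$cy - .data$h / 2,
    x1 = .data$cx + .data$w / 2, y1 = .data$cy + .data$h / 2)
}

#' @rdname box_corners
#' @export
corners_to_boxes <- function(x) {
  stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(x)))
  boxes(cx = (x$x0 + x$x1) / 2, cy = (x$y0 + x$y1) / 2,
        w = x$x1 - x$x0, h = x$y1 - x$y0)
}

#' Intersection-over-union between two sets of boxes
#'
#' Computes the full cross matrix of IoU area ratios. IoU is symmetric,
#' bounded in \[0, 1\], 0 for disjoint rectangles and 1 only for identical
#' ones. Degenerate zero-area boxes are permitted and yield IoU 0 (the 0/0
#' case is defined as 0); negative side lengths are rejected.
#'
#' @param a,b Box tibbles with `nrow(a)` and `nrow(b)` rows.
#' @return A numeric `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @examples
#' a <- boxes(0, 0, 2, 2)
#' b <- boxes(1, 0, 2, 2)
#' box_iou(a, b) # 1/3
#' @export
box_iou <- function(a, b) {
  check_boxes(a, allow_zero = TRUE)
  check_boxes(b, allow_zero = TRUE)
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  iw <- pmax(0, outer(ax1, bx1, pmin) - outer(ax0, bx0, pmax))
  ih <- pmax(0, outer(ay1, by1, pmin) - outer(ay0, by0, pmax))
  inter <- iw * ih
  uni <- outer(a$w * a$h, b$w * b$h, `+`) - inter
  out <- ifelse(uni > 0, inter / uni, 0)
  matrix(out, nrow(a), nrow(b))
}

#' Encode a ground-truth box as offsets relative to a default box
#'
#' The detector regresses dimensionless offsets of a ground-truth box `g`
#' relative to a default (anchor) box `d`:
#' \deqn{t_{cx} = (g_{cx} - d_{cx})/d_w, \quad t_{cy} = (g_{cy} - d_{cy})/d_h,}
#' \deqn{t_w = \log(g_w/d_w), \quad t_h = \log(g_h/d_h).}
#' `decode_boxes()` is the exact inverse. Both are vectorised row-wise;
#' `g` and `d` are recycled to a common length.
#'
#' @param g Ground-truth box tibble (positive sizes; the log is undefined
#'   otherwise).
#' @param d Default box tibble (positive sizes).
#' @return A tibble with columns `t_cx`, `t_cy`, `t_w`, `t_h`.
#' @export
encode_boxes <- function(g, d) {
  check_boxes(g); check_boxes(d)
  n <- max(nrow(g), nrow(d))
  g <- g[rep_len(seq_len(nrow(g)), n), ]
  d <- d[rep_len(seq_len(nrow(d)), n), ]
  tibble::tibble(
    t_cx = (g$cx - d$cx) / d$w,
    t_cy = (g$cy - d$cy) / d$h,
    t_w = log(g$w / d$w),
    t_h = log(g$h / d$h))
}

#' @rdname encode_boxes
#' @param t Offset tibble with columns `t_cx`, `t_cy`, `t_w`, `t_h`.
#' @export
decode_boxes <- function(t, d) {
  stopifnot(all(c("t_cx", "t_cy", "t_w", "t_h") %in% names(t)))
  check_boxes(d)
  n <- max(nrow(t), nrow(d))
  t <- t[rep_len(seq_len(nrow(t)), n), ]
  d <- d[rep_len(seq_len(nrow(d)), n), ]
  boxes(cx = t$t_cx * d$w + d$cx, cy = t$t_cy * d$h + d$cy,
        w = exp(t$t_w) * d$w, h = exp(t$t_h) * d$h)
}
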
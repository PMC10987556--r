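# Shared raster helpers. Images are numeric matrices in [0, 1], row = y
# (top-down), column = x. Continuous coordinates put pixel (r, c) at
# x in [c-1, c], y in [r-1, r].

#' Bilinear resize of a grayscale raster
#'
#' @param m Numeric matrix.
#' @param out_h,out_w Output dimensions in pixels.
#' @return A `out_h` x `out_w` numeric matrix.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  # map output pixel centers to input pixel-center coordinates
  yi <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xi <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(yi), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xi), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}

# Rotate a square raster 90 degrees clockwise; point (x, y) -> (H - y, x).
rot90_cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

rot90_boxes_cw <- function(b, h) {
  cx0 <- b$cx; w0 <- b$w
  b$cx <- h - b$cy; b$cy <- cx0
  b$w <- b$h; b$h <- w0
  b
}

# Extract a crop with zero padding outside the image extent.
crop_with_pad <- function(img, ox, oy, w, h) {
  out <- matrix(0, h, w)
  r0 <- max(1L, oy + 1L); r1 <- min(nrow(img), oy + h)
  c0 <- max(1L, ox + 1L); c1 <- min(ncol(img), ox + w)
  if (r1 >= r0 && c1 >= c0) {
    out[(r0 - oy):(r1 - oy), (c0 - ox):(c1 - ox)] <- img[r0:r1, c0:c1]
  }
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
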
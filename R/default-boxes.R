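#' Default (anchor) box grid configurations
#'
#' A grid configuration lists, per source feature map, the map size in cells,
#' the primary box scale in window pixels, an extra intermediate scale, and
#' the non-unit aspect ratios. Each cell receives one square box at the
#' primary scale, one square box at the extra scale, and a pair of boxes
#' (ratio r and 1/r) for each listed aspect ratio, so a map contributes
#' `size^2 * (2 + 2 * length(aspects))` boxes.
#'
#' `grid_config_reference()` is the classic 300x300 six-map multibox layout
#' (38, 19, 10, 5, 3, 1 cells; 8732 boxes). `grid_config_tiny()` is the
#' desk-scale two-map layout used by the trainable tiny detector
#' (default 64x64 window, 8x8 and 4x4 maps, 320 boxes).
#'
#' @param window Square window side in pixels.
#' @return A list with elements `window` and `maps` (a list of per-map specs).
#' @export
grid_config_reference <- function(window = 300) {
  min_sizes <- c(30, 60, 111, 162, 213, 264)
  max_sizes <- c(60, 111, 162, 213, 264, 315)
  aspects <- list(2, c(2, 3), c(2, 3), c(2, 3), 2, 2)
  sizes <- c(38, 19, 10, 5, 3, 1)
  list(window = window, maps = purrr::pmap(
    list(sizes, min_sizes, max_sizes, aspects),
    function(s, mn, mx, ar) {
      list(size = s, scale = mn, extra_scale = sqrt(mn * mx), aspects = ar)
    }))
}

#' @rdname grid_config_reference
#' @export
grid_config_tiny <- function(window = 64) {
  s1 <- 0.30 * window
  s2 <- 0.55 * window
  s3 <- 0.90 * window
  list(window = window, maps = list(
    list(size = window / 8, scale = s1, extra_scale = sqrt(s1 * s2), aspects = 2),
    list(size = window / 16, scale = s2, extra_scale = sqrt(s2 * s3), aspects = 2)))
}

boxes_per_cell <- function(map) {
  1L + as.integer(!is.null(map$extra_scale)) + 2L * length(map$aspects)
}

#' Build the ordered default-box grid for a configuration
#'
#' Centers sit at cell centers: for a map with `size` cells over a `window`
#' pixel extent, cell (i, j) (row i, column j, both 1-based) has center
#' `((j - 1/2) * window / size, (i - 1/2) * window / size)`. Ordering is
#' deterministic: maps in configuration order, cells row-major (row outer,
#' column inner), then boxes within the cell (primary scale, extra scale,
#' then each aspect pair r, 1/r). This ordering is the contract between the
#' grid and the detector head outputs.
#'
#' @param config A grid configuration (see [grid_config_tiny()]).
#' @return A box tibble with columns `cx`, `cy`, `w`, `h`, `layer`,
#'   `cell_row`, `cell_col`, `box_in_cell`.
#' @examples
#' nrow(default_box_grid(grid_config_reference())) # 8732
#' @export
default_box_grid <- function(config) {
  if (is.null(config$maps) || length(config$maps) == 0) {
    stop("grid configuration lists no feature maps", call. = FALSE)
  }
  window <- config$window
  purrr::imap_dfr(config$maps, function(map, li) {
    size <- map$size
    stopifnot(size >= 1)
    step <- window / size
    shapes <- cell_box_shapes(map)
    cells <- tidyr::expand_grid(cell_row = seq_len(size), cell_col = seq_len(size))
    tidyr::expand_grid(cells, box_in_cell = seq_len(nrow(shapes))) |>
      dplyr::mutate(
        layer = li,
        cx = (.data$cell_col - 0.5) * step,
        cy = (.data$cell_row - 0.5) * step,
        w = shapes$w[.data$box_in_cell],
        h = shapes$h[.data$box_in_cell]) |>
      dplyr::select("cx", "cy", "w", "h", "layer",
                    "cell_row", "cell_col", "box_in_cell")
  })
}

cell_box_shapes <- function(map) {
  w <- c(map$scale, map$extra_scale)  # extra_scale may be NULL (1 box fewer)
  h <- w
  for (r in map$aspects) {
    w <- c(w, map$scale * sqrt(r), map$scale / sqrt(r))
    h <- c(h, map$scale / sqrt(r), map$scale * sqrt(r))
  }
  tibble::tibble(w = w, h = h)
}
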
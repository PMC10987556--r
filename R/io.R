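#' Write and read joint annotations as JSON
#'
#' The annotation schema stores, per image: `id`, `patient`, `timepoint`,
#' `width`, `height`, a `coordinate_scale` field recording the resize factor
#' the coordinates refer to (0.5 for half-resolution pixels), and a `joints`
#' array whose entries carry `joint_id`, `hand`, `finger`, `type`, a center/
#' size `box` (`{"cx":..,"cy":..,"w":..,"h":..}`), and the two finding flags
#' `ankylosis` and `subluxation` (`null` where a joint has no annotation
#' slot for a task). Round-trips losslessly. Legacy corner-format boxes
#' (`x0`, `y0`, `x1`, `y1`) are converted to center form with a message.
#'
#' @param dataset A `phantom_dataset` or list of annotated images.
#' @param path Output JSON path.
#' @param coordinate_scale Stated resize factor of the coordinates.
#' @return `write_annotations()` invisibly returns `path`;
#'   `read_annotations()` returns a list of annotated images (class
#'   `hand_phantom`, without rasters) suitable for [dataset_joints()].
#' @export
write_annotations <- function(dataset, path, coordinate_scale = 0.5) {
  imgs <- dataset_images(dataset)
  payload <- list(
    coordinate_scale = coordinate_scale,
    images = purrr::imap(imgs, function(im, i) {
      list(id = i, patient = im$patient_id, timepoint = im$timepoint,
           width = im$width, height = im$height,
           joints = purrr::pmap(im$joints, function(joint_id, hand, finger,
                                                    joint_type, cx, cy, w, h,
                                                    ankylosis, subluxation,
                                                    ...) {
             list(joint_id = joint_id, hand = hand, finger = finger,
                  type = joint_type,
                  box = list(cx = cx, cy = cy, w = w, h = h),
                  ankylosis = ankylosis,
                  subluxation = if (is.na(subluxation)) NULL else subluxation)
           }))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  payload <- jsonlite::read_json(path)
  if (is.null(payload$images)) stop("annotation parse error: missing field 'images'",
                                    call. = FALSE)
  imgs <- purrr::map(payload$images, function(im) {
    for (f in c("id", "width", "height", "joints")) {
      if (is.null(im[[f]])) {
        stop(sprintf("annotation parse error: missing field '%s'", f),
             call. = FALSE)
      }
    }
    joints <- purrr::map_dfr(im$joints, function(j) {
      if (!is.null(j$box)) {
        b <- j$box
        if (is.null(b$cx) && !is.null(b$x0)) {
          message("converting legacy corner-format box to center form")
          b <- as.list(corners_to_boxes(tibble::as_tibble(b)))
        }
        for (f in c("cx", "cy", "w", "h")) {
          if (is.null(b[[f]])) {
            stop(sprintf("annotation parse error: missing field 'box.%s'", f),
                 call. = FALSE)
          }
        }
      } else stop("annotation parse error: missing field 'box'", call. = FALSE)
      if (is.null(j$ankylosis)) {
        stop("annotation parse error: missing field 'ankylosis'", call. = FALSE)
      }
      tibble::tibble(
        joint_id = j$joint_id, hand = j$hand, finger = j$finger,
        joint_type = j$type, cx = b$cx, cy = b$cy, w = b$w, h = b$h,
        ankylosis = j$ankylosis,
        subluxation = if (is.null(j$subluxation)) NA else j$subluxation)
    })
    structure(list(image = NULL, joints = joints,
                   width = im$width, height = im$height,
                   patient_id = im$patient %||% NA_integer_,
                   timepoint = im$timepoint %||% NA_integer_),
              class = "hand_phantom")
  })
  imgs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a radiograph raster from PNG or TIFF
#'
#' Reads a grayscale image into a \[0, 1\] matrix (multi-channel files are
#' averaged to gray; the format is chosen by file extension). Integer-valued
#' rasters using a stated bit depth are normalised as `value / (2^bits - 1)`;
#' a 10-bit image maps 1023 to 1.0. The optional half-resolution resize uses
#' bilinear interpolation.
#'
#' @param path PNG or TIFF file path.
#' @param resize_factor Applied scale (e.g. 0.5); `NULL` to skip.
#' @return A numeric matrix in \[0, 1\].
#' @export
load_image <- function(path, resize_factor = NULL) {
  if (!file.exists(path)) stop("unreadable image file: ", path, call. = FALSE)
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- rowMeans(img, dims = 2)
  if (!is.null(resize_factor)) {
    img <- resize_bilinear(img, round(nrow(img) * resize_factor),
                           round(ncol(img) * resize_factor))
  }
  img
}

#' Write a raster to PNG or TIFF
#'
#' PNG export is 8-bit (the png writer's precision); `bits = 16` writes a
#' 16-bit TIFF preserving the phantom's full gray-level resolution, so the
#' 1024-gradation source range survives a round-trip exactly.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Output path (`.png`, or `.tif`/`.tiff` for `bits = 16`).
#' @param bits 8 or 16.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, bits = 8) {
  if (bits == 16) {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      stop("16-bit export uses TIFF; give the file a .tif extension",
           call. = FALSE)
    }
    tiff::writeTIFF(clip01(img), path, bits.per.sample = 16L)
  } else {
    png::writePNG(clip01(img), path)
  }
  invisible(path)
}

#' Write fused or single-detector predictions as JSON
#'
#' @param preds_list A list of detection tibbles (one per image) or a
#'   single tibble.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(preds_list, path) {
  if (is.data.frame(preds_list)) preds_list <- list(preds_list)
  payload <- purrr::imap(preds_list, function(pr, i) {
    list(image_id = i, detections = purrr::transpose(as.list(pr)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
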
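## File formats: 16-bit two-channel TIFF images (red, green), optional RGB PNG
## with the blue plane zeroed, 8-bit indexed PNG masks (values 0/1/2), and
## bounding-box CSV tables (0-based, half-open).

BOX_COLUMNS <- c("image_id", "class_id", "row_min", "col_min", "row_max", "col_max")

#' Write a synthetic sample to disk
#'
#' Writes `image_<id>.tif` (16-bit, two samples per pixel: red, green),
#' `mask_<id>.png` (8-bit, values 0/1/2), `boxes_<id>.csv`, and optionally
#' `image_<id>.png` (RGB with the two channels in red and green, blue zeroed).
#'
#' @param sample a `synthetic_sample` from [generate_dataset()].
#' @param directory output directory (created if missing).
#' @param rgb_png also write the RGB PNG rendering.
#' @return invisibly, named character vector of the written paths.
#' @export
write_sample <- function(sample, directory, rgb_png = TRUE) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory))
      stop("cannot create directory: ", directory)
  }
  id <- sample$image_id
  tif <- file.path(directory, sprintf("image_%04d.tif", id))
  msk <- file.path(directory, sprintf("mask_%04d.png", id))
  csv <- file.path(directory, sprintf("boxes_%04d.csv", id))
  paths <- c(image = tif, mask = msk, boxes = csv)

  ok <- tryCatch({
    tiff::writeTIFF(sample$image, tif, bits.per.sample = 16L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write TIFF: ", tif)

  write_mask_png(sample$mask, msk)

  boxes <- sample$boxes
  if (is.null(boxes) || nrow(boxes) == 0)
    boxes <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(BOX_COLUMNS)), BOX_COLUMNS))
  utils::write.csv(boxes[, BOX_COLUMNS], csv, row.names = FALSE)

  if (rgb_png) {
    png_path <- file.path(directory, sprintf("image_%04d.png", id))
    rgb <- array(0, c(dim(sample$image)[1:2], 3))
    rgb[, , 1] <- sample$image[, , 1]
    rgb[, , 2] <- sample$image[, , 2]
    png::writePNG(rgb, png_path)
    paths <- c(paths, image_png = png_path)
  }
  invisible(paths)
}

#' Read a synthetic sample back from disk
#'
#' @param directory directory written by [write_sample()].
#' @param image_id integer id.
#' @return a `synthetic_sample` (without the vesicle list, which is not
#'   serialised).
#' @export
read_sample <- function(directory, image_id) {
  tif <- file.path(directory, sprintf("image_%04d.tif", image_id))
  msk <- file.path(directory, sprintf("mask_%04d.png", image_id))
  csv <- file.path(directory, sprintf("boxes_%04d.csv", image_id))
  if (!file.exists(tif)) stop("missing image file: ", tif)
  img <- suppressWarnings(tiff::readTIFF(tif))
  boxes <- utils::read.csv(csv)
  structure(
    list(image = img, mask = read_mask_png(msk), vesicles = NULL,
         boxes = boxes, image_id = image_id),
    class = "synthetic_sample"
  )
}

#' Write a label mask as an 8-bit PNG
#'
#' Class ids are stored directly as 8-bit grey values (0, 1, 2).
#'
#' @param mask integer matrix over \{0, 1, 2\}.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  ok <- tryCatch({
    png::writePNG(mask / 255, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write mask PNG: ", path)
  invisible(path)
}

#' Read a label mask written by [write_mask_png()]
#'
#' @param path PNG path.
#' @return integer matrix.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("missing mask file: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write / read bounding-box tables
#'
#' CSV with columns `image_id, class_id, row_min, col_min, row_max, col_max`
#' (0-based, half-open intervals).
#'
#' @param boxes data frame of boxes.
#' @param path CSV path.
#' @export
write_boxes_csv <- function(boxes, path) {
  utils::write.csv(boxes[, BOX_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_csv <- function(path) {
  utils::read.csv(path)
}
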
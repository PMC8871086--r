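#' Read an RGB histology image
#'
#' Reads a PNG or TIFF file into an 8-bit RGB array. Grayscale images are
#' replicated across the three channels; an alpha channel is dropped. 16-bit
#' inputs are rescaled to 8-bit by integer division of the full ranges
#' (`v8 = v16 %/% 257`), with no gamma change: the downstream color
#' segmentation is calibrated for 8-bit sRGB. JPEG is rejected because its
#' lossy compression corrupts stain colors.
#'
#' @param path Path to a PNG or TIFF file.
#' @return An integer `H x W x 3` array with values in 0..255.
#' @seealso [write_image()], [read_mask()]
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop_fdv("input image does not exist: %s", path, class = "fiberDV_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg"))
    stop_fdv("JPEG input is rejected (lossy compression corrupts stain colors): %s",
             path, class = "fiberDV_io_error")
  x <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      stop_fdv("unsupported image format '%s' (expected PNG or TIFF): %s",
               ext, path, class = "fiberDV_io_error")
    ),
    error = function(e) {
      if (inherits(e, "fiberDV_error")) stop(e)
      stop_fdv("unreadable image file %s (%s)", path, conditionMessage(e),
               class = "fiberDV_io_error")
    }
  )
  # readers return intensities in [0,1]; recover integer codes on the 16-bit
  # scale (an 8-bit code v maps to v*257 there since 65535 = 255*257), then
  # integer-divide down to 8 bits. Exact for both 8- and 16-bit sources.
  v16 <- round(x * 65535)
  v8 <- v16 %/% 257
  if (length(dim(v8)) == 2L) dim(v8) <- c(dim(v8), 1L)
  nc <- dim(v8)[3]
  rgb <- if (nc == 1L) v8[, , c(1, 1, 1), drop = FALSE]
         else if (nc == 2L) v8[, , c(1, 1, 1), drop = FALSE]   # gray + alpha
         else v8[, , 1:3, drop = FALSE]                        # drop alpha if RGBA
  storage.mode(rgb) <- "integer"
  rgb
}

#' Write an 8-bit RGB image to PNG or TIFF
#'
#' @param image Integer `H x W x 3` array, values in 0..255.
#' @param path Output path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb_image(image)
  ext <- tolower(tools::file_ext(path))
  x <- image / 255
  switch(ext,
    png  = png::writePNG(x, path),
    tif  = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop_fdv("unsupported output format '%s' (expected PNG or TIFF): %s",
             ext, path, class = "fiberDV_io_error")
  )
  invisible(path)
}

#' Read a binary mask from a single-channel image
#'
#' Nonzero pixels are positive (inside), per the 0 = background / 255 =
#' positive convention for mask files.
#'
#' @param path Path to a single-channel PNG or TIFF.
#' @return A logical `H x W` matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  img[, , 1] > 0
}

#' Write a binary mask as an 8-bit single-channel PNG (0 / 255)
#'
#' @param mask Logical `H x W` matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- check_mask(mask)
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Rectangular region of interest
#'
#' Coordinates are 0-based, row-major and half-open: the box covers rows
#' `row0 .. row1-1` and columns `col0 .. col1-1`.
#'
#' @param row0,col0 Top-left corner (inclusive), 0-based.
#' @param row1,col1 Bottom-right corner (exclusive).
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(row0, col0, row1, col1) {
  b <- list(row0 = as.integer(row0), col0 = as.integer(col0),
            row1 = as.integer(row1), col1 = as.integer(col1))
  if (any(vapply(b, is.na, logical(1))) || b$row0 < 0 || b$col0 < 0 ||
      b$row0 >= b$row1 || b$col0 >= b$col1)
    stop_fdv("invalid ROI box [%s,%s) x [%s,%s): need 0 <= row0 < row1, 0 <= col0 < col1",
             b$row0, b$row1, b$col0, b$col1, class = "fiberDV_bounds_error")
  structure(b, class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box rows [%d,%d) cols [%d,%d): %d x %d px>\n",
              x$row0, x$row1, x$col0, x$col1,
              x$row1 - x$row0, x$col1 - x$col0))
  invisible(x)
}

#' Crop a rectangular ROI out of an image or mask
#'
#' @param image An `H x W x 3` RGB array or an `H x W` matrix/mask.
#' @param box A [roi_box()] lying within the image frame.
#' @return The cropped image, same type as the input; the source is unchanged.
#' @export
crop_roi <- function(image, box) {
  stopifnot(inherits(box, "roi_box"))
  d <- dim(image)
  if (box$row1 > d[1] || box$col1 > d[2])
    stop_fdv("ROI box rows [%d,%d) cols [%d,%d) exceeds the %d x %d image frame",
             box$row0, box$row1, box$col0, box$col1, d[1], d[2],
             class = "fiberDV_bounds_error")
  rows <- (box$row0 + 1L):box$row1
  cols <- (box$col0 + 1L):box$col1
  if (length(d) == 3L) image[rows, cols, , drop = FALSE]
  else image[rows, cols, drop = FALSE]
}

#' Measure the area of a binary mask in pixels
#'
#' Counts positive pixels; the count is invariant under any rotation or
#' reflection of the mask.
#'
#' @param mask Logical `H x W` matrix.
#' @return Non-negative integer pixel count.
#' @export
measure_area <- function(mask) {
  mask <- check_mask(mask)
  sum(mask, na.rm = TRUE)
}
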
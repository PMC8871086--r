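#' @noRd
stop_fdv <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fiberDV_error")))
}

#' Run code with a temporary, restored RNG state
#' @noRd
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
}

#' @noRd
check_rgb_image <- function(image) {
  if (!is_rgb_image(image))
    stop_fdv("expected an H x W x 3 RGB array, got dimensions [%s]",
             paste(dim(image), collapse = ", "), class = "fiberDV_type_error")
  if (min(image) < 0 || max(image) > 255)
    stop_fdv("RGB values must lie in [0, 255]", class = "fiberDV_type_error")
  invisible(image)
}

#' @noRd
check_mask <- function(mask) {
  if (!is.matrix(mask))
    stop_fdv("expected a logical H x W matrix mask", class = "fiberDV_type_error")
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
  }
  mask
}

#' @noRd
same_frame <- function(a, b) identical(dim(a)[1:2], dim(b)[1:2])
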
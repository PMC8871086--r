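#' Airy-disk convolution kernel
#'
#' Builds a `(2r+1) x (2r+1)` kernel whose weight at radial offset `rho`
#' pixels is proportional to the airy diffraction pattern `[2 J1(x) / x]^2`
#' with `x = 3.8317 * rho / radius_px`, so the central weight is the maximum
#' and the first zero of the pattern falls exactly at `rho = radius_px`. The
#' pattern is truncated at that first zero and normalized to unit sum, giving
#' a smooth, rotationally symmetric local-averaging window.
#'
#' @param radius_px Kernel radius in pixels (first airy zero), >= 1.
#' @return An `airy_kernel`: numeric `(2r+1) x (2r+1)` matrix with attribute
#'   `radius_px`; weights sum to 1.
#' @export
airy_kernel <- function(radius_px) {
  radius_px <- as.integer(radius_px)
  if (is.na(radius_px) || radius_px < 1L)
    stop_fdv("airy kernel radius must be a positive integer (got %s)",
             radius_px, class = "fiberDV_param_error")
  off <- -radius_px:radius_px
  rho <- sqrt(outer(off^2, off^2, "+"))
  x <- 3.8317 * rho / radius_px
  w <- ifelse(x == 0, 1, (2 * besselJ(x, 1) / x)^2)
  w[rho >= radius_px] <- 0          # truncate at the first zero
  w <- w / sum(w)
  structure(w, radius_px = radius_px, class = c("airy_kernel", "matrix", "array"))
}

#' @export
print.airy_kernel <- function(x, ...) {
  r <- attr(x, "radius_px")
  cat(sprintf("<airy_kernel radius %d px (%d x %d), center weight %.4g>\n",
              r, nrow(x), ncol(x), x[r + 1, r + 1]))
  invisible(x)
}

# 2-D convolution with reflect padding (edge row/column duplicated into the
# pad, scipy "reflect" convention), so that convolving a constant image
# reproduces the constant exactly at every pixel including borders.
# FFT-backed via EBImage::filter2 on the padded matrix; values within 1e-9 of
# 0 or 1 are snapped to absorb FFT rounding.
convolve_reflect <- function(x, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  if (2L * r + 1L > min(h, w))
    stop_fdv("kernel (%d x %d) is larger than the %d x %d image",
             nrow(kernel), ncol(kernel), h, w, class = "fiberDV_param_error")
  ri <- c(r:1, 1:h, h:(h - r + 1L))
  ci <- c(r:1, 1:w, w:(w - r + 1L))
  padded <- x[ri, ci]
  k <- matrix(as.numeric(kernel), nrow(kernel))   # plain matrix for filter2
  out <- EBImage::filter2(padded, k, boundary = "circular")
  out <- out[(r + 1L):(r + h), (r + 1L):(r + w), drop = FALSE]
  out[abs(out) < 1e-9] <- 0
  out[abs(out - 1) < 1e-9] <- 1
  out
}

#' Collagen density map
#'
#' Convolves the binary collagen mask (CAS) with an airy-disk kernel,
#' yielding at each pixel the kernel-weighted local fraction of
#' collagen-positive pixels, `m` in [0, 1]. Borders use reflect padding, so
#' an all-positive mask maps to exactly 1 everywhere and an all-negative mask
#' to 0.
#'
#' @param cas Logical `H x W` collagen mask.
#' @param kernel An [airy_kernel()] (default radius 16 px).
#' @return A `density_map`: numeric `H x W` matrix `m` in [0, 1] with the
#'   kernel radius in attribute `radius_px`.
#' @export
collagen_density <- function(cas, kernel = airy_kernel(16L)) {
  cas <- check_mask(cas)
  stopifnot(inherits(kernel, "airy_kernel"))
  m <- convolve_reflect(cas * 1.0, kernel)
  m <- pmin(pmax(m, 0), 1)
  structure(m, radius_px = attr(kernel, "radius_px"),
            class = c("density_map", "matrix", "array"))
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map %d x %d, m in [%.3f, %.3f], mean %.3f>\n",
              nrow(x), ncol(x), min(x), max(x), mean(x)))
  invisible(x)
}
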
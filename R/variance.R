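#' Directional variance map V = 1 - R/m
#'
#' Axial orientations are doubled so that a fiber at theta and theta + 180
#' degrees contribute identically, mapped to unit vectors
#' (cos 2*theta, sin 2*theta) on valid pixels (zero elsewhere), and both
#' components are convolved with the airy-disk kernel. The resultant
#' magnitude `R = sqrt(Xc^2 + Yc^2)` is compared with the local density `m`
#' of the same validity mask under the same kernel, giving the directional
#' variance `V = 1 - R/m`: 0 where all local fibers share one axis, 1 where
#' orientations are isotropic (or exactly cancel, e.g. an equal orthogonal
#' mix). Using the orientation-validity mask for the denominator makes
#' `0 <= R <= m` hold pointwise, so `V` lies in [0, 1] by construction; it is
#' additionally clamped against floating-point overshoot below 1e-9. Pixels
#' with `m = 0` (no oriented fibers under the kernel) are invalid, never an
#' error.
#'
#' @param field An `orientation_field` from [estimate_orientation()].
#' @param kernel An [airy_kernel()] (default radius 16 px).
#' @param density Optional `density_map` sharing the frame; when supplied,
#'   pixels where it is 0 are also marked invalid.
#' @return A `variance_map`: list with `V` (`H x W`, `NA` where invalid), `R`,
#'   `m` (density of the validity mask), `valid` (logical mask).
#' @export
directional_variance <- function(field, kernel = airy_kernel(16L), density = NULL) {
  stopifnot(inherits(field, "orientation_field"), inherits(kernel, "airy_kernel"))
  if (!is.null(density) && !same_frame(field$theta, density))
    stop_fdv("orientation field (%d x %d) and density map (%d x %d) frames differ",
             nrow(field$theta), ncol(field$theta), nrow(density), ncol(density),
             class = "fiberDV_dim_error")
  th2 <- 2 * field$theta * pi / 180
  X <- ifelse(field$valid, cos(th2), 0)
  Y <- ifelse(field$valid, sin(th2), 0)
  Xc <- convolve_reflect(X, kernel)
  Yc <- convolve_reflect(Y, kernel)
  m <- convolve_reflect(field$valid * 1.0, kernel)
  m <- pmin(pmax(m, 0), 1)
  R <- sqrt(Xc^2 + Yc^2)
  R <- pmin(R, m)                       # triangle inequality, FFT-noise safe
  valid <- m > 0
  if (!is.null(density)) valid <- valid & density > 0
  V <- matrix(NA_real_, nrow(m), ncol(m))
  V[valid] <- pmin(pmax(1 - R[valid] / m[valid], 0), 1)
  structure(list(V = V, R = R, m = m, valid = valid),
            class = "variance_map")
}

#' @export
print.variance_map <- function(x, ...) {
  cat(sprintf("<variance_map %d x %d, %.1f%% valid, mean V %.3f>\n",
              nrow(x$V), ncol(x$V), 100 * mean(x$valid),
              mean(x$V[x$valid])))
  invisible(x)
}
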
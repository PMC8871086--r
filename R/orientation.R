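# Shift a matrix so out[i, j] = m[i + dr, j + dc], zero-filled outside.
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  r0 <- max(1L, 1L - dr); r1 <- min(h, h - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(w, w - dc)
  if (r0 <= r1 && c0 <= c1)
    out[r0:r1, c0:c1] <- m[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)]
  out
}

# Distinct integer pixel offsets of a centered line probe at `theta_deg`,
# unit parameter steps t = -w..w, nearest-pixel rounding. Angles follow the
# mathematical convention (counter-clockwise from the +x / column axis, y up),
# so the row offset is -t*sin(theta).
line_offsets <- function(theta_deg, window_radius) {
  t <- -window_radius:window_radius
  th <- theta_deg * pi / 180
  off <- unique(cbind(dr = round(-t * sin(th)), dc = round(t * cos(th))))
  off
}

#' Pixel-wise axial fiber orientation by directional line sampling
#'
#' For every collagen-positive pixel, the mask is sampled along a centered
#' line probe of half-length `window_radius` at each candidate angle
#' `k * 180 / n_angles` (nearest-pixel sampling); an angle's score is the
#' number of distinct collagen-positive pixels the probe passes through. The
#' estimated orientation is the arg-max angle (ties go to the smallest
#' angle). A pixel whose best score does not exceed 1 -- no support beyond
#' the pixel itself, e.g. an isolated point -- is marked invalid. Angles are
#' axial: theta and theta + 180 degrees are the same fiber direction.
#'
#' @param cas Logical `H x W` collagen mask.
#' @param window_radius Probe half-length in pixels, >= 2 (default 8).
#' @param n_angles Number of candidate angles over [0, 180), >= 4
#'   (default 18, i.e. 10-degree steps).
#' @return An `orientation_field`: list with `theta` (`H x W` matrix of
#'   degrees in [0, 180), `NA` where invalid), `valid` (logical mask),
#'   `score` (best line score), `n_angles`, `window_radius`.
#' @export
estimate_orientation <- function(cas, window_radius = 8L, n_angles = 18L) {
  cas <- check_mask(cas)
  window_radius <- as.integer(window_radius)
  n_angles <- as.integer(n_angles)
  if (window_radius < 2L)
    stop_fdv("window_radius must be >= 2 (got %d)", window_radius,
             class = "fiberDV_param_error")
  if (n_angles < 4L)
    stop_fdv("n_angles must be >= 4 (got %d)", n_angles,
             class = "fiberDV_param_error")
  angles <- (seq_len(n_angles) - 1L) * 180 / n_angles
  m <- cas * 1.0
  best_score <- matrix(-Inf, nrow(cas), ncol(cas))
  best_theta <- matrix(NA_real_, nrow(cas), ncol(cas))
  for (th in angles) {
    off <- line_offsets(th, window_radius)
    score <- matrix(0, nrow(cas), ncol(cas))
    for (i in seq_len(nrow(off)))
      score <- score + shift_mat(m, off[i, 1L], off[i, 2L])
    better <- score > best_score            # strict: ties keep smaller angle
    best_theta[better] <- th
    best_score[better] <- score[better]
  }
  valid <- cas & best_score > 1
  theta <- ifelse(valid, best_theta, NA_real_)
  structure(list(theta = theta, valid = valid, score = best_score,
                 n_angles = n_angles, window_radius = window_radius),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field %d x %d, %d angles (%.1f deg step), %.1f%% valid>\n",
              nrow(x$theta), ncol(x$theta), x$n_angles, 180 / x$n_angles,
              100 * mean(x$valid)))
  invisible(x)
}
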
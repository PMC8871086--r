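# Best-Fisher rejection sampler for the von Mises distribution on [0, 2*pi).
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) break
    }
    out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
  }
  out
}

#' Sample axial fiber angles
#'
#' Draws axial angles (degrees in [0, 180)) from the standard axial von Mises
#' construction: the doubled angle `2*theta` follows a von Mises distribution
#' with mean `2*mean_deg` and concentration `kappa`; `kappa = 0` gives the
#' uniform (isotropic) axial distribution. `kappa` thus directly controls the
#' expected directional variance of a field of such fibers.
#'
#' @param n Number of angles.
#' @param mean_deg Mean axial direction in degrees.
#' @param kappa Von Mises concentration on the doubled angles, >= 0.
#' @return Numeric vector of angles in [0, 180).
#' @export
sample_axial_angles <- function(n, mean_deg, kappa) {
  if (kappa < 0)
    stop_fdv("kappa must be >= 0 (got %g)", kappa, class = "fiberDV_param_error")
  phi <- rvonmises(n, 2 * mean_deg * pi / 180, kappa)
  (phi * 180 / pi / 2) %% 180
}

#' Specification for a synthetic H&E dermis image
#'
#' Describes a synthetic scene emulating H&E-stained dermis: a near-white
#' background, eosin-pink collagen fibers drawn as thick anti-aliased
#' segments with axial von Mises orientations, and hematoxylin-purple
#' ellipses for nuclei and skin appendages (glands, hair follicles), plus
#' per-channel Gaussian noise. The three colors must be pairwise at least 15
#' units apart in (a*, b*) so the color segmentation problem is well posed.
#'
#' @param height,width Image size in pixels.
#' @param fiber_count Number of collagen fiber segments.
#' @param fiber_width_px Fiber stroke width in pixels.
#' @param fiber_length_px Fiber segment length in pixels (default
#'   `0.6 * min(height, width)`).
#' @param orientation_mean_deg Mean axial fiber direction, degrees in
#'   [0, 180).
#' @param orientation_kappa Von Mises concentration on doubled angles
#'   (0 = isotropic).
#' @param ellipse_count Number of hematoxylin structures (nuclei and, with
#'   probability `gland_fraction`, large gland/follicle ellipses).
#' @param gland_fraction Fraction of ellipses drawn as large appendage
#'   structures rather than small nuclei.
#' @param colors List with sRGB triplets `background`, `collagen`,
#'   `structure`.
#' @param noise_sd Per-channel Gaussian noise standard deviation (8-bit
#'   scale).
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 500L, width = 500L,
                           fiber_count = 150L, fiber_width_px = 3,
                           fiber_length_px = NULL,
                           orientation_mean_deg = 90, orientation_kappa = 0,
                           ellipse_count = 150L, gland_fraction = 0.15,
                           colors = list(background = c(247, 243, 246),
                                         collagen = c(228, 110, 160),
                                         structure = c(70, 32, 110)),
                           noise_sd = 4, seed = 0L) {
  if (is.null(fiber_length_px)) fiber_length_px <- 0.6 * min(height, width)
  spec <- structure(list(
    height = as.integer(height), width = as.integer(width),
    fiber_count = as.integer(fiber_count),
    fiber_width_px = fiber_width_px, fiber_length_px = fiber_length_px,
    orientation_mean_deg = orientation_mean_deg %% 180,
    orientation_kappa = orientation_kappa,
    ellipse_count = as.integer(ellipse_count),
    gland_fraction = gland_fraction,
    colors = colors, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_spec")
  if (spec$height < 1L || spec$width < 1L || spec$fiber_count < 0L ||
      spec$ellipse_count < 0L || spec$orientation_kappa < 0 || spec$noise_sd < 0)
    stop_fdv("invalid synthetic spec (negative counts, kappa or noise)",
             class = "fiberDV_param_error")
  ab <- vapply(colors[c("background", "collagen", "structure")], function(col) {
    img <- array(as.numeric(col), c(1, 1, 3))
    lab <- rgb_to_lab(img)
    c(lab$a[1, 1], lab$b[1, 1])
  }, numeric(2))
  dmin <- min(stats::dist(t(ab)))
  if (dmin < 15)
    stop_fdv("spec colors are only %.1f units apart in (a*, b*); need >= 15 for the segmentation to be testable",
             dmin, class = "fiberDV_param_error")
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec %d x %d: %d fibers (w %.1f px, mean %.0f deg, kappa %.1f), %d ellipses, seed %d>\n",
    x$height, x$width, x$fiber_count, x$fiber_width_px,
    x$orientation_mean_deg, x$orientation_kappa, x$ellipse_count, x$seed))
  invisible(x)
}

# Blend an anti-aliased shape into the scene. `alpha` is computed on the
# bounding-box subgrid; class/theta ground truth uses alpha >= 0.5
# ("last drawn wins").
blend_shape <- function(scene, rows, cols, alpha, col, class_id, theta = NA_real_) {
  for (ch in 1:3) {
    sub <- scene$rgb[[ch]][rows, cols, drop = FALSE]
    scene$rgb[[ch]][rows, cols] <- alpha * col[ch] + (1 - alpha) * sub
  }
  hit <- alpha >= 0.5
  cm <- scene$class_map[rows, cols, drop = FALSE]
  tm <- scene$theta_map[rows, cols, drop = FALSE]
  cm[hit] <- class_id
  tm[hit] <- theta
  scene$class_map[rows, cols] <- cm
  scene$theta_map[rows, cols] <- tm
  scene
}

draw_fiber <- function(scene, r0, c0, theta_deg, len, width, col) {
  th <- theta_deg * pi / 180
  ux <- cos(th); uy <- sin(th)           # y points up (decreasing row)
  half <- len / 2
  pad <- width / 2 + 1.5
  rows <- max(1L, floor(r0 - half * abs(uy) - pad)):
          min(scene$h, ceiling(r0 + half * abs(uy) + pad))
  cols <- max(1L, floor(c0 - half * abs(ux) - pad)):
          min(scene$w, ceiling(c0 + half * abs(ux) + pad))
  X <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(-(rows - r0), length(rows), length(cols))
  tproj <- pmin(pmax(X * ux + Y * uy, -half), half)
  dist <- sqrt((X - tproj * ux)^2 + (Y - tproj * uy)^2)
  alpha <- pmin(1, pmax(0, (width / 2 + 0.5) - dist))
  blend_shape(scene, rows, cols, alpha, col, 1L, theta_deg)
}

draw_ellipse <- function(scene, r0, c0, a, b, phi, col) {
  pad <- max(a, b) + 1.5
  rows <- max(1L, floor(r0 - pad)):min(scene$h, ceiling(r0 + pad))
  cols <- max(1L, floor(c0 - pad)):min(scene$w, ceiling(c0 + pad))
  X <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(-(rows - r0), length(rows), length(cols))
  xr <- X * cos(phi) + Y * sin(phi)
  yr <- -X * sin(phi) + Y * cos(phi)
  d <- sqrt((xr / a)^2 + (yr / b)^2)
  alpha <- pmin(1, pmax(0, (1 - d) * min(a, b) + 0.5))
  blend_shape(scene, rows, cols, alpha, col, 2L)
}

#' Generate a synthetic H&E dermis image with ground truth
#'
#' Renders the scene described by a [synthetic_spec()]: background fill, then
#' `fiber_count` anti-aliased collagen segments with per-fiber angles drawn
#' from the axial von Mises distribution, then `ellipse_count` hematoxylin
#' ellipses on top, then clamped Gaussian noise. Ground truth records, for
#' every pixel, the last-drawn class (0 background, 1 collagen, 2 structure)
#' and, on collagen pixels, the drawing angle. Deterministic given the spec's
#' seed.
#'
#' For a "mixed" composite spec (see [preset()]) the left and right halves
#' are rendered independently and stitched.
#'
#' @param spec A `synthetic_spec` (or composite spec from
#'   `preset("mixed")`).
#' @return List with `image` (integer `H x W x 3`, 0..255) and `truth`: list
#'   of `class_map` (integer matrix in 0..2), `theta_map` (degrees, `NA` off
#'   collagen), `fiber_angles` (vector of drawn per-fiber angles), and the
#'   `spec`.
#' @export
generate_image <- function(spec) {
  if (!is.null(spec$composite)) {
    left <- generate_image(spec$composite$left)
    right <- generate_image(spec$composite$right)
    img <- array(0L, c(dim(left$image)[1],
                       dim(left$image)[2] + dim(right$image)[2], 3L))
    img[, seq_len(dim(left$image)[2]), ] <- left$image
    img[, dim(left$image)[2] + seq_len(dim(right$image)[2]), ] <- right$image
    storage.mode(img) <- "integer"
    return(list(
      image = img,
      truth = list(class_map = cbind(left$truth$class_map, right$truth$class_map),
                   theta_map = cbind(left$truth$theta_map, right$truth$theta_map),
                   fiber_angles = c(left$truth$fiber_angles,
                                    right$truth$fiber_angles),
                   spec = spec)
    ))
  }
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height; w <- spec$width
  scene <- list(
    h = h, w = w,
    rgb = lapply(spec$colors$background, function(v) matrix(v, h, w)),
    class_map = matrix(0L, h, w),
    theta_map = matrix(NA_real_, h, w)
  )
  angles <- numeric(0)
  local_seed(spec$seed, {
    if (spec$fiber_count > 0L) {
      angles <- sample_axial_angles(spec$fiber_count, spec$orientation_mean_deg,
                                     spec$orientation_kappa)
      r0s <- stats::runif(spec$fiber_count, 1, h)
      c0s <- stats::runif(spec$fiber_count, 1, w)
      for (i in seq_len(spec$fiber_count))
        scene <- draw_fiber(scene, r0s[i], c0s[i], angles[i],
                             spec$fiber_length_px, spec$fiber_width_px,
                             spec$colors$collagen)
    }
    if (spec$ellipse_count > 0L) {
      big <- stats::runif(spec$ellipse_count) < spec$gland_fraction
      for (i in seq_len(spec$ellipse_count)) {
        a <- if (big[i]) stats::runif(1, 12, 28) else stats::runif(1, 2.5, 5)
        b <- a * stats::runif(1, 0.55, 0.95)
        scene <- draw_ellipse(scene, stats::runif(1, 1, h), stats::runif(1, 1, w),
                               a, b, stats::runif(1, 0, pi),
                               spec$colors$structure)
      }
    }
    if (spec$noise_sd > 0) {
      for (ch in 1:3)
        scene$rgb[[ch]] <- scene$rgb[[ch]] +
          matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
  })
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- pmin(pmax(round(scene$rgb[[ch]]), 0), 255)
  storage.mode(img) <- "integer"
  list(image = img,
       truth = list(class_map = scene$class_map, theta_map = scene$theta_map,
                    fiber_angles = angles, spec = spec))
}

#' Preset synthetic tissue specs: normal, scar, mixed
#'
#' `"normal"` dermis: isotropic fibers (`kappa = 0`) at roughly 50% coverage
#' with nuclei plus large gland/follicle ellipses. `"scar"`: dense
#' (roughly 90% coverage), strongly aligned fibers (`kappa = 8`) running
#' horizontally, the orientation scar collagen bundles take parallel to the
#' epidermis; skin appendages are absent but small nuclei persist throughout
#' the tissue. `"mixed"`: left half scar, right half normal, rendered as a
#' composite. Fiber counts are derived from the target coverage via the
#' Poisson-coverage relation `n = -log(1 - coverage) * H*W / fiber_area`.
#'
#' @param name One of `"normal"`, `"scar"`, `"mixed"`.
#' @param seed Integer RNG seed.
#' @param height,width Image size in pixels.
#' @return A `synthetic_spec` (for `"mixed"`, a composite spec whose
#'   `composite$left`/`composite$right` are the half-frame specs).
#' @export
preset <- function(name, seed = 0L, height = 500L, width = 500L) {
  name <- match.arg(name, c("normal", "scar", "mixed"))
  fiber_w <- 6
  fiber_len <- 0.6 * min(height, width)
  count_for <- function(coverage)
    as.integer(ceiling(-log(1 - coverage) * height * width / (fiber_len * fiber_w)))
  if (name == "normal") {
    synthetic_spec(height = height, width = width,
                   fiber_count = count_for(0.5), fiber_width_px = fiber_w,
                   fiber_length_px = fiber_len,
                   orientation_mean_deg = 90, orientation_kappa = 0,
                   ellipse_count = round(7e-4 * height * width),
                   gland_fraction = 0.15, seed = seed)
  } else if (name == "scar") {
    synthetic_spec(height = height, width = width,
                   fiber_count = count_for(0.9), fiber_width_px = fiber_w,
                   fiber_length_px = fiber_len,
                   orientation_mean_deg = 0, orientation_kappa = 8,
                   ellipse_count = round(6e-4 * height * width),
                   gland_fraction = 0, seed = seed)
  } else {
    wl <- as.integer(floor(width / 2))
    spec <- structure(list(
      height = as.integer(height), width = as.integer(width),
      composite = list(left = preset("scar", seed = seed,
                                     height = height, width = wl),
                       right = preset("normal", seed = seed + 1L,
                                      height = height, width = width - wl)),
      seed = as.integer(seed)
    ), class = "synthetic_spec")
    spec
  }
}

#' Rotate an image by a right angle
#'
#' @param image `H x W x 3` array or `H x W` matrix.
#' @param angle Degrees, a multiple of 90 (counter-clockwise).
#' @return Rotated image; right-angle rotations are lossless.
#' @export
rotate_image <- function(image, angle) {
  if (angle %% 90 != 0)
    stop_fdv("rotation by %g deg needs interpolation, which is not supported; use multiples of 90",
             angle, class = "fiberDV_param_error")
  k <- (as.integer(angle / 90)) %% 4L
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]   # 90 deg CCW
  rot_plane <- function(m, k) {
    for (i in seq_len(k)) m <- rot90(m)
    m
  }
  if (k == 0L) return(image)
  if (is.matrix(image)) return(rot_plane(image, k))
  planes <- lapply(1:3, function(ch) rot_plane(image[, , ch], k))
  out <- array(0, c(dim(planes[[1]]), 3L))
  for (ch in 1:3) out[, , ch] <- planes[[ch]]
  storage.mode(out) <- storage.mode(image)
  out
}

#' Rotation augmentation of an image set
#'
#' Produces every image at every requested angle, image-major order (all
#' angles of image 1, then image 2, ...). With the default right-angle set
#' `{0, 90, 180, 270}` the augmentation is lossless and quadruples the set
#' (93 slides become 372).
#'
#' @param images List of images (arrays or matrices).
#' @param angles Numeric vector of angles in degrees, multiples of 90;
#'   default `c(0, 90, 180, 270)`.
#' @return List of `length(images) * length(angles)` images.
#' @export
rotate_augment <- function(images, angles = c(0, 90, 180, 270)) {
  if (length(angles) == 0)
    stop_fdv("angles must be non-empty", class = "fiberDV_param_error")
  if (any(angles %% 90 != 0))
    stop_fdv("non-right-angle rotation requested (%s); interpolation is not supported",
             paste(angles[angles %% 90 != 0], collapse = ", "),
             class = "fiberDV_param_error")
  out <- vector("list", length(images) * length(angles))
  i <- 1L
  for (img in images) {
    for (ang in angles) {
      out[[i]] <- rotate_image(img, ang)
      i <- i + 1L
    }
  }
  out
}

#' Random train / validate / test split
#'
#' Validate and test sizes are floors of their fractions; the remainder goes
#' to train -- the rounding rule under which 372 items at fractions
#' (0.64, 0.16, 0.20) split into 239 / 59 / 74. Assignment is a seeded
#' shuffle; the three 1-based index vectors are disjoint and cover
#' `1..n_items`.
#'
#' @param n_items Number of items, >= 3.
#' @param fractions Length-3 numeric `(train, validate, test)` summing to 1.
#' @param seed Integer RNG seed.
#' @return List with integer vectors `train`, `validate`, `test`.
#' @export
split_dataset <- function(n_items, fractions = c(0.64, 0.16, 0.20), seed = 0L) {
  n_items <- as.integer(n_items)
  if (n_items < 3L)
    stop_fdv("need n_items >= 3 (got %d)", n_items, class = "fiberDV_param_error")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop_fdv("fractions must be 3 positive numbers summing to 1",
             class = "fiberDV_param_error")
  n_val <- as.integer(floor(n_items * fractions[2]))
  n_test <- as.integer(floor(n_items * fractions[3]))
  n_train <- n_items - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop_fdv("split produces an empty partition (%d/%d/%d)", n_train, n_val, n_test,
             class = "fiberDV_param_error")
  perm <- local_seed(seed, sample.int(n_items))
  list(train = perm[seq_len(n_train)],
       validate = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}
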
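# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: scalar loops and textbook formulas only.

# Scalar sRGB (D65) -> CIE L*a*b*, straight from the CIE definitions.
oracle_lab_pixel <- function(r, g, b) {
  v <- c(r, g, b) / 255
  lin <- numeric(3)
  for (i in 1:3) {
    lin[i] <- if (v[i] <= 0.04045) v[i] / 12.92 else ((v[i] + 0.055) / 1.055)^2.4
  }
  X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
  Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
  Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  wn <- c(0.95047, 1, 1.08883)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / wn[1]); fy <- f(Y / wn[2]); fz <- f(Z / wn[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Order-1 Bessel function of the first kind by its power series.
oracle_j1_series <- function(x, terms = 40) {
  s <- 0
  for (m in 0:(terms - 1)) {
    s <- s + (-1)^m / (factorial(m) * factorial(m + 1)) * (x / 2)^(2 * m + 1)
  }
  s
}

# Direct per-pixel weighted summation of a mask under a kernel with
# reflect (edge-duplicating) padding.
oracle_density <- function(mask, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  ri <- c(r:1, 1:h, h:(h - r + 1L))
  ci <- c(r:1, 1:w, w:(w - r + 1L))
  padded <- (mask * 1.0)[ri, ci]
  out <- matrix(0, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      out[i, j] <- sum(kernel * padded[i:(i + 2 * r), j:(j + 2 * r)])
    }
  }
  out
}

# Plain Lloyd iteration from given starting centers (clustering oracle).
oracle_lloyd <- function(x, centers, iters = 100) {
  for (it in seq_len(iters)) {
    d2 <- sapply(seq_len(nrow(centers)), function(j)
      rowSums(sweep(x, 2, centers[j, ])^2))
    lab <- max.col(-d2)
    newc <- centers
    for (j in seq_len(nrow(centers)))
      if (any(lab == j)) newc[j, ] <- colMeans(x[lab == j, , drop = FALSE])
    if (max(abs(newc - centers)) < 1e-12) break
    centers <- newc
  }
  list(labels = lab, centers = centers)
}

# Axial circular distance in degrees (angles mod 180).
circ_dist_axial <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Axial circular mean in degrees via the doubled-angle resultant.
circ_mean_axial <- function(theta_deg) {
  phi <- 2 * theta_deg * pi / 180
  (atan2(mean(sin(phi)), mean(cos(phi))) * 180 / pi / 2) %% 180
}

# Solid-color RGB array.
solid_image <- function(h, w, col) {
  img <- array(rep(as.integer(col), each = h * w), c(h, w, 3L))
  storage.mode(img) <- "integer"
  img
}

# Vertical three-band image of the given colors.
three_band_image <- function(h, w, cols) {
  img <- array(0L, c(h, w, 3L))
  bands <- split(seq_len(w), cut(seq_len(w), 3, labels = FALSE))
  for (b in 1:3)
    for (ch in 1:3) img[, bands[[b]], ch] <- cols[[b]][ch]
  storage.mode(img) <- "integer"
  img
}

# Binary mask of a straight fiber through the image center at `theta_deg`
# (axial, math convention: counter-clockwise from +x, y up), given stroke
# width and optional half-length.
make_fiber_mask <- function(h, w, theta_deg, width = 3, half_len = Inf) {
  th <- theta_deg * pi / 180
  r0 <- (h + 1) / 2; c0 <- (w + 1) / 2
  X <- matrix(rep(seq_len(w), each = h) - c0, h, w)
  Y <- matrix(-(seq_len(h) - r0), h, w)
  dist_perp <- abs(X * sin(th) - Y * cos(th))
  tproj <- X * cos(th) + Y * sin(th)
  dist_perp <= width / 2 & abs(tproj) <= half_len
}

# Orientation field constructed directly (bypasses estimation).
make_field <- function(theta, valid = !is.na(theta)) {
  theta[!valid] <- NA_real_
  structure(list(theta = theta, valid = valid, score = NULL,
                 n_angles = NA_integer_, window_radius = NA_integer_),
            class = "orientation_field")
}

# Pixel accuracy of a segmentation against a ground-truth class map
# (0 = background, 1 = collagen, 2 = structure) under the role mapping.
role_accuracy <- function(seg, class_map) {
  mean((seg$bs & class_map == 0) | (seg$cas & class_map == 1) |
         (seg$fs & class_map == 2))
}

# Pixel accuracy under the best bijection between masks and classes
# (permutation-invariant clustering accuracy).
best_perm_accuracy <- function(seg, class_map) {
  masks <- list(seg$bs, seg$cas, seg$fs)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  best <- 0
  for (p in perms) {
    acc <- mean(masks[[p[1]]] & class_map == 0 |
                  masks[[p[2]]] & class_map == 1 |
                  masks[[p[3]]] & class_map == 2)
    best <- max(best, acc)
  }
  best
}
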
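#' Convert an 8-bit sRGB image to CIE L*a*b*
#'
#' Applies the standard sRGB piecewise transfer function, the sRGB (D65)
#' RGB-to-XYZ matrix, and the CIE 1976 L*a*b* formulas with the D65 reference
#' white (Xn, Yn, Zn) = (0.95047, 1, 1.08883). For H&E images essentially all
#' stain chromaticity ends up in the a* (green-red) and b* (blue-yellow)
#' layers; L* carries lightness.
#'
#' @param image Integer `H x W x 3` sRGB array, values in 0..255.
#' @return A `lab_image`: list of `H x W` matrices `L` (0..100), `a`, `b`.
#' @export
rgb_to_lab <- function(image) {
  check_rgb_image(image)
  d <- dim(image)
  v <- matrix(as.numeric(image), ncol = 3L) / 255   # columns R,G,B
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wn <- c(0.95047, 1, 1.08883)
  t3 <- sweep(xyz, 2, wn, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  out <- list(
    L = matrix(116 * f[, 2] - 16, d[1], d[2]),
    a = matrix(500 * (f[, 1] - f[, 2]), d[1], d[2]),
    b = matrix(200 * (f[, 2] - f[, 3]), d[1], d[2])
  )
  structure(out, class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf("<lab_image %d x %d, L* in [%.1f, %.1f]>\n",
              nrow(x$L), ncol(x$L), min(x$L), max(x$L)))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each next
# center drawn with probability proportional to squared distance to the
# nearest chosen center. Ties in the nearest-center distance resolve toward
# the lowest index through which.min.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Cluster image chromaticity with K-means (k = 3)
#'
#' Runs Lloyd's algorithm on the (a*, b*) feature pairs only: L* carries
#' lightness, not stain identity, and is reserved for role assignment
#' afterwards. Each of `restarts` runs is seeded with k-means++ and the run
#' with the lowest within-cluster sum of squares (inertia) is kept. The
#' result is deterministic given `seed`.
#'
#' @param lab A `lab_image` from [rgb_to_lab()] with at least 3 pixels and at
#'   least 3 distinct (a*, b*) values.
#' @param seed Integer RNG seed (default 0).
#' @param restarts Number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return A `cluster_model`: list with `k` (3), `centroids` (3 x 2 matrix,
#'   columns a*, b*), `labels` (`H x W` integer matrix in 0..2), `seed`,
#'   `inertia`.
#' @export
kmeans_cluster <- function(lab, seed = 0L, restarts = 10L, max_iter = 300L) {
  stopifnot(inherits(lab, "lab_image"))
  x <- cbind(a = as.vector(lab$a), b = as.vector(lab$b))
  ndistinct <- nrow(unique(x))
  if (ndistinct < 3L)
    stop_fdv("need at least 3 distinct (a*, b*) values to form 3 clusters, found %d",
             ndistinct, class = "fiberDV_degenerate_error")
  k <- 3L
  best <- NULL
  local_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = max_iter, algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  labels <- matrix(best$cluster - 1L, nrow(lab$L), ncol(lab$L))
  structure(list(k = k,
                 centroids = unname(best$centers),
                 labels = labels,
                 seed = as.integer(seed),
                 inertia = best$tot.withinss),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model k=%d on %d x %d px, inertia %.1f, seed %d>\n",
              x$k, nrow(x$labels), ncol(x$labels), x$inertia, x$seed))
  invisible(x)
}

#' Assign tissue roles to the three clusters
#'
#' The cluster with the highest mean L* is the background (BS, near-white
#' empty slide), the lowest mean L* is the foreground (FS, hematoxylin-dark
#' nuclei/glands/follicles), and the remaining cluster is the collagen area
#' (CAS, eosin pink). The assignment is invariant to cluster index
#' permutation.
#'
#' @param model A `cluster_model` from [kmeans_cluster()].
#' @param lab The `lab_image` the model was fitted on (source of L*).
#' @return A `segmentation`: list of disjoint logical masks `cas`, `fs`, `bs`
#'   covering the frame, `role_map` (named integer vector role -> cluster
#'   index 0..2), and the model `centroids`.
#' @export
assign_roles <- function(model, lab) {
  stopifnot(inherits(model, "cluster_model"), inherits(lab, "lab_image"))
  if (!same_frame(model$labels, lab$L))
    stop_fdv("cluster labels (%d x %d) and Lab image (%d x %d) frames differ",
             nrow(model$labels), ncol(model$labels), nrow(lab$L), ncol(lab$L),
             class = "fiberDV_dim_error")
  mean_L <- vapply(0:2, function(j) mean(lab$L[model$labels == j]), numeric(1))
  ord <- order(mean_L)   # lowest first
  if (any(diff(sort(mean_L)) < 1e-6))
    stop_fdv(paste0("ambiguous roles: two clusters have mean L* within 1e-6 ",
                    "(mean L* = %s; centroids a*,b* = %s)"),
             paste(sprintf("%.6f", mean_L), collapse = ", "),
             paste(apply(model$centroids, 1,
                         function(z) sprintf("(%.2f, %.2f)", z[1], z[2])),
                   collapse = " "),
             class = "fiberDV_ambiguous_error")
  role_map <- c(fs = ord[1] - 1L, cas = ord[2] - 1L, bs = ord[3] - 1L)
  structure(list(
    cas = model$labels == role_map[["cas"]],
    fs  = model$labels == role_map[["fs"]],
    bs  = model$labels == role_map[["bs"]],
    role_map = role_map,
    centroids = model$centroids
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  n <- length(x$cas)
  cat(sprintf("<segmentation %d x %d: CAS %.1f%%, FS %.1f%%, BS %.1f%%>\n",
              nrow(x$cas), ncol(x$cas),
              100 * sum(x$cas) / n, 100 * sum(x$fs) / n, 100 * sum(x$bs) / n))
  invisible(x)
}

#' Segment an H&E image into collagen / foreground / background
#'
#' Convenience wrapper: [rgb_to_lab()], [kmeans_cluster()], [assign_roles()].
#'
#' @inheritParams kmeans_cluster
#' @param image Integer `H x W x 3` sRGB array.
#' @return A `segmentation` (see [assign_roles()]).
#' @export
segment_tissue <- function(image, seed = 0L, restarts = 10L) {
  lab <- rgb_to_lab(image)
  model <- kmeans_cluster(lab, seed = seed, restarts = restarts)
  assign_roles(model, lab)
}

#' Render a color overlay of a segmentation
#'
#' Foreground in purple, collagen in magenta, background untouched white --
#' the conventional H&E segmentation display.
#'
#' @param seg A `segmentation`.
#' @return An integer `H x W x 3` RGB array.
#' @export
segmentation_overlay <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  d <- dim(seg$cas)
  img <- array(255L, c(d, 3L))
  paint <- function(img, mask, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch]
      img[, , ch] <- plane
    }
    img
  }
  img <- paint(img, seg$cas, c(222L, 49L, 199L))  # magenta collagen
  img <- paint(img, seg$fs, c(104L, 30L, 126L))   # purple foreground
  storage.mode(img) <- "integer"
  img
}
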
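test_that("rgb_to_lab matches the CIE definitions", {
  lab_white <- rgb_to_lab(solid_image(1, 1, c(255, 255, 255)))
  expect_equal(lab_white$L[1, 1], 100, tolerance = 1e-4)
  expect_lt(abs(lab_white$a[1, 1]), 0.01)
  expect_lt(abs(lab_white$b[1, 1]), 0.01)

  lab_black <- rgb_to_lab(solid_image(1, 1, c(0, 0, 0)))
  expect_equal(c(lab_black$L[1, 1], lab_black$a[1, 1], lab_black$b[1, 1]),
               c(0, 0, 0), tolerance = 1e-10)

  # red and a panel of random colors against the independent scalar oracle
  set.seed(3)
  cols <- rbind(c(255, 0, 0),
                matrix(sample.int(256, 60, replace = TRUE) - 1, ncol = 3))
  for (i in seq_len(nrow(cols))) {
    got <- rgb_to_lab(solid_image(1, 1, cols[i, ]))
    want <- oracle_lab_pixel(cols[i, 1], cols[i, 2], cols[i, 3])
    expect_lt(max(abs(c(got$L[1, 1], got$a[1, 1], got$b[1, 1]) - want)), 0.05)
  }
})

test_that("k-means exactly partitions three well-separated solid colors", {
  cols <- list(c(250, 245, 248), c(228, 110, 160), c(70, 32, 110))
  img <- three_band_image(12, 30, cols)
  lab <- rgb_to_lab(img)
  model <- kmeans_cluster(lab, seed = 1)
  # all pixels of one band share a label, and bands differ
  band_labels <- c(model$labels[1, 5], model$labels[1, 15], model$labels[1, 25])
  expect_equal(length(unique(band_labels)), 3L)
  for (b in 1:3) {
    cols_idx <- ((b - 1) * 10 + 1):(b * 10)
    expect_true(all(model$labels[, cols_idx] == band_labels[b]))
  }
})

test_that("different seeds give the same partition up to label permutation", {
  img <- three_band_image(10, 30, list(c(250, 245, 248), c(228, 110, 160),
                                       c(70, 32, 110)))
  lab <- rgb_to_lab(img)
  m1 <- kmeans_cluster(lab, seed = 1)
  m2 <- kmeans_cluster(lab, seed = 99)
  # compare as set families: group pixels by label, sort each family
  fam <- function(m) {
    f <- split(seq_along(m$labels), as.vector(m$labels))
    unname(f[order(vapply(f, min, integer(1)))])
  }
  expect_identical(fam(m1), fam(m2))
})

test_that("k-means recovers tight Gaussian blobs and agrees with a Lloyd oracle", {
  set.seed(11)
  centers <- rbind(c(0, 0), c(40, 0), c(0, 40))
  pts <- do.call(rbind, lapply(1:3, function(j)
    cbind(rnorm(300, centers[j, 1], 1), rnorm(300, centers[j, 2], 1))))
  truth <- rep(1:3, each = 300)
  lab <- structure(list(L = matrix(50, 30, 30),
                        a = matrix(pts[, 1], 30, 30),
                        b = matrix(pts[, 2], 30, 30)), class = "lab_image")
  model <- kmeans_cluster(lab, seed = 5)
  agree <- function(a, b) {
    tab <- table(a, b)
    sum(apply(tab, 1, max)) / length(a)
  }
  expect_gte(agree(as.vector(model$labels), truth), 0.99)

  orc <- oracle_lloyd(pts, centers)
  expect_gte(agree(as.vector(model$labels), orc$labels), 0.99)
})

test_that("the best-of-restarts inertia is never worse than a single restart", {
  g <- generate_image(preset("normal", seed = 2, height = 60, width = 60))
  lab <- rgb_to_lab(g$image)
  multi <- kmeans_cluster(lab, seed = 4, restarts = 8)
  single <- kmeans_cluster(lab, seed = 4, restarts = 1)
  expect_lte(multi$inertia, single$inertia + 1e-9)
})

test_that("degenerate inputs with fewer than 3 distinct chromaticities error", {
  img <- solid_image(4, 4, c(100, 100, 100))
  expect_error(kmeans_cluster(rgb_to_lab(img)), "distinct",
               class = "fiberDV_degenerate_error")
})

test_that("roles follow mean L*: background brightest, foreground darkest", {
  img <- three_band_image(10, 30, list(c(250, 245, 248),   # bright -> bs
                                       c(228, 110, 160),   # mid    -> cas
                                       c(70, 32, 110)))    # dark   -> fs
  lab <- rgb_to_lab(img)
  model <- kmeans_cluster(lab, seed = 1)
  seg <- assign_roles(model, lab)
  expect_true(all(seg$bs[, 1:10]))
  expect_true(all(seg$cas[, 11:20]))
  expect_true(all(seg$fs[, 21:30]))

  # partition property: every pixel in exactly one mask
  expect_true(all(seg$cas + seg$fs + seg$bs == 1L))

  # permutation robustness: relabeling clusters leaves the masks unchanged
  perm <- c(2L, 0L, 1L)
  model2 <- model
  model2$labels <- matrix(perm[model$labels + 1L], nrow(model$labels))
  model2$centroids <- model$centroids[order(perm), ]
  seg2 <- assign_roles(model2, lab)
  expect_identical(seg2$cas, seg$cas)
  expect_identical(seg2$fs, seg$fs)
  expect_identical(seg2$bs, seg$bs)
})

test_that("two clusters with identical mean L* are an ambiguous-roles error", {
  labels <- matrix(rep(0:2, each = 4), 2, 6)
  model <- structure(list(k = 3L, centroids = matrix(0, 3, 2), labels = labels,
                          seed = 0L, inertia = 0), class = "cluster_model")
  lab <- structure(list(L = matrix(rep(c(40, 70, 40), each = 4), 2, 6),
                        a = matrix(0, 2, 6), b = matrix(0, 2, 6)),
                   class = "lab_image")
  expect_error(assign_roles(model, lab), "ambiguous",
               class = "fiberDV_ambiguous_error")
})

test_that("foreground mask captures the drawn hematoxylin structures", {
  g <- generate_image(preset("normal", seed = 3, height = 160, width = 160))
  seg <- segment_tissue(g$image, seed = 0, restarts = 5)
  structure_px <- g$truth$class_map == 2
  expect_gte(sum(seg$fs & structure_px) / sum(structure_px), 0.9)

  g_scar <- generate_image(preset("scar", seed = 3, height = 160, width = 160))
  seg_scar <- segment_tissue(g_scar$image, seed = 0, restarts = 5)
  expect_lt(mean(seg_scar$fs), mean(seg$fs))
})

test_that("segmentation labels are deterministic given the seed", {
  g <- generate_image(preset("normal", seed = 5, height = 60, width = 60))
  lab <- rgb_to_lab(g$image)
  m1 <- kmeans_cluster(lab, seed = 7)
  m2 <- kmeans_cluster(lab, seed = 7)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$centroids, m2$centroids)
})
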
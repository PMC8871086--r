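test_that("generation is deterministic given the spec", {
  sp <- synthetic_spec(height = 60, width = 60, fiber_count = 30,
                       ellipse_count = 10, seed = 9)
  g1 <- generate_image(sp)
  g2 <- generate_image(sp)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$truth$class_map, g2$truth$class_map)
})

test_that("ground truth is consistent with the drawing rules", {
  sp <- synthetic_spec(height = 80, width = 80, fiber_count = 25,
                       ellipse_count = 8, seed = 2)
  g <- generate_image(sp)
  # theta defined exactly on collagen pixels
  expect_true(all(!is.na(g$truth$theta_map[g$truth$class_map == 1])))
  expect_true(all(is.na(g$truth$theta_map[g$truth$class_map != 1])))
  # zero ellipses -> no structure pixels
  g0 <- generate_image(synthetic_spec(height = 60, width = 60, fiber_count = 20,
                                      ellipse_count = 0, seed = 2))
  expect_false(any(g0$truth$class_map == 2))
})

test_that("colors too close in chromaticity are rejected", {
  expect_error(
    synthetic_spec(colors = list(background = c(247, 243, 246),
                                 collagen = c(240, 235, 240),
                                 structure = c(70, 32, 110))),
    "15", class = "fiberDV_param_error")
})

test_that("drawn fiber angles follow the axial von Mises construction", {
  set.seed(101)
  th <- sample_axial_angles(2000, 45, 50)
  expect_lt(circ_dist_axial(circ_mean_axial(th), 45), 3)
  expect_true(all(th >= 0 & th < 180))

  # the same holds for angles actually drawn into a scene
  sp <- synthetic_spec(height = 50, width = 50, fiber_count = 300,
                       orientation_mean_deg = 45, orientation_kappa = 50,
                       ellipse_count = 0, seed = 13)
  g <- generate_image(sp)
  expect_lt(circ_dist_axial(circ_mean_axial(g$truth$fiber_angles), 45), 3)

  # kappa = 0 passes a Rayleigh-style uniformity check on doubled angles
  set.seed(55)
  u <- sample_axial_angles(2000, 0, 0)
  phi <- 2 * u * pi / 180
  z <- 2000 * (mean(cos(phi))^2 + mean(sin(phi))^2)
  expect_lt(z, -log(0.01))       # fail to reject uniformity at alpha = 0.01
})

test_that("presets encode the tissue contrasts", {
  normal <- preset("normal", seed = 1)
  scar <- preset("scar", seed = 1)
  expect_equal(normal$orientation_kappa, 0)
  expect_equal(scar$orientation_kappa, 8)
  expect_equal(scar$gland_fraction, 0)     # appendages absent, nuclei persist
  expect_gt(normal$gland_fraction, 0)
  expect_gt(scar$fiber_count, normal$fiber_count)

  mixed <- preset("mixed", seed = 1, height = 60, width = 80)
  g <- generate_image(mixed)
  expect_equal(dim(g$image), c(60L, 80L, 3L))
  # appendage-scale structures only on the normal (right) half
  expect_equal(mixed$composite$left$gland_fraction, 0)
  expect_gt(mixed$composite$right$gland_fraction, 0)

  expect_error(preset("tumor"), "arg")
})

test_that("scar coverage dominates normal coverage across seeds", {
  cov <- function(p, s) {
    g <- generate_image(preset(p, seed = s, height = 100, width = 100))
    mean(g$truth$class_map == 1)
  }
  for (s in 0:9) expect_gt(cov("scar", s), cov("normal", s))
})

test_that("rotation augmentation is lossless and multiplies the set", {
  imgs <- replicate(93, solid_image(2, 3, c(1, 2, 3)), simplify = FALSE)
  out <- rotate_augment(imgs)
  expect_length(out, 372L)

  set.seed(19)
  img <- array(sample.int(256, 24) - 1L, c(2, 4, 3))
  storage.mode(img) <- "integer"
  expect_identical(rotate_image(img, 360), img)
  expect_identical(rotate_image(rotate_image(img, 90), 90),
                   rotate_image(img, 180))
  expect_identical(rotate_image(rotate_image(img, 90), 270), img)
  expect_error(rotate_augment(list(img), angles = c(0, 45)),
               "interpolation", class = "fiberDV_param_error")
  expect_error(rotate_augment(list(img), angles = numeric(0)),
               class = "fiberDV_param_error")
})

test_that("split sizes follow the floor-remainder rule", {
  sp <- split_dataset(372, c(0.64, 0.16, 0.20), seed = 4)
  expect_equal(lengths(sp), c(train = 239L, validate = 59L, test = 74L))

  sp10 <- split_dataset(10, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(lengths(sp10), c(train = 8L, validate = 1L, test = 1L))
})

test_that("splits are disjoint, complete, and seed-shuffled", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(10:500, 1)
    f2 <- runif(1, 0.1, 0.3); f3 <- runif(1, 0.1, 0.3)
    fr <- c(1 - f2 - f3, f2, f3)
    sp <- split_dataset(n, fr, seed = i)
    expect_identical(sort(unlist(sp, use.names = FALSE)), seq_len(n))
  }
  s1 <- split_dataset(100, seed = 1)
  s2 <- split_dataset(100, seed = 2)
  expect_equal(lengths(s1), lengths(s2))
  expect_false(identical(s1$train, s2$train))

  expect_error(split_dataset(4, c(0.98, 0.01, 0.01)),
               class = "fiberDV_param_error")
  expect_error(split_dataset(10, c(0.5, 0.5, 0.5)),
               class = "fiberDV_param_error")
})

test_that("the pipeline recovers generator ground truth end to end", {
  # moderate-coverage scene so most collagen pixels lie on isolated fibers
  sp <- synthetic_spec(height = 150, width = 150, fiber_count = 60,
                       fiber_width_px = 3, fiber_length_px = 60,
                       orientation_kappa = 0, ellipse_count = 25, seed = 8)
  g <- generate_image(sp)
  seg <- segment_tissue(g$image, seed = 0, restarts = 5)
  expect_gte(role_accuracy(seg, g$truth$class_map), 0.9)

  f <- estimate_orientation(seg$cas)
  on_fiber <- f$valid & g$truth$class_map == 1
  err <- circ_dist_axial(f$theta[on_fiber], g$truth$theta_map[on_fiber])
  expect_lte(median(err), 180 / 18)        # within one angular step
})
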
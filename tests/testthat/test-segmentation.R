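test_that("histogram peak finder recovers constructed modes", {
  g <- tiny_geometry()
  n <- prod(g$matrix_shape)
  # two-delta histogram at 100 / 300
  vals <- array(rep(c(100, 300), times = c(round(0.7 * n), n - round(0.7 * n))),
                g$matrix_shape)
  peaks <- find_histogram_peaks(image3d(vals, g))
  expect_equal(unname(peaks), c(100, 300))
  # constant image: one mode only
  flat <- image3d(array(42, g$matrix_shape), g)
  expect_error(find_histogram_peaks(flat), class = "adiposim_unimodal_error")
})

test_that("threshold segmentation inverts the linear mixing rule", {
  g <- tiny_geometry()
  # box face placed so boundary voxels carry fractions 0.25 / 0.50 / 0.75
  # (sub-voxel offsets at s = 4): fraction > (150-15)/405 = 1/3 is kept
  spec <- box_spec(c(-9, 0.225), c(-9, 9), c(-6, 6))
  img <- render(spec, g, clean_model(), rng_seed = 1, supersample = 4L)
  m150 <- threshold_segment(img, threshold_config(150, 0))
  fr <- rasterize_fractions(spec, g, supersample = 4L)$fat
  expect_identical(m150$labels > 0L, fr > 1 / 3)
  # threshold at/above the maximum intensity: empty mask
  m_top <- threshold_segment(img, threshold_config(420, 0))
  expect_equal(sum(m_top$labels), 0)
})

test_that("measured volume is non-increasing in the threshold", {
  spec <- build_phantom_spec(150, 13)
  img <- render(spec, phantom_geometry("cartesian"), rng_seed = 3)
  vols <- vapply(c(150, 250, 350), function(t) {
    mask_volume(threshold_segment(img, threshold_config(t)))
  }, 0)
  expect_true(all(diff(vols) < 0))
})

test_that("small-region exclusion follows area x slice thickness", {
  g <- tiny_geometry()   # 0.9 x 0.9 x 5 mm voxels
  lab <- array(0L, g$matrix_shape)
  lab[5:10, 5, 1] <- 1L          # 6 voxels: 24.3 mm^3 < 25 -> removed
  lab[20:26, 20, 1] <- 1L        # 7 voxels: 28.35 mm^3    -> kept
  lab[2, 2, 2] <- 1L             # diagonal pair: 8-connected, one region
  lab[3, 3, 2] <- 1L
  m <- remove_small_regions(label_mask(lab, g), 25)
  expect_equal(sum(m$labels[, , 1][, 5]), 0)
  expect_equal(sum(m$labels[20:26, 20, 1]), 7)
  expect_equal(sum(m$labels[, , 2]), 0)   # 2 voxels = 8.1 mm^3, removed
  # idempotent; never adds voxels
  m2 <- remove_small_regions(m, 25)
  expect_identical(m2$labels, m$labels)
  expect_true(all(m$labels <= lab))
  # min_volume = 0 is the identity
  m0 <- remove_small_regions(label_mask(lab, g), 0)
  expect_identical(m0$labels, lab)
})

test_that("8-connectivity merges diagonal neighbours into one region", {
  g <- tiny_geometry()
  lab <- array(0L, g$matrix_shape)
  # a diagonal staircase of 7 voxels: one 8-connected region of 28.35 mm^3
  for (i in 1:7) lab[10 + i, 10 + i, 1] <- 1L
  m <- remove_small_regions(label_mask(lab, g), 25)
  expect_equal(sum(m$labels), 7)
})

test_that("bias correction recovers a known quadratic field", {
  spec <- build_infant_spec(31, n_depots = 0L, suppression_failure = FALSE)
  g <- infant_geometry("cartesian")
  biased <- render(spec, g,
                   intensity_model(noise_sigma = 0, streak_fraction = 0,
                                   bias_field_amplitude = 0.2),
                   rng_seed = 1)
  clean <- render(spec, g, clean_model(), rng_seed = 1)
  bc <- correct_bias_field(biased, 2)
  fat <- clean$data == 420
  cv <- function(x) stats::sd(x) / mean(x)
  expect_gt(cv(biased$data[fat]) / cv(bc$image$data[fat]), 2)
  expect_true(all(bc$field > 0))
  # unbiased input: output essentially unchanged
  bc0 <- correct_bias_field(clean, 2)
  expect_lt(max(abs(bc0$image$data[fat] / clean$data[fat] - 1)), 1e-2)
  # all-background image returns unchanged with a unit field
  flat <- image3d(array(15, c(20, 20, 2)),
                  acquisition_geometry(c(1, 1), 5, 1, c(20, 20, 2)))
  bcf <- correct_bias_field(flat, 2)
  expect_identical(bcf$image$data, flat$data)
  expect_true(all(bcf$field == 1))
})

test_that("cluster centers come deterministically from the histogram", {
  spec <- build_phantom_spec(172, 7)
  img <- render(spec, phantom_geometry("cartesian"), clean_model(),
                rng_seed = 2)
  c3 <- estimate_cluster_params(img, 3)
  expect_equal(length(c3), 3)
  expect_lt(abs(c3[1] - 15), 10)
  expect_lt(abs(c3[3] - 420), 25)
  expect_equal(c3[2], (c3[1] + c3[3]) / 2)
  c2 <- estimate_cluster_params(img, 2)
  expect_equal(unname(c2), unname(c3[c(1, 3)]))
  expect_identical(c3, estimate_cluster_params(img, 3))
  expect_error(estimate_cluster_params(img, 1), class = "adiposim_error")
})

test_that("k-means equals midpoint thresholding in the two-class limit", {
  g <- tiny_geometry()
  # (a) arbitrary blob, regularization off: exact equivalence
  spec <- box_spec(c(-5.4, 6.3), c(-4.5, 8.1), c(-6, 6))
  img <- render(spec, g, clean_model(), rng_seed = 1)
  km <- kmeans_segment(img, cluster_config(contour_smoothing = 0L,
                                           presmooth_fwhm = 0,
                                           bias_order = 0L))
  thr <- threshold_segment(img, threshold_config(217.5))
  expect_identical(km$labels, thr$labels)
  # (b) straight-edged band across the full image width, default
  # regularization: no boundary curvature, so equivalence persists
  band <- box_spec(c(-22, 22), c(-4, 4), c(-6, 6))
  gb <- tiny_geometry(nx = 44, ny = 24, spacing = 1)
  imgb <- render(band, gb, clean_model(), rng_seed = 1)
  kmb <- kmeans_segment(imgb, cluster_config(bias_order = 0L))
  thrb <- threshold_segment(imgb, threshold_config(217.5))
  expect_identical(kmb$labels, thrb$labels)
})

test_that("k-means segmentation is deterministic", {
  spec <- build_phantom_spec(120, 17)
  img <- render(spec, phantom_geometry("cartesian"), rng_seed = 4)
  a <- kmeans_segment(img)
  b <- kmeans_segment(img)
  expect_identical(a$labels, b$labels)
})
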
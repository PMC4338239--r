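test_that("mask volume applies the pitch-slab formula", {
  g <- acquisition_geometry(c(0.9, 0.9), 5, 1, c(10, 10, 10))
  m <- label_mask(array(1L, c(10, 10, 10)), g)
  # 1000 voxels x 0.81 mm^2 x (5 + 1) mm = 4.86 ml
  expect_equal(mask_volume(m), 4.86)
  expect_equal(mask_volume(m, slab = "thickness"), 4.05)
  empty <- label_mask(array(0L, c(10, 10, 10)), g)
  expect_equal(mask_volume(empty), 0)
})

test_that("volume is additive over disjoint labels and ignores intensities", {
  g <- tiny_geometry()
  lab <- array(0L, g$matrix_shape)
  lab[1:10, 1:10, 1] <- 2L
  lab[20:29, 20:29, 2] <- 3L
  m <- label_mask(lab, g)
  expect_equal(mask_volume(m, 2L) + mask_volume(m, 3L), mask_volume(m))
})

test_that("mass conversion uses the adipose density 0.925 g/ml", {
  expect_equal(volume_to_mass(100), 92.5)
  expect_equal(volume_to_mass(0), 0)
  expect_equal(volume_to_mass(172), 159.1)
  expect_error(volume_to_mass(-1), class = "adiposim_error")
})

test_that("halving the slice pitch changes measured volume by < 2%", {
  spec <- build_infant_spec(rng_seed = 21, n_depots = 0L,
                            suppression_failure = FALSE)
  model <- clean_model()
  g1 <- acquisition_geometry(c(0.9, 0.9), 5, 1, c(120, 120, 26))
  g2 <- acquisition_geometry(c(0.9, 0.9), 2.5, 0.5, c(120, 120, 52))
  v <- vapply(list(g1, g2), function(g) {
    img <- render(spec, g, model, rng_seed = 1)
    mask_volume(threshold_segment(img, threshold_config(217.5)))
  }, 0)
  expect_lt(abs(v[2] / v[1] - 1), 0.02)
})

test_that("measure_mask emits tidy rows per compartment", {
  g <- tiny_geometry()
  lab <- array(0L, g$matrix_shape)
  lab[1:10, 1:10, 1] <- 2L
  lab[20:25, 20:25, 2] <- 3L
  rows <- measure_mask(label_mask(lab, g), subject_id = "s1",
                       repeat_idx = 2L, method = "kmeans",
                       sequence_mode = "cartesian")
  expect_setequal(rows$compartment,
                  c("total", "subcutaneous", "intra_abdominal"))
  expect_equal(rows$mass_g, rows$volume_ml * 0.925)
  tot <- rows$volume_ml[rows$compartment == "total"]
  expect_equal(sum(rows$volume_ml) - tot, tot)
})
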
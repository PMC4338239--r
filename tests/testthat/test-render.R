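test_that("partial-volume mixing is linear in the fat volume fraction", {
  g <- tiny_geometry()
  # box face through voxel centres: boundary voxels are exactly half fat
  half_box <- box_spec(c(-9, 0.45), c(-9, 9), c(-6, 6))
  img <- render(half_box, g, clean_model(), rng_seed = 1, supersample = 4L)
  vals <- sort(unique(round(as.vector(img$data), 6)))
  expect_true(all(c(15, 217.5, 420) %in% vals))
  # the column of voxels split by the face sits exactly at the midpoint
  ax <- axis_centers(g)
  split_col <- which(abs(ax$x - 0.45) < 1e-9)
  inner_rows <- which(abs(ax$y) < 8.5)
  expect_equal(unique(as.vector(img$data[split_col, inner_rows, 2])), 217.5)
})

test_that("voxels fully inside fat render exactly at the fat mode", {
  g <- tiny_geometry()
  img <- render(aligned_box(), g, clean_model(), rng_seed = 1)
  ax <- axis_centers(g)
  inside <- abs(ax$x) < 8
  expect_true(all(img$data[inside, which(abs(ax$y) < 8), 2] == 420))
  corner <- img$data[1, 1, 1]
  expect_equal(corner, 15)
})

test_that("renders are reproducible and respond to the seed", {
  spec <- build_phantom_spec(60, 3)
  g <- phantom_geometry("cartesian")
  a <- render(spec, g, rng_seed = 5)
  b <- render(spec, g, rng_seed = 5)
  c <- render(spec, g, rng_seed = 6)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("rendered phantom histogram has modes near 15 and 420", {
  spec <- build_phantom_spec(172, 7)
  img <- render(spec, phantom_geometry("cartesian"), rng_seed = 2)
  peaks <- find_histogram_peaks(img)
  expect_lt(abs(peaks[["background_peak"]] / 15 - 1), 0.1)
  expect_lt(abs(peaks[["fat_peak"]] / 420 - 1), 0.1)
})

test_that("raster fractions agree with the brute-force oracle volume", {
  spec <- build_phantom_spec(80, 11)
  g <- phantom_geometry("cartesian")
  fr <- rasterize_fractions(spec, g, supersample = 5L)
  # pitch-scaled sampled volume vs analytic: slice sampling leaves ~1-2%
  sampled <- sum(fr$fat) * prod(g$in_plane_spacing) * slice_pitch(g) / 1000
  expect_rel_equal(sampled, analytic_fat_volume(spec), 0.04)
})

test_that("supersampling converges towards the analytic volume", {
  spec <- box_spec(c(-9.13, 9.41), c(-8.77, 8.91), c(-8.5, 8.5))
  g <- acquisition_geometry(c(0.9, 0.9), 5, 0, c(40, 40, 6))
  errs <- vapply(c(2L, 4L, 8L, 16L), function(s) {
    fr <- rasterize_fractions(spec, g, supersample = s)
    v <- sum(fr$fat) * prod(g$in_plane_spacing) * 5 / 1000
    abs(v / analytic_fat_volume(spec) - 1)
  }, 0)
  expect_lt(errs[4], 0.005)
  expect_lte(errs[4], errs[1] + 1e-12)
  expect_lte(errs[3], errs[1] + 1e-12)
})

test_that("specs larger than the field of view fail loudly", {
  spec <- build_phantom_spec(172, 1)
  small <- acquisition_geometry(c(0.9, 0.9), 5, 1, c(60, 60, 10))
  expect_error(render(spec, small), class = "adiposim_fov_error")
})

test_that("repeat series share anatomy but differ in noise", {
  spec <- build_infant_spec(2, n_depots = 0L, suppression_failure = FALSE)
  g <- acquisition_geometry(c(1.8, 1.8), 5, 1, c(80, 64, 26))
  reps <- render_repeat_series(spec, g, n_repeats = 3, rng_seed = 4,
                               artifact_mode = "none", supersample = 3L)
  expect_length(reps, 3)
  expect_false(identical(reps[[1]]$data, reps[[2]]$data))
  expect_false(identical(reps[[2]]$data, reps[[3]]$data))
  expect_identical(reps[[1]]$geometry, reps[[2]]$geometry)
  # zero noise and zero jitter: repeats are identical
  quiet <- render_repeat_series(spec, g, clean_model(), n_repeats = 2,
                                rng_seed = 4, artifact_mode = "none",
                                jitter_sd = 0, supersample = 3L)
  expect_identical(quiet[[1]]$data, quiet[[2]]$data)
  expect_error(render_repeat_series(spec, g, n_repeats = 1),
               class = "adiposim_spec_error")
})
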
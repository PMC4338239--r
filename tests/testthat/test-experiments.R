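small_phantom_config <- function(seed = 5, out_dir = NULL) {
  experiment_config(
    study = "phantom_accuracy", n_phantoms = 2L, volume_range = c(54, 120),
    sequences = "cartesian", motion_modes = "motionless",
    methods = c("kmeans", "thr150"), supersample = 3L, seed = seed,
    out_dir = out_dir, verbose = FALSE
  )
}

small_infant_config <- function(seed = 5, out_dir = NULL) {
  experiment_config(
    study = "infant_reproducibility", sequences = "cartesian",
    cartesian_repeats = c(2L, 2L), infant_methods = "thr150",
    supersample = 3L, seed = seed, out_dir = out_dir, verbose = FALSE
  )
}

test_that("experiment configs validate methods and design", {
  expect_error(experiment_config(methods = "watershed"),
               class = "adiposim_config_error")
  expect_error(experiment_config(n_phantoms = 0),
               class = "adiposim_config_error")
  expect_error(experiment_config(volume_range = c(10, 600)),
               class = "adiposim_config_error")
  cfg <- experiment_config()
  expect_equal(cfg$n_phantoms, 10L)
  expect_equal(cfg$volume_range, c(54, 300))
  expect_equal(sum(cfg$cartesian_repeats), 21)       # 7 x 3 scans
  expect_equal(sum(cfg$propeller_repeats), 13)       # 4 + 3 + 3 + 3 scans
})

test_that("phantom study runs are deterministic and write reports", {
  dir1 <- file.path(tempdir(), "run1")
  s1 <- run_phantom_accuracy(small_phantom_config(out_dir = dir1))
  s2 <- run_phantom_accuracy(small_phantom_config())
  expect_identical(s1$measurements, s2$measurements)
  s3 <- run_phantom_accuracy(small_phantom_config(seed = 6))
  expect_false(identical(s1$measurements$volume_ml,
                         s3$measurements$volume_ml))
  expect_equal(nrow(s1$measurements), 2 * 2)   # 2 phantoms x 2 methods
  expect_true(all(c("rms_error_pct", "pearson_r2", "mean_signed_pct") %in%
                    names(s1$accuracy)))
  expect_true(file.exists(file.path(dir1, "phantom_measurements.csv")))
  expect_true(file.exists(file.path(dir1, "phantom_accuracy_wide.csv")))
  expect_true(file.exists(file.path(dir1, "phantom_accuracy.json")))
  unlink(dir1, recursive = TRUE)
})

test_that("infant study bookkeeping matches the repeat design", {
  st <- run_infant_reproducibility(small_infant_config())
  expect_equal(nrow(st$measurements), 4)   # 2 subjects x 2 repeats, total only
  rep_row <- st$reproducibility
  expect_equal(rep_row$df, 2)              # 2 subjects x (2 - 1)
  expect_equal(rep_row$n_scans, 4)
  st2 <- run_infant_reproducibility(small_infant_config())
  expect_identical(st$measurements, st2$measurements)
})

test_that("degenerate limit: no noise, no artifacts, no partial volume", {
  g <- tiny_geometry()
  img <- render(aligned_box(), g, clean_model(), rng_seed = 1)
  truth <- analytic_fat_volume(aligned_box())
  v_thr <- mask_volume(threshold_segment(img, threshold_config(150)))
  v_km <- mask_volume(kmeans_segment(img, cluster_config(
    contour_smoothing = 0L, presmooth_fwhm = 0, bias_order = 0L
  )))
  expect_rel_equal(v_thr, truth, 0.005)
  expect_rel_equal(v_km, truth, 0.005)
})

test_that("study objects have tidy/glance/autoplot methods", {
  st <- run_phantom_accuracy(small_phantom_config())
  expect_identical(tidy(st), st$accuracy)
  expect_equal(glance(st)$n_phantoms, 2L)
  expect_s3_class(autoplot(st), "ggplot")
  sti <- run_infant_reproducibility(small_infant_config())
  expect_identical(tidy(sti), sti$reproducibility)
  expect_s3_class(autoplot(sti), "ggplot")
})
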
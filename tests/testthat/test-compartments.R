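seg_and_split <- function(spec, rng_seed = 1) {
  img <- render(spec, infant_geometry("cartesian"), rng_seed = rng_seed)
  km <- kmeans_segment(img)
  list(img = img, km = km, split = split_compartments(km, img))
}

test_that("compartment labels partition the adipose mask", {
  spec <- build_infant_spec(rng_seed = 4)
  res <- seg_and_split(spec)
  expect_false(attr(res$split, "low_confidence"))
  adipose <- res$km$labels > 0L
  expect_identical(res$split$labels > 0L, adipose)
  expect_true(all(res$split$labels[adipose] %in% c(2L, 3L)))
  expect_equal(mask_volume(res$split, 2L) + mask_volume(res$split, 3L),
               mask_volume(res$km))
})

test_that("compartment volumes land near the analytic truth", {
  spec <- build_infant_spec(rng_seed = 4)
  res <- seg_and_split(spec)
  expect_rel_equal(mask_volume(res$split, 2L), spec$true_subcutaneous_ml, 0.15)
  expect_rel_equal(mask_volume(res$split, 3L), spec$true_intra_abdominal_ml,
                   0.15)
})

test_that("a depot-free infant yields an empty intra-abdominal label", {
  spec <- build_infant_spec(rng_seed = 8, n_depots = 0L)
  res <- seg_and_split(spec)
  expect_equal(mask_volume(res$split, 3L), 0)
})

test_that("an open body outline is flagged low confidence", {
  spec <- build_infant_spec(rng_seed = 6, shell_opening = 1.2)
  img <- render(spec, infant_geometry("cartesian"), rng_seed = 1)
  km <- kmeans_segment(img)
  expect_warning(sp <- split_compartments(km, img), "low confidence")
  expect_true(attr(sp, "low_confidence"))
})
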
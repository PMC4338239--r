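test_that("zero amplitude is the identity", {
  spec <- build_phantom_spec(60, 3)
  img <- render(spec, phantom_geometry("cartesian"), rng_seed = 1)
  for (mode in c("cartesian_ghost", "propeller_blur")) {
    expect_identical(apply_breathing_artifact(img, mode, 0, 1), img)
  }
  expect_error(apply_breathing_artifact(img, "cartesian_ghost", -1),
               class = "adiposim_artifact_error")
})

test_that("both artifact operators conserve total intensity within 1%", {
  spec <- build_phantom_spec(150, 9)
  for (seq_name in c("cartesian", "propeller")) {
    g <- phantom_geometry(seq_name)
    img <- render(spec, g, rng_seed = 2)
    mode <- if (seq_name == "cartesian") "cartesian_ghost" else "propeller_blur"
    out <- apply_breathing_artifact(img, mode, 2.5, rng_seed = 3)
    expect_rel_equal(sum(out$data), sum(img$data), 0.01)
  }
})

test_that("cartesian ghosting displaces an impulse along exactly one axis", {
  g <- acquisition_geometry(c(1, 1), 5, 1, c(64, 64, 1))
  arr <- array(0, c(64, 64, 1))
  arr[32, 32, 1] <- 1000
  img <- image3d(arr, g)
  out <- apply_breathing_artifact(img, "cartesian_ghost", 3, rng_seed = 5)
  hit <- which(out$data > 1e-6, arr.ind = TRUE)
  # every replica stays in the impulse's x row: displacement is y-only
  expect_true(all(hit[, 1] == 32))
  expect_gt(nrow(hit), 1)   # ghosts exist
})

test_that("artifact realizations are seeded and reproducible", {
  spec <- build_phantom_spec(90, 4)
  img <- render(spec, phantom_geometry("cartesian"), rng_seed = 1)
  a <- apply_breathing_artifact(img, "cartesian_ghost", 2.5, rng_seed = 7)
  b <- apply_breathing_artifact(img, "cartesian_ghost", 2.5, rng_seed = 7)
  expect_identical(a$data, b$data)
})

test_that("rotational blur degrades fat edges less than coherent ghosting", {
  spec <- build_phantom_spec(172, 101)
  g <- phantom_geometry("cartesian")
  img <- render(spec, g, rng_seed = 5)
  fat <- rasterize_fractions(spec, g, 5)$fat > 0.5
  edge_gradient <- function(image) {
    d <- image$data
    gx <- d[-1, , , drop = FALSE] - d[-dim(d)[1], , , drop = FALSE]
    boundary <- fat[-1, , , drop = FALSE] != fat[-dim(d)[1], , , drop = FALSE]
    mean(abs(gx[boundary]))
  }
  base <- edge_gradient(img)
  cart <- edge_gradient(apply_breathing_artifact(img, "cartesian_ghost", 2.5, 7))
  prop <- edge_gradient(apply_breathing_artifact(img, "propeller_blur", 2.5, 7))
  expect_lt(cart, base)
  expect_lt(prop, base)
  expect_gt(prop, cart)   # rotating blades scatter motion incoherently
})
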
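# Small geometries and degenerate intensity models shared across tests.

tiny_geometry <- function(nx = 40, ny = 40, nz = 4, spacing = 0.9,
                          thickness = 5, gap = 1) {
  acquisition_geometry(c(spacing, spacing), thickness, gap, c(nx, ny, nz))
}

# noiseless two-level contrast: intensities are exactly bg/fat (+ linear
# partial-volume mixtures)
clean_model <- function(...) {
  intensity_model(noise_sigma = 0, bias_field_amplitude = 0,
                  streak_fraction = 0, ...)
}

# a box whose faces lie on voxel boundaries of tiny_geometry() and whose z
# extent spans whole slice pitches -> renders without partial volume
aligned_box <- function(half_x = 9, half_y = 9, half_pitches = 1) {
  box_spec(c(-half_x, half_x), c(-half_y, half_y),
           c(-6 * half_pitches, 6 * half_pitches))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
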
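#' Intensity model for water-suppressed TSE contrast
#'
#' Image-level model of water-suppressed turbo-spin-echo contrast in arbitrary
#' scanner units: water and air are suppressed to a background noise level
#' with an intensity mode near 15, adipose tissue maps to a mode near 420.
#' Partial-volume voxels mix the two linearly by sub-voxel fat volume
#' fraction. On top of this two-point contrast the model applies:
#'
#' * a smooth multiplicative bias field (low-order polynomial, centre-bright
#'   coil-sensitivity shape plus a small seeded random component), emulating
#'   magnetic-field/coil inhomogeneity;
#' * an optional low-intensity "streak" texture inside fat, emulating thin
#'   connective-tissue and water-content structures in lard and adipose
#'   tissue that the water suppression nulls;
#' * additive Gaussian noise, folded to magnitude (absolute value), since the
#'   two tissue modes sit far from zero and a full Rician model adds nothing
#'   at these signal levels.
#'
#' @param background_mode Background (suppressed water/air) intensity mode
#'   (default 15).
#' @param fat_mode Adipose intensity mode (default 420).
#' @param noise_sigma Additive Gaussian noise sd in scanner units (default 12).
#' @param bias_field_order Polynomial order of the bias field (default 2).
#' @param bias_field_amplitude Peak relative amplitude of the bias field
#'   (default 0.12, i.e. multiplicative factors within 1 +/- 0.12).
#' @param streak_fraction Fraction of fat volume occupied by suppressed
#'   streak texture (default 0.15; 0 disables the texture).
#' @param streak_depth Relative intensity drop inside streaks (default 0.75,
#'   i.e. streak voxels sit at 25% of the local fat intensity).
#' @param streak_scale Correlation length of the streak texture in mm
#'   (default 0.9; the septa are at voxel scale, thin relative to the
#'   segmentation's contour smoothing scale).
#' @return An `intensity_model` object.
#' @export
#' @examples
#' intensity_model()                      # study defaults
#' intensity_model(noise_sigma = 0, bias_field_amplitude = 0,
#'                 streak_fraction = 0)   # noiseless two-level contrast
intensity_model <- function(background_mode = 15,
                            fat_mode = 420,
                            noise_sigma = 12,
                            bias_field_order = 2L,
                            bias_field_amplitude = 0.12,
                            streak_fraction = 0.15,
                            streak_depth = 0.75,
                            streak_scale = 0.9) {
  if (!is.finite(background_mode) || !is.finite(fat_mode) ||
      background_mode < 0 || fat_mode <= background_mode) {
    stop_adiposim("Need 0 <= background_mode < fat_mode.",
                  "adiposim_model_error")
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop_adiposim("`noise_sigma` must be >= 0.", "adiposim_model_error")
  }
  if (bias_field_order < 0) {
    stop_adiposim("`bias_field_order` must be >= 0.", "adiposim_model_error")
  }
  if (bias_field_amplitude < 0 || bias_field_amplitude >= 1) {
    stop_adiposim("`bias_field_amplitude` must be in [0, 1).",
                  "adiposim_model_error")
  }
  if (streak_fraction < 0 || streak_fraction >= 1 ||
      streak_depth < 0 || streak_depth > 1 || streak_scale <= 0) {
    stop_adiposim("Invalid streak texture parameters.", "adiposim_model_error")
  }
  structure(
    list(
      background_mode = background_mode,
      fat_mode = fat_mode,
      noise_sigma = noise_sigma,
      bias_field_order = as.integer(bias_field_order),
      bias_field_amplitude = bias_field_amplitude,
      streak_fraction = streak_fraction,
      streak_depth = streak_depth,
      streak_scale = streak_scale
    ),
    class = "intensity_model"
  )
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("<intensity_model>\n")
  cat(sprintf("  modes: background %.0f, fat %.0f (scanner units)\n",
              x$background_mode, x$fat_mode))
  cat(sprintf("  noise sd %.1f; bias order %d amplitude %.2f; streaks %.0f%% at depth %.2f\n",
              x$noise_sigma, x$bias_field_order, x$bias_field_amplitude,
              100 * x$streak_fraction, x$streak_depth))
  invisible(x)
}
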
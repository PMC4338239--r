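#' Render a synthetic spec into a water-suppressed MR-like image
#'
#' Rasterizes the spec's fat (and residual-signal) solids onto the
#' acquisition grid with sub-voxel supersampling, mixes class intensities
#' linearly by volume fraction (partial-volume model), applies the
#' multiplicative bias field and the fat streak texture of the
#' [intensity_model()], and adds magnitude-folded Gaussian noise. Slices
#' integrate over the slice thickness only and are placed at the slice pitch
#' (thickness + gap).
#'
#' The streak texture and the random part of the bias field are derived from
#' the *spec's* seed — they are properties of the anatomy and the scan
#' session — while `rng_seed` drives the noise realization, so repeated
#' renders of one subject share anatomy but not noise.
#'
#' @param spec A phantom, infant or box spec.
#' @param geometry An [acquisition_geometry()]. The spec must fit inside the
#'   field of view, otherwise rendering fails.
#' @param intensity_model An [intensity_model()].
#' @param rng_seed Integer seed for the noise realization.
#' @param offset Rigid world-space displacement (mm, length 3) of the
#'   subject, used for repositioning jitter between repeat scans.
#' @param supersample In-plane supersampling factor per axis (default 5).
#' @return An [image3d()].
#' @export
#' @examples
#' spec <- build_phantom_spec(100, rng_seed = 1)
#' img <- render(spec, phantom_geometry("cartesian"), rng_seed = 1)
render <- function(spec, geometry, intensity_model = adiposim::intensity_model(),
                   rng_seed = 1L, offset = c(0, 0, 0), supersample = 5L) {
  bb <- spec_bbox(spec)
  half <- fov_half_extent(geometry)
  zr <- slab_z_range(geometry)
  if (bb$x[1] - offset[1] < -half[1] || bb$x[2] - offset[1] > half[1] ||
      bb$y[1] - offset[2] < -half[2] || bb$y[2] - offset[2] > half[2] ||
      bb$z[1] - offset[3] < zr[1] - geometry$slice_gap ||
      bb$z[2] - offset[3] > zr[2] + geometry$slice_gap) {
    stop_adiposim("Spec does not fit inside the acquisition field of view.",
                  "adiposim_fov_error")
  }
  fr <- rasterize_fractions(spec, geometry, supersample, offset)
  m <- intensity_model
  texture <- streak_texture(spec, geometry, m, offset)
  effective_fat <- fr$fat * texture + fr$other
  img <- m$background_mode + effective_fat * (m$fat_mode - m$background_mode)
  bias <- bias_field(spec, geometry, m)
  img <- img * bias
  if (m$noise_sigma > 0) {
    noise <- with_seed(rng_seed,
                       array(stats::rnorm(length(img), 0, m$noise_sigma),
                             dim(img)))
    img <- abs(img + noise)  # magnitude image
  }
  image3d(img, geometry, provenance = list(
    spec_class = class(spec)[1], spec_seed = spec$seed,
    rng_seed = as.integer(rng_seed), offset = offset,
    supersample = as.integer(supersample)
  ))
}

# Multiplicative bias field: centre-bright order-2 coil-sensitivity profile
# plus a small seeded random polynomial of the model's order, scaled so the
# field stays within 1 +/- amplitude. Deterministic per spec (scanner set-up
# and subject position do not change between back-to-back repeats).
bias_field <- function(spec, geometry, model) {
  amp <- model$bias_field_amplitude
  n <- geometry$matrix_shape
  if (amp == 0 || model$bias_field_order == 0L) {
    return(array(1, n))
  }
  ax <- axis_centers(geometry)
  half <- fov_half_extent(geometry)
  xh <- ax$x / half[1]
  yh <- ax$y / half[2]
  zh <- ax$z / max(abs(ax$z), 1)
  rho2 <- outer(xh^2, yh^2, `+`)           # nx x ny
  q_det <- 1 - rho2                        # centre-bright paraboloid
  seed <- if (is.null(spec$seed) || is.na(spec$seed)) 0L else spec$seed
  coef <- with_seed(seed + 104729L, stats::runif(6, -1, 1))
  out <- array(0, n)
  for (k in seq_len(n[3])) {
    q_rand <- coef[1] * outer(xh, rep(1, n[2])) +
      coef[2] * outer(rep(1, n[1]), yh) +
      coef[3] * zh[k] +
      coef[4] * outer(xh, yh) +
      coef[5] * outer(xh, rep(1, n[2])) * zh[k] +
      coef[6] * zh[k]^2
    q <- 0.75 * q_det + 0.25 * q_rand / 3
    # the floor only engages in the far corners of the fov, outside any
    # rendered anatomy, so the field stays a polynomial over the object
    out[, , k] <- 1 + amp * pmax(q, -1)
  }
  out
}

# Thin low-intensity streak texture inside fat: smoothed per-slice white
# noise thresholded at the model's streak fraction. Anatomy-locked (seeded
# from the spec), in-plane correlated at `streak_scale`.
streak_texture <- function(spec, geometry, model, offset = c(0, 0, 0)) {
  n <- geometry$matrix_shape
  if (model$streak_fraction == 0 || model$streak_depth == 0) {
    return(array(1, n))
  }
  seed <- if (is.null(spec$seed) || is.na(spec$seed)) 0L else spec$seed
  noise <- with_seed(seed + 7919L, array(stats::rnorm(prod(n)), n))
  sm <- if (model$streak_scale > max(geometry$in_plane_spacing)) {
    k <- gaussian_kernel(model$streak_scale /
                           (2 * mean(geometry$in_plane_spacing)))
    conv_ip(conv_ip(noise, k, 1L), k, 2L)
  } else {
    noise  # at or below voxel scale the septa are independent speckle
  }
  cutoff <- stats::quantile(sm, 1 - model$streak_fraction, names = FALSE)
  1 - model$streak_depth * (sm > cutoff)
}

#' Render repeated scans of one subject
#'
#' Produces `n_repeats` images of identical anatomy with independent noise
#' realizations, small rigid repositioning jitter, and (when an artifact mode
#' is requested) independent breathing-artifact realizations — the in-silico
#' analog of repeating a sequence three or four times for reproducibility
#' measurements. All per-repeat seeds derive deterministically from
#' `rng_seed`.
#'
#' @inheritParams render
#' @param n_repeats Number of repeats (>= 2).
#' @param artifact_mode `"none"`, `"cartesian_ghost"` or `"propeller_blur"`.
#' @param artifact_amplitude Breathing displacement amplitude in mm
#'   (default 2.5; about a 20 ml tidal breath in a young infant).
#' @param jitter_sd Standard deviation (mm) of the per-repeat rigid
#'   repositioning jitter (default 0.4).
#' @return List of [image3d()] of length `n_repeats`.
#' @export
render_repeat_series <- function(spec, geometry,
                                 intensity_model = adiposim::intensity_model(),
                                 n_repeats = 3L, rng_seed = 1L,
                                 artifact_mode = geometry$artifact_mode,
                                 artifact_amplitude = 2.5,
                                 jitter_sd = 0.4,
                                 supersample = 5L) {
  if (n_repeats < 2L) {
    stop_adiposim("`n_repeats` must be >= 2.", "adiposim_spec_error")
  }
  seeds <- derive_seeds(rng_seed, 2L * n_repeats)
  lapply(seq_len(n_repeats), function(i) {
    off <- if (jitter_sd > 0) {
      with_seed(seeds[2L * i - 1L], stats::rnorm(3, 0, jitter_sd))
    } else {
      c(0, 0, 0)
    }
    img <- render(spec, geometry, intensity_model, rng_seed = seeds[2L * i],
                  offset = off, supersample = supersample)
    if (artifact_mode != "none" && artifact_amplitude > 0) {
      img <- apply_breathing_artifact(img, artifact_mode, artifact_amplitude,
                                      rng_seed = seeds[2L * i])
    }
    img
  })
}
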
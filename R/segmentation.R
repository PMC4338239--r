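#' Label mask aligned to an image
#'
#' Integer voxel labels on the acquisition grid: 0 background, 1 adipose;
#' after compartment separation, 2 subcutaneous and 3 intra-abdominal
#' (which partition the adipose voxels).
#'
#' @param labels Integer 3D array with values in \{0, 1, 2, 3\}.
#' @param geometry The [acquisition_geometry()] of the source image.
#' @param meta Optional list of per-run metadata (threshold used, removed
#'   component count, iterations, ...), kept for the JSON run report.
#' @return A `label_mask`.
#' @export
label_mask <- function(labels, geometry, meta = list()) {
  if (!all(dim(labels) == geometry$matrix_shape)) {
    stop_adiposim("Mask dimensions do not match the geometry.",
                  "adiposim_mask_error")
  }
  if (!all(labels %in% 0:3)) {
    stop_adiposim("Labels must be 0 (background), 1 (adipose), 2 (s.c.) or 3 (i.a.).",
                  "adiposim_mask_error")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, geometry = geometry, meta = meta),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("background", "adipose", "subcutaneous",
                                 "intra_abdominal")))
  cat("<label_mask>\n")
  print(tab[tab > 0])
  invisible(x)
}

#' Locate the background and fat modes of an image histogram
#'
#' Water-suppressed TSE images of adipose tissue have a bimodal intensity
#' histogram: a background-noise mode (around 15 in scanner units) and a fat
#' mode (around 420). The finder bins intensities (5-unit bins), smooths the
#' counts, and returns the two most prominent well-separated local maxima.
#'
#' @param image An [image3d()].
#' @param bin_width Histogram bin width (default 5 scanner units).
#' @param min_separation Minimum intensity separation between the two modes
#'   (default 60).
#' @return Named numeric vector `c(background_peak, fat_peak)` with
#'   `background_peak < fat_peak`.
#' @section Errors: fails with class `adiposim_unimodal_error` when no second
#'   mode exists (e.g. a constant image), signalling non-separable classes.
#' @export
find_histogram_peaks <- function(image, bin_width = 5, min_separation = 60) {
  h <- image_histogram(image, bin_width)
  sm <- h$smooth
  n <- length(sm)
  if (n < 3L) {
    stop_adiposim("Histogram is unimodal: classes are not separable.",
                  "adiposim_unimodal_error")
  }
  left <- c(-Inf, sm[-n])
  right <- c(sm[-1L], -Inf)
  is_peak <- sm > left & sm >= right & sm > 0.005 * max(sm)
  cand <- which(is_peak)
  if (length(cand) >= 2L) {
    # greedily keep prominent peaks separated by at least min_separation
    ord <- cand[order(sm[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(h$intensity[i] - h$intensity[kept]) >= min_separation)) {
        kept <- c(kept, i)
      }
      if (length(kept) == 2L) break
    }
    cand <- kept
  }
  if (length(cand) < 2L) {
    stop_adiposim("Histogram is unimodal: classes are not separable.",
                  "adiposim_unimodal_error")
  }
  peaks <- sort(h$intensity[cand])
  c(background_peak = peaks[1], fat_peak = peaks[2])
}

#' Threshold segmentation configuration
#'
#' @param threshold Intensity threshold in scanner units. The study design
#'   places candidate thresholds (150, 250, 350) between the background and
#'   fat histogram modes.
#' @param min_region_volume Minimum physical volume (mm^3) of a connected
#'   region to keep; smaller regions are excluded (default 25).
#' @return A `threshold_config`.
#' @export
threshold_config <- function(threshold = 150, min_region_volume = 25) {
  if (!is.finite(threshold) || threshold <= 0) {
    stop_adiposim("`threshold` must be positive.", "adiposim_config_error")
  }
  if (!is.finite(min_region_volume) || min_region_volume < 0) {
    stop_adiposim("`min_region_volume` must be >= 0.", "adiposim_config_error")
  }
  structure(list(threshold = threshold, min_region_volume = min_region_volume),
            class = "threshold_config")
}

#' Threshold-based adipose segmentation
#'
#' Selects all voxels with signal intensity strictly higher than the
#' threshold (ties go to background), then excludes connected regions
#' smaller than `min_region_volume` via [remove_small_regions()].
#' Deterministic; operates on raw (bias-uncorrected) intensities.
#'
#' @param image An [image3d()].
#' @param config A [threshold_config()].
#' @return A [label_mask()] with labels 0/1.
#' @export
threshold_segment <- function(image, config = threshold_config()) {
  stopifnot(inherits(config, "threshold_config"))
  mask <- image$data > config$threshold
  out <- remove_small_regions(
    label_mask(array(as.integer(mask), dim(mask)), image$geometry),
    config$min_region_volume
  )
  out$meta <- c(out$meta, list(method = "threshold",
                               threshold = config$threshold))
  out
}

#' Exclude small segmented regions
#'
#' Removes connected components whose physical volume is smaller than
#' `min_volume` mm^3. Components are 2D 8-connected within each slice and
#' their volume is in-plane area times slice thickness: with a slice gap of
#' 1 mm or more, through-plane connectivity of thin structures is not
#' physically meaningful for gapped 2D multi-slice data.
#'
#' Idempotent, and never adds voxels.
#'
#' @param mask A [label_mask()].
#' @param min_volume Minimum region volume in mm^3 (default 25); regions with
#'   volume strictly smaller are set to background.
#' @return A [label_mask()].
#' @export
remove_small_regions <- function(mask, min_volume = 25) {
  stopifnot(inherits(mask, "label_mask"))
  if (min_volume <= 0) {
    return(mask)
  }
  g <- mask$geometry
  fg <- mask$labels > 0L
  comp <- label_components_ip8(fg)
  voxel_vol <- prod(g$in_plane_spacing) * g$slice_thickness
  small <- which(comp$sizes * voxel_vol < min_volume)
  labels <- mask$labels
  if (length(small) > 0L) {
    labels[comp$labels %in% small] <- 0L
  }
  label_mask(labels, g, meta = c(mask$meta,
                                 list(removed_components = length(small))))
}

#' Estimate and remove a multiplicative bias field
#'
#' Fits a smooth multiplicative intensity inhomogeneity (coil sensitivity /
#' B-field variation) as a polynomial of the given order in scaled world
#' coordinates, by least squares on the log-intensities of bright (fat-like)
#' voxels, and divides it out. The estimated field is positive everywhere
#' and normalized to mean 1 over the fitted voxels, so tissue intensity
#' scale is preserved while the fat-region coefficient of variation is
#' reduced.
#'
#' @param image An [image3d()].
#' @param order Polynomial order (default 2); `order = 0` or an image
#'   without a separable bright class returns the input unchanged with a
#'   unit field.
#' @return A list with `image` (corrected [image3d()]) and `field` (the
#'   estimated multiplicative field as a 3D array).
#' @export
correct_bias_field <- function(image, order = 2L) {
  if (order < 0) {
    stop_adiposim("`order` must be >= 0.", "adiposim_config_error")
  }
  unit <- list(image = image, field = array(1, dim(image$data)))
  if (order == 0L) {
    return(unit)
  }
  peaks <- tryCatch(find_histogram_peaks(image),
                    adiposim_unimodal_error = function(e) NULL)
  if (is.null(peaks)) {
    return(unit)
  }
  # fit on nearly-pure fat voxels; partial-volume mixtures would tilt the fit
  bright <- image$data > 0.75 * peaks["fat_peak"]
  idx <- which(bright)
  if (length(idx) < 200L) {
    return(unit)
  }
  n <- dim(image$data)
  ax <- axis_centers(image$geometry)
  half <- fov_half_extent(image$geometry)
  coords <- arrayInd(idx, n)
  xh <- ax$x[coords[, 1]] / half[1]
  yh <- ax$y[coords[, 2]] / half[2]
  zh <- ax$z[coords[, 3]] / max(abs(ax$z), 1)
  if (length(idx) > 30000L) {
    keep <- round(seq(1L, length(idx), length.out = 30000L))
    idx_fit <- idx[keep]
    xh_f <- xh[keep]; yh_f <- yh[keep]; zh_f <- zh[keep]
  } else {
    idx_fit <- idx
    xh_f <- xh; yh_f <- yh; zh_f <- zh
  }
  X <- poly_design(xh_f, yh_f, zh_f, order)
  yv <- log(pmax(image$data[idx_fit], 1e-6))
  fit <- stats::lm.fit(X, yv)
  # one trimming pass: drop the worst residuals (residual partial-volume and
  # texture voxels that survived the brightness cut) and refit
  keep <- abs(fit$residuals) <= stats::quantile(abs(fit$residuals), 0.8)
  fit <- stats::lm.fit(X[keep, , drop = FALSE], yv[keep])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  # evaluate the fitted log-field on the full grid
  xg <- ax$x / half[1]
  yg <- ax$y / half[2]
  zg <- ax$z / max(abs(ax$z), 1)
  field <- array(0, n)
  for (k in seq_len(n[3])) {
    Xk <- poly_design(rep(xg, times = n[2]), rep(yg, each = n[1]),
                      rep(zg[k], n[1] * n[2]), order)
    field[, , k] <- matrix(Xk %*% beta, n[1], n[2])
  }
  centre <- mean(field[idx])
  field <- exp(field - centre)
  corrected <- image3d(image$data / field, image$geometry,
                       provenance = c(image$provenance,
                                      list(bias_corrected = TRUE,
                                           bias_order = as.integer(order))))
  list(image = corrected, field = field)
}

# full polynomial design matrix in three scaled coordinates
poly_design <- function(x, y, z, order) {
  terms <- list(rep(1, length(x)))
  for (total in seq_len(order)) {
    for (i in 0:total) {
      for (j in 0:(total - i)) {
        k <- total - i - j
        terms[[length(terms) + 1L]] <- x^i * y^j * z^k
      }
    }
  }
  do.call(cbind, terms)
}

#' Deterministic initial centers for k-means intensity clustering
#'
#' Derives initial cluster centers from the histogram structure instead of
#' random initialization, so the clustering (and everything downstream) is
#' exactly reproducible: the background mode, the fat mode, and for
#' `n_clusters > 2` evenly spaced intermediate centers representing
#' partial-volume mixtures.
#'
#' @param image An [image3d()] (bias-corrected in the k-means pipeline).
#' @param n_clusters Number of clusters (>= 2; default 3:
#'   background / partial-volume / fat).
#' @return Sorted numeric vector of initial centers.
#' @export
estimate_cluster_params <- function(image, n_clusters = 3L) {
  if (n_clusters < 2L) {
    stop_adiposim("`n_clusters` must be >= 2.", "adiposim_config_error")
  }
  peaks <- find_histogram_peaks(image)
  seq(peaks[["background_peak"]], peaks[["fat_peak"]],
      length.out = n_clusters)
}

#' k-means pipeline configuration
#'
#' @param n_clusters Number of intensity clusters (default 3).
#' @param bias_order Polynomial order of the bias-field correction
#'   (default 2).
#' @param contour_iterations Active-contour refinement iterations
#'   (default 12).
#' @param contour_smoothing Binary-median smoothing passes per contour
#'   iteration (default 1); 0 disables boundary regularization.
#' @param presmooth_fwhm In-plane Gaussian denoising FWHM in mm applied to
#'   the bias-corrected image before parameter estimation, clustering and
#'   contour refinement (default `NULL` = 1.1 in-plane voxels, so the
#'   denoising scale follows the acquisition resolution; 0 disables).
#'   Intensity clustering on
#'   raw magnitude data is dominated by voxel-scale noise and texture; a
#'   sub-voxel-scale smooth is the standard preprocessing step. The
#'   threshold pipeline deliberately stays on raw intensities.
#' @param contour_lambda_out Chan-Vese weight of the outside-region variance
#'   term relative to the inside term (default 2). Values above 1 penalize
#'   misclassifying voxels as background more than as adipose, which is the
#'   standard weighting when the inside class (fat with partial-volume and
#'   texture spread) has much larger variance than the suppressed
#'   background; the contour then includes the partial-volume rim.
#' @param convergence_tol Upper bound on the relative center movement at
#'   which clustering is declared converged (default 1e-3; the Lloyd
#'   iterations used run to full assignment stability, which satisfies any
#'   positive tolerance).
#' @param min_region_volume Small-region exclusion threshold in mm^3
#'   (default 25).
#' @return A `cluster_config`.
#' @export
cluster_config <- function(n_clusters = 3L, bias_order = 2L,
                           contour_iterations = 12L, contour_smoothing = 1L,
                           presmooth_fwhm = NULL, contour_lambda_out = 1.6,
                           convergence_tol = 1e-3, min_region_volume = 25) {
  if (n_clusters < 2L || contour_iterations < 0L || contour_smoothing < 0L ||
      (!is.null(presmooth_fwhm) && presmooth_fwhm < 0) ||
      contour_lambda_out <= 0 ||
      convergence_tol <= 0 || min_region_volume < 0) {
    stop_adiposim("Invalid cluster_config parameters.",
                  "adiposim_config_error")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 bias_order = as.integer(bias_order),
                 contour_iterations = as.integer(contour_iterations),
                 contour_smoothing = as.integer(contour_smoothing),
                 presmooth_fwhm = presmooth_fwhm,
                 contour_lambda_out = contour_lambda_out,
                 convergence_tol = convergence_tol,
                 min_region_volume = min_region_volume),
            class = "cluster_config")
}

#' k-means clustering segmentation with active-contour refinement
#'
#' The four-stage semi-automatic segmentation pipeline: (i) bias-field
#' correction ([correct_bias_field()]), (ii) deterministic parameter
#' estimation for the clustering ([estimate_cluster_params()]), (iii)
#' k-means clustering of the corrected intensities, and (iv) adipose
#' detection by a region-based active contour: starting from the
#' highest-center cluster, voxels are iteratively reassigned to minimize the
#' within/outside intensity variance (two-phase piecewise-constant model)
#' with a binary-median curvature regularizer that smooths the boundary and
#' bridges thin signal voids. Small regions are then excluded as in the
#' threshold pipeline. Fully deterministic for a given image and config.
#'
#' @param image An [image3d()].
#' @param config A [cluster_config()].
#' @return A [label_mask()] with labels 0/1; `meta` records the cluster
#'   centers and iteration count.
#' @export
kmeans_segment <- function(image, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  bc <- correct_bias_field(image, config$bias_order)
  corrected <- bc$image
  presmooth_fwhm <- config$presmooth_fwhm %||%
    (1.1 * mean(image$geometry$in_plane_spacing))
  if (presmooth_fwhm > 0) {
    sigma_px <- presmooth_fwhm / 2.355 /
      mean(image$geometry$in_plane_spacing)
    k <- gaussian_kernel(sigma_px)
    corrected <- image3d(conv_ip(conv_ip(corrected$data, k, 1L), k, 2L),
                         image$geometry, corrected$provenance)
  }
  centers <- estimate_cluster_params(corrected, config$n_clusters)
  v <- as.vector(corrected$data)
  km <- suppressWarnings(
    stats::kmeans(v, centers = matrix(centers, ncol = 1),
                  iter.max = 50L, algorithm = "Lloyd")
  )
  fitted_centers <- as.vector(km$centers)
  top <- which.max(fitted_centers)
  mask <- array(km$cluster == top, dim(corrected$data))
  mask <- acwe_refine(corrected$data, mask, config$contour_iterations,
                      config$contour_smoothing, config$contour_lambda_out)
  out <- remove_small_regions(
    label_mask(array(as.integer(mask), dim(mask)), image$geometry),
    config$min_region_volume
  )
  out$meta <- c(out$meta, list(
    method = "kmeans",
    centers = fitted_centers,
    kmeans_iterations = km$iter,
    contour_iterations = config$contour_iterations
  ))
  out
}

# Region-based (two-phase, variance-minimizing) morphological active
# contour: alternate optimal reassignment against the inside/outside means
# (with the Chan-Vese lambda weighting) and binary-median curvature
# smoothing; the final pass is a smoothing pass, so thin refilled voids
# persist in the result.
acwe_refine <- function(intensities, mask, iterations, smoothing,
                        lambda_out = 1.6) {
  if (iterations == 0L) {
    return(mask)
  }
  for (it in seq_len(iterations)) {
    n_in <- sum(mask)
    if (n_in == 0L || n_in == length(mask)) break
    c_in <- mean(intensities[mask])
    c_out <- mean(intensities[!mask])
    mask <- (intensities - c_in)^2 < lambda_out * (intensities - c_out)^2
    if (smoothing > 0L) {
      for (s in seq_len(smoothing)) mask <- binary_majority_ip(mask)
    }
  }
  mask
}

#' Separate subcutaneous from intra-abdominal adipose tissue
#'
#' Splits an adipose mask into a subcutaneous and an intra-abdominal
#' compartment. The body outline is built per slice by morphological closing
#' of the adipose mask and filling of its enclosed interior; adipose
#' components (2D, 8-connected) touching the body-surface shell are labelled
#' subcutaneous (2), all remaining internal adipose intra-abdominal (3). The
#' two labels always partition the input adipose voxels.
#'
#' When the subcutaneous ring fails to enclose an interior (an open body
#' outline, e.g. a shell with a wide gap), the result is flagged low
#' confidence: `attr(mask, "low_confidence")` is `TRUE` and a warning is
#' raised.
#'
#' @param mask A [label_mask()] with adipose voxels (labels > 0).
#' @param image The source [image3d()] (reserved for contrast-based outline
#'   refinements; the default body outline uses the mask only, since
#'   everything inside the body except fat is water-suppressed).
#' @param closing_radius Morphological closing iterations used to seal small
#'   partial-volume pores in the shell before filling (default 2).
#' @return A [label_mask()] with labels 2 (subcutaneous) and
#'   3 (intra-abdominal).
#' @export
split_compartments <- function(mask, image = NULL, closing_radius = 2L) {
  stopifnot(inherits(mask, "label_mask"))
  adipose <- mask$labels > 0L
  closed <- closing_ip(adipose, closing_radius)
  body <- fill_slicewise(closed)
  interior <- body & !closed
  # open body outline: the ring fails to enclose an interior on most of the
  # adipose-bearing slices (isolated end slices with thin, broken rings are
  # normal where the fat shell tapers out)
  ad_area <- apply(adipose, 3L, sum)
  int_area <- apply(interior, 3L, sum)
  carrying <- ad_area > 50
  suspect <- carrying & int_area < 0.2 * ad_area
  low_confidence <- sum(carrying) > 0L && sum(suspect) > 0.3 * sum(carrying)
  band <- body & !erode_ip(body, 2L)
  comp <- label_components_ip8(adipose)
  touching <- unique(comp$labels[band & adipose])
  touching <- touching[touching > 0L]
  labels <- array(0L, dim(adipose))
  labels[adipose] <- 3L
  labels[comp$labels %in% touching] <- 2L
  out <- label_mask(labels, mask$geometry,
                    meta = c(mask$meta,
                             list(split = "surface-connected",
                                  low_confidence = low_confidence)))
  attr(out, "low_confidence") <- low_confidence
  if (low_confidence) {
    warning("Open body outline: compartment split is low confidence.",
            call. = FALSE)
  }
  out
}

# Fill enclosed interior per slice (holes in the 2D body outline).
fill_slicewise <- function(mask) {
  arr <- array(as.integer(mask), dim(mask))
  filled <- EBImage::fillHull(arr)
  filled > 0
}
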
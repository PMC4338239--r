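#' Plot one slice of a 3D image
#'
#' @param image An [image3d()].
#' @param slice Slice index (default: middle slice).
#' @return A ggplot object.
#' @export
plot_image_slice <- function(image, slice = NULL) {
  stopifnot(inherits(image, "image3d"))
  nz <- dim(image$data)[3]
  if (is.null(slice)) slice <- (nz + 1L) %/% 2L
  ax <- axis_centers(image$geometry)
  df <- tidyr::expand_grid(y = ax$y, x = ax$x) |>
    dplyr::mutate(intensity = as.vector(image$data[, , slice]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", fill = "a.u.",
                  title = sprintf("slice %d (z = %.0f mm)", slice,
                                  ax$z[slice]))
}

#' Plot an image intensity histogram with its detected modes
#'
#' @param image An [image3d()].
#' @param bin_width Histogram bin width (default 5).
#' @return A ggplot object; the background and fat modes, when separable,
#'   are marked with vertical lines.
#' @export
plot_intensity_histogram <- function(image, bin_width = 5) {
  h <- image_histogram(image, bin_width)
  peaks <- tryCatch(find_histogram_peaks(image, bin_width),
                    adiposim_unimodal_error = function(e) NULL)
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$intensity, .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey40") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "intensity [a.u.]", y = "voxels")
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_vline(xintercept = unname(peaks),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @method autoplot phantom_accuracy_study
#' @export
autoplot.phantom_accuracy_study <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(.data$method, .data$rms_error_pct,
                               fill = .data$motion)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sequence)) +
    ggplot2::labs(y = "RMS accuracy error [%]", x = NULL,
                  title = "In-silico phantom accuracy")
}

#' @method autoplot infant_repro_study
#' @export
autoplot.infant_repro_study <- function(object, ...) {
  ggplot2::ggplot(object$reproducibility,
                  ggplot2::aes(.data$method, .data$rms_cv_pct,
                               fill = .data$sequence_mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$compartment), scales = "free_y") +
    ggplot2::labs(y = "RMS-CV [%]", x = NULL,
                  title = "In-silico repeat-scan reproducibility")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
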
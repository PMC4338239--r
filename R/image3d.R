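#' 3D scalar image with acquisition geometry
#'
#' Container for a rendered (or loaded) 3D scalar MR-like image: a numeric
#' array ordered (x, y, slice) plus the [acquisition_geometry()] it was
#' sampled on and a provenance record (spec class, seeds, offsets) that makes
#' renders reproducible.
#'
#' @param data Numeric 3D array of finite, non-negative intensities.
#' @param geometry An [acquisition_geometry()]; its `matrix_shape` must match
#'   `dim(data)`.
#' @param provenance Optional list describing how the image was produced.
#' @return An `image3d` object.
#' @export
image3d <- function(data, geometry, provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_adiposim("`data` must be a 3D array.", "adiposim_image_error")
  }
  if (!all(dim(data) == geometry$matrix_shape)) {
    stop_adiposim("Image dimensions do not match `geometry$matrix_shape`.",
                  "adiposim_image_error")
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop_adiposim("Image intensities must be finite and non-negative.",
                  "adiposim_image_error")
  }
  structure(
    list(data = data, geometry = geometry, provenance = provenance),
    class = "image3d"
  )
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$data)
  cat("<image3d>", sprintf("%d x %d x %d slices,", d[1], d[2], d[3]),
      sprintf("intensities [%.1f, %.1f]\n", min(x$data), max(x$data)))
  print(x$geometry)
  invisible(x)
}

#' @export
as.array.image3d <- function(x, ...) x$data

#' @export
dim.image3d <- function(x) dim(x$data)

#' Write / read an image as NIfTI-1 with a JSON sidecar
#'
#' Images are stored as `.nii.gz` with voxel spacing
#' `(dx, dy, slice_thickness + slice_gap)` — each slice represents its full
#' slab of one pitch — while the true slice thickness, gap, artifact mode and
#' provenance are recorded in a JSON sidecar next to the NIfTI file.
#'
#' @param image An [image3d()].
#' @param path Output path; `".nii"`/`".nii.gz"` extension expected.
#' @return `write_image3d` returns `path` invisibly; `read_image3d` returns
#'   the restored [image3d()].
#' @export
write_image3d <- function(image, path) {
  stopifnot(inherits(image, "image3d"))
  g <- image$geometry
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- c(g$in_plane_spacing, slice_pitch(g))
  RNifti::writeNifti(nii, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(
      in_plane_spacing = g$in_plane_spacing,
      slice_thickness = g$slice_thickness,
      slice_gap = g$slice_gap,
      matrix_shape = g$matrix_shape,
      artifact_mode = g$artifact_mode,
      provenance = image$provenance
    ),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_image3d
#' @export
read_image3d <- function(path) {
  nii <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) {
    stop_adiposim("Missing JSON sidecar for NIfTI image.", "adiposim_io_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  geometry <- acquisition_geometry(
    in_plane_spacing = meta$in_plane_spacing,
    slice_thickness = meta$slice_thickness,
    slice_gap = meta$slice_gap,
    matrix_shape = meta$matrix_shape,
    artifact_mode = meta$artifact_mode
  )
  data <- array(as.numeric(nii), dim = dim(nii))
  image3d(data, geometry, provenance = meta$provenance %||% list())
}

#' Intensity histogram of an image as a tibble
#'
#' Bins intensities into `bin_width`-wide bins centred on multiples of
#' `bin_width`, the representation used by the histogram-peak finder.
#'
#' @param image An [image3d()].
#' @param bin_width Bin width in scanner units (default 5).
#' @return A tibble with `intensity` (bin centre), `count` and a smoothed
#'   count used for mode detection.
#' @export
image_histogram <- function(image, bin_width = 5) {
  v <- as.vector(image$data)
  centre <- round(v / bin_width)
  tab <- tabulate(centre + 1L)
  counts <- tibble::tibble(
    intensity = (seq_along(tab) - 1L) * bin_width,
    count = as.numeric(tab)
  )
  k <- c(1, 2, 3, 2, 1) / 9
  n <- nrow(counts)
  padded <- c(0, 0, counts$count, 0, 0)
  smooth <- vapply(seq_len(n), function(i) sum(padded[i:(i + 4)] * k), 0)
  counts$smooth <- smooth
  counts
}
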
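#' Acquisition geometry of a gapped 2D multi-slice MR scan
#'
#' Describes the voxel lattice of a 2D multi-slice turbo-spin-echo style
#' acquisition: anisotropic in-plane spacing, slice thickness, and a slice gap
#' (unimaged tissue between slices). Slices are placed at a pitch of
#' `slice_thickness + slice_gap`; voxel values integrate signal over the slice
#' thickness only. The grid is centred on the world origin, with world
#' coordinates in millimetres and array axes ordered (x, y, slice).
#'
#' @param in_plane_spacing Numeric pair, in-plane voxel spacing in mm
#'   (default 0.9 x 0.9, the cartesian protocol; the PROPELLER protocol uses
#'   1.1 x 1.1).
#' @param slice_thickness Slice thickness in mm (default 5).
#' @param slice_gap Gap between slices in mm (default 1).
#' @param matrix_shape Integer triple: voxels along x, y and number of slices.
#' @param artifact_mode One of `"none"`, `"cartesian_ghost"`,
#'   `"propeller_blur"`; the breathing-artifact surrogate associated with the
#'   acquisition.
#' @return An `acquisition_geometry` object.
#' @seealso [phantom_geometry()], [infant_geometry()], [slice_centers()]
#' @export
#' @examples
#' g <- acquisition_geometry(matrix_shape = c(64, 64, 8))
#' slice_pitch(g)
acquisition_geometry <- function(in_plane_spacing = c(0.9, 0.9),
                                 slice_thickness = 5,
                                 slice_gap = 1,
                                 matrix_shape = c(214, 132, 10),
                                 artifact_mode = c("none", "cartesian_ghost",
                                                   "propeller_blur")) {
  artifact_mode <- match.arg(artifact_mode)
  in_plane_spacing <- as.numeric(in_plane_spacing)
  if (length(in_plane_spacing) == 1L) {
    in_plane_spacing <- rep(in_plane_spacing, 2L)
  }
  if (length(in_plane_spacing) != 2L || any(!is.finite(in_plane_spacing)) ||
      any(in_plane_spacing <= 0)) {
    stop_adiposim("`in_plane_spacing` must be two positive numbers (mm).",
                  "adiposim_geometry_error")
  }
  if (!is.finite(slice_thickness) || slice_thickness <= 0) {
    stop_adiposim("`slice_thickness` must be a positive number (mm).",
                  "adiposim_geometry_error")
  }
  if (!is.finite(slice_gap) || slice_gap < 0) {
    stop_adiposim("`slice_gap` must be >= 0 (mm).", "adiposim_geometry_error")
  }
  matrix_shape <- as.integer(matrix_shape)
  if (length(matrix_shape) != 3L || any(is.na(matrix_shape)) ||
      any(matrix_shape < 1L)) {
    stop_adiposim("`matrix_shape` must be three integers >= 1.",
                  "adiposim_geometry_error")
  }
  structure(
    list(
      in_plane_spacing = in_plane_spacing,
      slice_thickness = slice_thickness,
      slice_gap = slice_gap,
      matrix_shape = matrix_shape,
      artifact_mode = artifact_mode
    ),
    class = "acquisition_geometry"
  )
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("<acquisition_geometry>\n")
  cat(sprintf("  voxels: %d x %d x %d slices\n", x$matrix_shape[1],
              x$matrix_shape[2], x$matrix_shape[3]))
  cat(sprintf("  spacing: %.2f x %.2f mm in-plane, %.1f mm slices + %.1f mm gap\n",
              x$in_plane_spacing[1], x$in_plane_spacing[2],
              x$slice_thickness, x$slice_gap))
  cat(sprintf("  artifact mode: %s\n", x$artifact_mode))
  invisible(x)
}

#' @rdname acquisition_geometry
#' @export
slice_pitch <- function(geometry) {
  geometry$slice_thickness + geometry$slice_gap
}

#' Voxel centre coordinates of a geometry
#'
#' World (mm) coordinates of voxel centres along each axis; the grid is
#' centred on the origin. Slice centres are spaced at the slice pitch
#' (thickness + gap).
#'
#' @param geometry An [acquisition_geometry()].
#' @return For `slice_centers`, the slice-centre z coordinates; for
#'   `axis_centers`, a list with elements `x`, `y`, `z`.
#' @export
slice_centers <- function(geometry) {
  nz <- geometry$matrix_shape[3L]
  (seq_len(nz) - (nz + 1) / 2) * slice_pitch(geometry)
}

#' @rdname slice_centers
#' @export
axis_centers <- function(geometry) {
  n <- geometry$matrix_shape
  sp <- geometry$in_plane_spacing
  list(
    x = (seq_len(n[1L]) - (n[1L] + 1) / 2) * sp[1L],
    y = (seq_len(n[2L]) - (n[2L] + 1) / 2) * sp[2L],
    z = slice_centers(geometry)
  )
}

# In-plane field-of-view half-extents (mm), measured to voxel edges.
fov_half_extent <- function(geometry) {
  n <- geometry$matrix_shape
  sp <- geometry$in_plane_spacing
  c(n[1L] * sp[1L] / 2, n[2L] * sp[2L] / 2)
}

# z range covered by slice slabs (thickness only, outermost edges).
slab_z_range <- function(geometry) {
  zc <- slice_centers(geometry)
  c(min(zc) - geometry$slice_thickness / 2,
    max(zc) + geometry$slice_thickness / 2)
}

#' Study geometries for the two sequence protocols
#'
#' Convenience constructors reproducing the two acquisition protocols of the
#' study design: a cartesian water-suppressed TSE at 0.9 x 0.9 x 5 mm and a
#' PROPELLER water-suppressed TSE at 1.1 x 1.1 x 5 mm, both with a 1 mm slice
#' gap. The matrix shapes are sized to the desk-scale phantom and infant
#' models shipped with the package.
#'
#' @param sequence `"cartesian"` or `"propeller"`. Selects in-plane
#'   resolution and the matching breathing-artifact surrogate
#'   (coherent ghosting vs rotational blur).
#' @return An [acquisition_geometry()].
#' @export
phantom_geometry <- function(sequence = c("cartesian", "propeller")) {
  sequence <- match.arg(sequence)
  if (sequence == "cartesian") {
    acquisition_geometry(c(0.9, 0.9), 5, 1, c(214, 132, 10), "cartesian_ghost")
  } else {
    acquisition_geometry(c(1.1, 1.1), 5, 1, c(176, 108, 10), "propeller_blur")
  }
}

#' @rdname phantom_geometry
#' @export
infant_geometry <- function(sequence = c("cartesian", "propeller")) {
  sequence <- match.arg(sequence)
  if (sequence == "cartesian") {
    acquisition_geometry(c(0.9, 0.9), 5, 1, c(156, 112, 26), "cartesian_ghost")
  } else {
    acquisition_geometry(c(1.1, 1.1), 5, 1, c(128, 92, 26), "propeller_blur")
  }
}
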
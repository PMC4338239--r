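#' Physical volume of a labelled compartment
#'
#' Converts voxel counts to millilitres under the acquisition geometry. By
#' default each slice represents its full slab of one pitch
#' (`slice_thickness + slice_gap`): gapped 2D multi-slice protocols image
#' only the slice thickness, and whole-body volumes extrapolate across the
#' unimaged gap by pitch scaling. `slab = "thickness"` restricts the volume
#' to imaged tissue only, for sensitivity analyses of the gap handling.
#'
#' @param mask A [label_mask()].
#' @param label Integer label(s) to count; `NULL` (default) counts all
#'   non-background voxels.
#' @param slab `"pitch"` (default) or `"thickness"`.
#' @return Volume in ml.
#' @export
#' @examples
#' g <- acquisition_geometry(c(0.9, 0.9), 5, 1, c(10, 10, 10))
#' m <- label_mask(array(1L, c(10, 10, 10)), g)
#' mask_volume(m)   # 1000 voxels x 0.81 mm^2 x 6 mm = 4.86 ml
mask_volume <- function(mask, label = NULL, slab = c("pitch", "thickness")) {
  stopifnot(inherits(mask, "label_mask"))
  slab <- match.arg(slab)
  g <- mask$geometry
  count <- if (is.null(label)) {
    sum(mask$labels > 0L)
  } else {
    sum(mask$labels %in% as.integer(label))
  }
  depth <- if (slab == "pitch") slice_pitch(g) else g$slice_thickness
  count * prod(g$in_plane_spacing) * depth / 1000
}

#' Convert adipose volume to mass
#'
#' Adipose tissue mass from volume at a density of 0.925 g/cm^3.
#'
#' @param volume Volume(s) in ml; must be >= 0.
#' @return Mass in grams.
#' @export
#' @examples
#' volume_to_mass(100)   # 92.5 g
volume_to_mass <- function(volume) {
  if (any(!is.finite(volume)) || any(volume < 0)) {
    stop_adiposim("`volume` must be finite and >= 0.", "adiposim_volume_error")
  }
  volume * 0.925
}

#' Measure a mask into long-format measurement rows
#'
#' Emits one tidy row per compartment present in the mask (total adipose,
#' plus subcutaneous / intra-abdominal when the mask is split), with volume
#' and mass, ready to append to a measurement table for the statistics
#' module.
#'
#' @param mask A [label_mask()].
#' @param subject_id,repeat_idx,method,sequence_mode Identifying columns for
#'   the measurement table.
#' @return A tibble with columns `subject_id`, `repeat_idx`, `method`,
#'   `sequence_mode`, `compartment`, `volume_ml`, `mass_g`.
#' @export
measure_mask <- function(mask, subject_id = NA_character_,
                         repeat_idx = NA_integer_, method = NA_character_,
                         sequence_mode = NA_character_) {
  stopifnot(inherits(mask, "label_mask"))
  rows <- list(
    tibble::tibble(compartment = "total",
                   volume_ml = mask_volume(mask))
  )
  if (any(mask$labels == 2L) || any(mask$labels == 3L)) {
    rows <- c(rows, list(
      tibble::tibble(compartment = "subcutaneous",
                     volume_ml = mask_volume(mask, 2L)),
      tibble::tibble(compartment = "intra_abdominal",
                     volume_ml = mask_volume(mask, 3L))
    ))
  }
  out <- dplyr::bind_rows(rows)
  tibble::tibble(
    subject_id = subject_id,
    repeat_idx = repeat_idx,
    method = method,
    sequence_mode = sequence_mode,
    compartment = out$compartment,
    volume_ml = out$volume_ml,
    mass_g = volume_to_mass(out$volume_ml)
  )
}
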
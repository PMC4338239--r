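# Sub-voxel rasterization of spec components onto an acquisition grid.
#
# Partial-volume handling: each voxel's class fraction is the fraction of
# `supersample`^2 in-plane sub-points (at the slice's sampled z positions)
# falling inside the component. Extruded components factor exactly into an
# in-plane footprint times a closed-form through-slab z coverage (the limit
# of infinite z supersampling); fully 3D components are sampled at
# `supersample` z positions across the slice thickness. Slices integrate over
# the slice thickness only; the gap between slices is never sampled — exactly
# how gapped 2D multi-slice acquisitions see the object.

# supersampled in-plane coordinates aligned to voxel blocks
supersampled_axis <- function(centers, spacing, s) {
  offsets <- ((seq_len(s) - 0.5) / s - 0.5) * spacing
  as.vector(t(outer(centers, offsets, `+`)))
}

# fraction of the slab [zc - th/2, zc + th/2] covered by [z1, z2]
slab_coverage <- function(zc, thickness, z_range) {
  lo <- pmax(z_range[1], zc - thickness / 2)
  hi <- pmin(z_range[2], zc + thickness / 2)
  pmax(0, hi - lo) / thickness
}

# Returns list(fat = nx x ny x nz fraction array,
#              other = level-weighted fraction array for non-fat signal).
rasterize_fractions <- function(spec, geometry, supersample = 5L,
                                offset = c(0, 0, 0)) {
  s <- as.integer(supersample)
  n <- geometry$matrix_shape
  ax <- axis_centers(geometry)
  th <- geometry$slice_thickness
  xs <- supersampled_axis(ax$x, geometry$in_plane_spacing[1], s) - offset[1]
  ys <- supersampled_axis(ax$y, geometry$in_plane_spacing[2], s) - offset[2]
  zc <- ax$z - offset[3]

  xg <- matrix(rep(xs, times = length(ys)), length(xs), length(ys))
  yg <- matrix(rep(ys, each = length(xs)), length(xs), length(ys))

  fat <- array(0, n)
  other <- array(0, n)

  for (comp in spec_components(spec)) {
    target <- if (comp$channel == "fat") "fat" else "other"
    w <- if (comp$channel == "fat") 1 else comp$level
    if (comp$kind == "extruded") {
      fr2d <- block_average(
        matrix(as.numeric(comp$indicator_xy(xg, yg)), nrow(xg), ncol(xg)), s
      )
      if (!any(fr2d > 0)) next
      zcov <- slab_coverage(zc, th, comp$z_range)
      for (k in which(zcov > 0)) {
        if (target == "fat") {
          fat[, , k] <- fat[, , k] + fr2d * zcov[k]
        } else {
          other[, , k] <- other[, , k] + w * fr2d * zcov[k]
        }
      }
    } else {
      bb <- comp$bbox
      ix <- which(ax$x - offset[1] >= bb$x[1] - geometry$in_plane_spacing[1] &
                    ax$x - offset[1] <= bb$x[2] + geometry$in_plane_spacing[1])
      iy <- which(ax$y - offset[2] >= bb$y[1] - geometry$in_plane_spacing[2] &
                    ax$y - offset[2] <= bb$y[2] + geometry$in_plane_spacing[2])
      kz <- which(zc + th / 2 >= bb$z[1] & zc - th / 2 <= bb$z[2])
      if (!length(ix) || !length(iy) || !length(kz)) next
      sx <- ((min(ix) - 1L) * s + 1L):(max(ix) * s)
      sy <- ((min(iy) - 1L) * s + 1L):(max(iy) * s)
      xg_s <- xg[sx, sy, drop = FALSE]
      yg_s <- yg[sx, sy, drop = FALSE]
      dz <- ((seq_len(s) - 0.5) / s - 0.5) * th
      for (k in kz) {
        acc <- matrix(0, nrow(xg_s), ncol(xg_s))
        for (d in dz) {
          acc <- acc + comp$indicator_xyz(xg_s, yg_s,
                                          matrix(zc[k] + d, nrow(xg_s),
                                                 ncol(xg_s)))
        }
        fr <- block_average(acc / s, s)
        xi <- min(ix):max(ix)
        yi <- min(iy):max(iy)
        if (target == "fat") {
          fat[xi, yi, k] <- fat[xi, yi, k] + fr
        } else {
          other[xi, yi, k] <- other[xi, yi, k] + w * fr
        }
      }
    }
  }
  fat <- pmin(fat, 1)
  list(fat = fat, other = other)
}
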
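#' Build a lard-layer phantom spec with a known fat volume
#'
#' Constructs the in-silico analog of the accuracy phantoms: two water-filled
#' tubes (total diameter about 15 cm) with an empty breathing tube between
#' them, wrapped in nested layers of lard 2-4 mm thick and about 5 cm wide.
#' Successive wraps are separated radially by a thin signal-void gap (the
#' sealed plastic bags the lard is kept in), which gives the phantom the high
#' surface-to-volume ratio that makes partial-volume segmentation errors
#' visible. The last layer's arc and width are solved analytically so the
#' total fat volume lands on `target_volume` (well within the 5% contract).
#'
#' @param target_volume Target total fat volume in ml; must be in
#'   \[20, 500\], and large targets (above roughly 430 ml, depending on the
#'   draw) can exhaust the available wrap slots, which raises an explicit
#'   infeasibility error rather than silently truncating.
#' @param rng_seed Integer seed; the same target and seed always reproduce
#'   the identical spec.
#' @return A `phantom_spec` with elements `tube_radii` (two water tubes and
#'   the air tube), `tube_centers`, `layers` (a tibble with radii, arc
#'   placement, width and z offset per wrap) and `true_fat_volume` (ml,
#'   analytic).
#' @export
#' @examples
#' spec <- build_phantom_spec(172, rng_seed = 7)
#' spec$true_fat_volume
build_phantom_spec <- function(target_volume, rng_seed) {
  if (!is.finite(target_volume) || target_volume < 20 || target_volume > 500) {
    stop_adiposim("`target_volume` must be in [20, 500] ml.",
                  "adiposim_spec_error")
  }
  water_radius <- 30
  air_radius <- 7
  tube_x <- c(-(water_radius + air_radius + 0.5),
              water_radius + air_radius + 0.5)
  tube_sep <- diff(tube_x)
  wrap_gap <- 2.2    # bag walls + trapped air between wraps (signal void)
  first_gap <- 0.75  # bag between tube and innermost wrap
  max_slots <- 5L    # wraps per tube

  target_mm3 <- target_volume * 1000

  # Wraps of the two tubes must not interpenetrate: a wrap of outer radius
  # r_out stays on its own side of the inter-tube bisector iff its arc
  # avoids the sector facing the other tube by half-angle acos((sep/2)/r_out).
  facing_half_angle <- function(r_out) {
    if (r_out <= tube_sep / 2) 0 else acos((tube_sep / 2) / r_out) + 0.02
  }

  with_seed(rng_seed, {
    layers <- list()
    outer_r <- rep(water_radius + first_gap, 2L) # running outer radius per tube
    slots_used <- c(0L, 0L)
    remaining <- target_mm3

    max_slot_volume <- function(r_in) {
      ext <- 2 * pi - 2 * facing_half_angle(r_in + 4)
      0.5 * ext * ((r_in + 4)^2 - r_in^2) * 55
    }
    capacity_left <- function() {
      tot <- 0
      for (tube in 1:2) {
        r <- outer_r[tube]
        for (s in seq_len(max_slots - slots_used[tube])) {
          tot <- tot + max_slot_volume(r)
          r <- r + 4 + wrap_gap
        }
      }
      tot
    }

    tube <- 1L
    while (remaining > 0.005 * target_mm3) {
      if (all(slots_used >= max_slots)) {
        stop_adiposim(
          sprintf(paste0("Cannot place enough lard layers for a target of ",
                         "%.0f ml: all wrap slots exhausted."), target_volume),
          "adiposim_infeasible_error"
        )
      }
      if (slots_used[tube] >= max_slots) tube <- 3L - tube
      r_in <- outer_r[tube]
      # Draw layer parameters, biased towards thick full wraps when the
      # remaining volume is large relative to the remaining capacity.
      rho <- min(1, remaining / max(capacity_left(), 1))
      thickness <- min(4, max(2, 2.4 + 1.6 * rho^0.7 + stats::runif(1, -0.3, 0.3)))
      width <- min(55, max(46, 48 + 7 * rho + stats::runif(1, -1.5, 1.5)))
      z_offset <- stats::runif(1, -2, 2)
      r_out <- r_in + thickness
      # the angle of the tube-facing axis this wrap must keep clear of
      facing <- if (tube == 1L) 0 else pi
      avoid <- facing_half_angle(r_out)
      max_extent <- 2 * pi - 2 * avoid
      extent <- if (rho > 0.7) max_extent else {
        min(max_extent, 4.8 + 1.6 * rho + stats::runif(1, -0.3, 0.3))
      }
      vol <- 0.5 * extent * (r_out^2 - r_in^2) * width

      if (vol >= remaining) {
        # Final layer: solve the arc (and if needed the width) for an exact
        # landing on the target volume.
        extent <- 2 * remaining / ((r_out^2 - r_in^2) * width)
        if (extent < 0.35) {
          width <- max(8, 2 * remaining / ((r_out^2 - r_in^2) * 0.35))
          extent <- 2 * remaining / ((r_out^2 - r_in^2) * width)
        }
        vol <- 0.5 * extent * (r_out^2 - r_in^2) * width
      }
      arc_start <- facing + avoid +
        stats::runif(1, 0, max(0, max_extent - extent))
      layers[[length(layers) + 1L]] <- tibble::tibble(
        tube = tube, r_in = r_in, r_out = r_out, arc_start = arc_start,
        arc_extent = extent, width = width, z_offset = z_offset,
        volume_mm3 = vol
      )
      remaining <- remaining - vol
      outer_r[tube] <- r_out + wrap_gap
      slots_used[tube] <- slots_used[tube] + 1L
      tube <- 3L - tube
    }
    layers <- dplyr::bind_rows(layers)
    structure(
      list(
        tube_radii = c(water = water_radius, water = water_radius,
                       air = air_radius),
        tube_centers = tube_x,
        layer_count = nrow(layers),
        layers = layers,
        true_fat_volume = sum(layers$volume_mm3) / 1000,
        target_volume = target_volume,
        seed = as.integer(rng_seed)
      ),
      class = c("phantom_spec", "adiposim_spec")
    )
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>", x$layer_count, "lard layers,",
      sprintf("true fat volume %.1f ml (target %.0f ml), seed %d\n",
              x$true_fat_volume, x$target_volume, x$seed))
  invisible(x)
}

# angle within [start, start + extent] on the circle
in_arc <- function(theta, start, extent) {
  ((theta - start) %% (2 * pi)) <= extent
}

#' @export
spec_components.phantom_spec <- function(spec, ...) {
  lapply(seq_len(nrow(spec$layers)), function(i) {
    l <- spec$layers[i, ]
    cx <- spec$tube_centers[l$tube]
    extruded_component(
      local({
        r_in2 <- l$r_in^2; r_out2 <- l$r_out^2
        a0 <- l$arc_start; ext <- l$arc_extent; cx0 <- cx
        function(x, y) {
          dx <- x - cx0
          r2 <- dx^2 + y^2
          r2 > r_in2 & r2 <= r_out2 & in_arc(atan2(y, dx), a0, ext)
        }
      }),
      c(l$z_offset - l$width / 2, l$z_offset + l$width / 2)
    )
  })
}

#' @export
fat_indicator.phantom_spec <- function(spec, x, y, z) {
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(spec$layers))) {
    l <- spec$layers[i, ]
    dx <- x - spec$tube_centers[l$tube]
    r2 <- dx^2 + y^2
    out <- out | (
      r2 > l$r_in^2 & r2 <= l$r_out^2 &
        in_arc(atan2(y, dx), l$arc_start, l$arc_extent) &
        z > l$z_offset - l$width / 2 & z <= l$z_offset + l$width / 2
    )
  }
  out
}

#' @export
analytic_fat_volume.phantom_spec <- function(spec, ...) {
  # wraps are disjoint annular sectors: union volume = sum of sector volumes
  with(spec$layers,
       sum(0.5 * arc_extent * (r_out^2 - r_in^2) * width)) / 1000
}

#' @export
spec_bbox.phantom_spec <- function(spec, ...) {
  r_max <- max(spec$layers$r_out)
  list(
    x = range(spec$tube_centers) + c(-r_max, r_max),
    y = c(-r_max, r_max),
    z = range(c(spec$layers$z_offset - spec$layers$width / 2,
                spec$layers$z_offset + spec$layers$width / 2))
  )
}
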
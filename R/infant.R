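#' Build a synthetic infant torso spec
#'
#' Parametric desk-scale model of a young infant's torso for the
#' reproducibility studies: a cylindrical torso of suppressed (water) tissue
#' carrying a subcutaneous fat shell whose thickness varies smoothly around
#' the circumference, a few small intra-abdominal fat depots (young infants
#' carry little internal fat, most of it retroperitoneal), two arms alongside
#' the torso, and an optional head sphere. Water-suppressed contrast renders
#' everything but fat at background level; optionally the arms carry regions
#' of imperfect water suppression with elevated non-fat intensity, the
#' situation that in practice defeats purely automatic segmentation of the
#' extremities.
#'
#' All fat solids are constructed pairwise disjoint, so the analytic truth
#' decomposes exactly into a subcutaneous and an intra-abdominal compartment.
#'
#' @param rng_seed Integer seed; same seed, same spec.
#' @param n_depots Number of intra-abdominal depots (default 4).
#' @param suppression_failure If `TRUE` (default) the arms contain
#'   water-suppression-failure regions of elevated non-fat intensity.
#' @param shell_opening Angular width (radians, default 0) of a sector where
#'   the subcutaneous shell is absent; a non-zero opening produces an open
#'   body outline, the degraded case the compartment splitter flags.
#' @return An `infant_spec` with analytic `true_fat_volume`,
#'   `true_subcutaneous_ml` and `true_intra_abdominal_ml`.
#' @export
#' @examples
#' spec <- build_infant_spec(rng_seed = 3)
#' c(spec$true_subcutaneous_ml, spec$true_intra_abdominal_ml)
build_infant_spec <- function(rng_seed, n_depots = 4L,
                              suppression_failure = TRUE,
                              shell_opening = 0) {
  if (shell_opening < 0 || shell_opening > pi) {
    stop_adiposim("`shell_opening` must be in [0, pi] radians.",
                  "adiposim_spec_error")
  }
  with_seed(rng_seed, {
    torso_radius <- stats::runif(1, 41, 44)
    torso_length <- stats::runif(1, 126, 140)
    shell <- list(
      t0 = stats::runif(1, 5, 7),
      a1 = stats::runif(1, 0.10, 0.25),
      a2 = stats::runif(1, 0.05, 0.15),
      phi1 = stats::runif(1, 0, 2 * pi),
      phi2 = stats::runif(1, 0, 2 * pi),
      opening_start = stats::runif(1, 0, 2 * pi),
      opening = shell_opening
    )
    t_max <- shell$t0 * (1 + shell$a1 + shell$a2)

    # intra-abdominal depots: disjoint ellipsoids well inside the shell
    depots <- NULL
    if (n_depots > 0L) {
      placed <- list()
      tries <- 0L
      while (length(placed) < n_depots && tries < 400L) {
        tries <- tries + 1L
        a <- stats::runif(1, 8, 13)
        b <- 0.8 * a
        cc <- stats::runif(1, 8, 14)
        rho_max <- torso_radius - t_max - max(a, b) - 4
        rho <- sqrt(stats::runif(1)) * rho_max
        ang <- stats::runif(1, 0, 2 * pi)
        cz <- stats::runif(1, -(torso_length / 2 - cc - 15),
                           torso_length / 2 - cc - 15)
        cand <- c(cx = rho * cos(ang), cy = rho * sin(ang), cz = cz,
                  a = a, b = b, c = cc)
        ok <- TRUE
        for (p in placed) {
          d <- sqrt(sum((cand[1:3] - p[1:3])^2))
          if (d < max(cand[4:6]) + max(p[4:6]) + 4) {
            ok <- FALSE
            break
          }
        }
        if (ok) placed[[length(placed) + 1L]] <- cand
      }
      if (length(placed) < n_depots) {
        stop_adiposim("Could not place disjoint intra-abdominal depots.",
                      "adiposim_spec_error")
      }
      depots <- tibble::as_tibble(do.call(rbind, placed))
    } else {
      depots <- tibble::tibble(cx = numeric(0), cy = numeric(0),
                               cz = numeric(0), a = numeric(0),
                               b = numeric(0), c = numeric(0))
    }

    arm_x <- torso_radius + 11
    arms <- tibble::tibble(
      cx = c(-arm_x, arm_x), cy = c(0, 0), radius = 9,
      z_lo = -55, z_hi = 55
    )
    failures <- if (isTRUE(suppression_failure)) {
      tibble::tibble(
        cx = c(-arm_x, arm_x), cy = c(0, 0), radius = 5.5,
        z_lo = c(-24, -18), z_hi = c(16, 22),
        level = stats::runif(2, 0.35, 0.45)
      )
    } else {
      tibble::tibble(cx = numeric(0), cy = numeric(0), radius = numeric(0),
                     z_lo = numeric(0), z_hi = numeric(0), level = numeric(0))
    }

    spec <- structure(
      list(
        torso_radius = torso_radius,
        torso_length = torso_length,
        taper_length = 15,   # shell thins to zero over the last 15 mm
        shell = shell,
        depots = depots,
        arms = arms,
        failure_regions = failures,
        head = list(radius = 26, center_z = torso_length / 2 + 24),
        seed = as.integer(rng_seed)
      ),
      class = c("infant_spec", "adiposim_spec")
    )
    spec$true_subcutaneous_ml <- shell_volume_ml(spec)
    spec$true_intra_abdominal_ml <- depot_volume_ml(spec)
    spec$true_fat_volume <- spec$true_subcutaneous_ml +
      spec$true_intra_abdominal_ml
    spec
  })
}

#' @export
print.infant_spec <- function(x, ...) {
  cat("<infant_spec>",
      sprintf("torso %.0f mm x r %.0f mm; fat %.1f ml (s.c. %.1f + i.a. %.1f), seed %d\n",
              x$torso_length, x$torso_radius, x$true_fat_volume,
              x$true_subcutaneous_ml, x$true_intra_abdominal_ml, x$seed))
  invisible(x)
}

# circumferential shell thickness map t(theta), >= 1 mm where present
shell_thickness <- function(shell, theta) {
  t <- shell$t0 * (1 + shell$a1 * cos(theta - shell$phi1) +
                     shell$a2 * cos(2 * theta - shell$phi2))
  t <- pmax(t, 1)
  if (shell$opening > 0) {
    t[in_arc(theta, shell$opening_start, shell$opening)] <- 0
  }
  t
}

# Axial taper of the shell: thickness ramps linearly to zero over the last
# `taper_length` mm at both torso ends (subcutaneous fat thins out rather
# than terminating in a flat face).
shell_ramp <- function(z, torso_length, taper_length) {
  pmin(pmax((torso_length / 2 - abs(z)) / taper_length, 0), 1)
}

# Shell volume by composite Simpson quadrature over theta; the z integral of
# the tapered cross-section [t*ramp*R - (t*ramp)^2/2] is closed form:
# int ramp dz = L - taper, int ramp^2 dz = L - 4/3 taper.
shell_volume_ml <- function(spec) {
  n <- 4096L
  theta <- seq(0, 2 * pi, length.out = n + 1L)
  t <- shell_thickness(spec$shell, theta)
  R <- spec$torso_radius
  L <- spec$torso_length
  tp <- spec$taper_length
  i_ramp <- L - tp
  i_ramp2 <- L - 4 / 3 * tp
  f <- t * R * i_ramp - t^2 / 2 * i_ramp2
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f) * (2 * pi / n) / 3 / 1000
}

depot_volume_ml <- function(spec) {
  if (nrow(spec$depots) == 0L) return(0)
  sum(4 / 3 * pi * spec$depots$a * spec$depots$b * spec$depots$c) / 1000
}

#' @export
spec_components.infant_spec <- function(spec, ...) {
  comps <- list()
  R0 <- spec$torso_radius
  sh <- spec$shell
  L <- spec$torso_length
  tp <- spec$taper_length
  # full-thickness core section (extruded) ...
  comps[[1L]] <- extruded_component(
    function(x, y) {
      r2 <- x^2 + y^2
      theta <- atan2(y, x)
      t <- shell_thickness(sh, theta)
      r2 <= R0^2 & r2 > (R0 - t)^2
    },
    c(-(L / 2 - tp), L / 2 - tp)
  )
  # ... plus the two tapering end caps (thickness varies with z)
  for (s in c(-1, 1)) {
    comps[[length(comps) + 1L]] <- solid_component(
      local({
        sgn <- s
        function(x, y, z) {
          r2 <- x^2 + y^2
          theta <- atan2(y, x)
          t <- shell_thickness(sh, theta) * shell_ramp(z, L, tp)
          r2 <= R0^2 & r2 > (R0 - t)^2 & t > 0 & sgn * z > L / 2 - tp
        }
      }),
      list(x = c(-R0, R0), y = c(-R0, R0),
           z = sort(c(s * (L / 2 - tp), s * L / 2)))
    )
  }
  for (i in seq_len(nrow(spec$depots))) {
    d <- spec$depots[i, ]
    comps[[length(comps) + 1L]] <- solid_component(
      local({
        cx <- d$cx; cy <- d$cy; cz <- d$cz; a <- d$a; b <- d$b; cc <- d$c
        function(x, y, z) {
          ((x - cx) / a)^2 + ((y - cy) / b)^2 + ((z - cz) / cc)^2 <= 1
        }
      }),
      list(x = c(d$cx - d$a, d$cx + d$a), y = c(d$cy - d$b, d$cy + d$b),
           z = c(d$cz - d$c, d$cz + d$c))
    )
  }
  for (i in seq_len(nrow(spec$failure_regions))) {
    f <- spec$failure_regions[i, ]
    comps[[length(comps) + 1L]] <- extruded_component(
      local({
        cx <- f$cx; cy <- f$cy; r2 <- f$radius^2
        function(x, y) (x - cx)^2 + (y - cy)^2 <= r2
      }),
      c(f$z_lo, f$z_hi),
      channel = "other", level = f$level
    )
  }
  comps
}

#' @export
fat_indicator.infant_spec <- function(spec, x, y, z) {
  r2 <- x^2 + y^2
  theta <- atan2(y, x)
  t <- shell_thickness(spec$shell, theta) *
    shell_ramp(z, spec$torso_length, spec$taper_length)
  out <- r2 <= spec$torso_radius^2 & r2 > (spec$torso_radius - t)^2 & t > 0
  for (i in seq_len(nrow(spec$depots))) {
    d <- spec$depots[i, ]
    out <- out | (((x - d$cx) / d$a)^2 + ((y - d$cy) / d$b)^2 +
                    ((z - d$cz) / d$c)^2 <= 1)
  }
  out
}

#' @export
analytic_fat_volume.infant_spec <- function(spec, ...) {
  spec$true_fat_volume
}

#' @export
spec_bbox.infant_spec <- function(spec, ...) {
  xr <- c(-spec$torso_radius, spec$torso_radius)
  yr <- xr
  zr <- c(-spec$torso_length / 2, spec$torso_length / 2)
  if (nrow(spec$failure_regions) > 0L) {
    xr <- range(c(xr, spec$failure_regions$cx - spec$failure_regions$radius,
                  spec$failure_regions$cx + spec$failure_regions$radius))
    yr <- range(c(yr, spec$failure_regions$cy - spec$failure_regions$radius,
                  spec$failure_regions$cy + spec$failure_regions$radius))
    zr <- range(c(zr, spec$failure_regions$z_lo, spec$failure_regions$z_hi))
  }
  list(x = xr, y = yr, z = zr)
}
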
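# Internal helpers shared across the simulator and segmentation code.

# Evaluate `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic stream of n sub-seeds derived from a master seed.
# Kept below 2^31 so they remain valid R integer seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_adiposim <- function(msg, class) {
  rlang::abort(msg, class = c(class, "adiposim_error"))
}

# --- in-plane (2D, per-slice) binary morphology on 3D arrays -----------------
# All operators treat outside-image as background and act identically on every
# slice; they never touch the through-slice direction (slice gaps make
# through-plane adjacency physically dubious for gapped 2D multi-slice data).

# Shift a 3D array in-plane by (di, dj), filling vacated cells with `fill`.
shift_ip <- function(x, di, dj, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  src_i <- max(1L, 1L - di):min(d[1L], d[1L] - di)
  src_j <- max(1L, 1L - dj):min(d[2L], d[2L] - dj)
  out[src_i + di, src_j + dj, ] <- x[src_i, src_j, , drop = FALSE]
  out
}

neighbor_sum_ip <- function(mask) {
  m <- array(as.numeric(mask), dim(mask))
  s <- array(0, dim(mask))
  for (di in -1:1) {
    for (dj in -1:1) {
      s <- s + shift_ip(m, di, dj)
    }
  }
  s
}

# 3x3 binary median (majority of the 9-cell neighbourhood) with replicated
# image edges, the conventional boundary handling for median filters; the
# curvature regulariser of the active-contour refinement.
binary_majority_ip <- function(mask) {
  d <- dim(mask)
  padded <- array(0, d + c(2L, 2L, 0L))
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- mask
  padded[1L, , ] <- padded[2L, , ]
  padded[d[1] + 2L, , ] <- padded[d[1] + 1L, , ]
  padded[, 1L, ] <- padded[, 2L, ]
  padded[, d[2] + 2L, ] <- padded[, d[2] + 1L, ]
  s <- array(0, d)
  for (di in 0:2) {
    for (dj in 0:2) {
      s <- s + padded[di + seq_len(d[1]), dj + seq_len(d[2]), , drop = FALSE]
    }
  }
  s >= 5
}

dilate_ip <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) mask <- neighbor_sum_ip(mask) > 0
  mask
}

erode_ip <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) mask <- neighbor_sum_ip(mask) >= 9
  mask
}

closing_ip <- function(mask, iterations = 1L) {
  erode_ip(dilate_ip(mask, iterations), iterations)
}

# --- connected components, 2D 8-connectivity per slice -----------------------
# Returns integer labels (0 = background) and component voxel counts.
label_components_ip8 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0L) {
    return(list(labels = labels, sizes = integer(0)))
  }
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  i <- ((idx - 1L) %% d[1L]) + 1L
  j <- (((idx - 1L) %/% d[1L]) %% d[2L]) + 1L
  edges <- vector("list", 4L)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (o in seq_along(offs)) {
    di <- offs[[o]][1L]
    dj <- offs[[o]][2L]
    ok <- i + di >= 1L & i + di <= d[1L] & j + dj >= 1L & j + dj <= d[2L]
    nk <- idx[ok] + di + dj * d[1L]
    hit <- mask[nk]
    edges[[o]] <- cbind(pos[idx[ok][hit]], pos[nk[hit]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

# --- block averaging ----------------------------------------------------------
# Average an (nx*s) x (ny*s) supersampled matrix down to nx x ny.
block_average <- function(mat, s) {
  if (s == 1L) return(mat)
  d <- dim(mat)
  nx <- d[1L] %/% s
  ny <- d[2L] %/% s
  dim(mat) <- c(s, nx, ny * s)
  a <- colMeans(mat)          # nx x (ny*s)
  dim(a) <- c(nx, s, ny)
  a <- aperm(a, c(2L, 1L, 3L))
  dim(a) <- c(s, nx * ny)
  out <- colMeans(a)
  dim(out) <- c(nx, ny)
  out
}

# --- separable smoothing (in-plane) ------------------------------------------
# Circular 1D convolution along the first or second array dimension.
conv_ip <- function(x, kernel, axis) {
  stopifnot(axis %in% c(1L, 2L))
  half <- (length(kernel) - 1L) / 2
  taps <- seq_along(kernel) - 1L - half
  out <- array(0, dim(x))
  n <- dim(x)[axis]
  for (t in seq_along(taps)) {
    sh <- ((taps[t]) %% n + n) %% n
    ord <- if (sh == 0L) seq_len(n) else c((n - sh + 1L):n, seq_len(n - sh))
    perm <- if (axis == 1L) {
      x[ord, , , drop = FALSE]
    } else {
      x[, ord, , drop = FALSE]
    }
    out <- out + kernel[t] * perm
  }
  out
}

gaussian_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Circular in-plane shift along the second (phase-encode) axis.
circshift_y <- function(x, shift) {
  ny <- dim(x)[2L]
  sh <- ((shift %% ny) + ny) %% ny
  if (sh == 0L) return(x)
  x[, c((ny - sh + 1L):ny, seq_len(ny - sh)), , drop = FALSE]
}

# Bilinear in-plane rotation of every slice about the grid centre, replicating
# edge values outside the field of view (the background there is uniform).
rotate_ip <- function(x, theta) {
  d <- dim(x)
  nx <- d[1L]; ny <- d[2L]
  ci <- (nx + 1) / 2
  cj <- (ny + 1) / 2
  ii <- matrix(rep(seq_len(nx), ny), nx, ny) - ci
  jj <- matrix(rep(seq_len(ny), each = nx), nx, ny) - cj
  si <- cos(theta) * ii - sin(theta) * jj + ci
  sj <- sin(theta) * ii + cos(theta) * jj + cj
  si <- pmin(pmax(si, 1), nx)
  sj <- pmin(pmax(sj, 1), ny)
  i0 <- pmin(floor(si), nx - 1L); fi <- si - i0
  j0 <- pmin(floor(sj), ny - 1L); fj <- sj - j0
  w00 <- (1 - fi) * (1 - fj); w10 <- fi * (1 - fj)
  w01 <- (1 - fi) * fj;       w11 <- fi * fj
  k00 <- cbind(as.vector(i0), as.vector(j0))
  out <- array(0, d)
  for (k in seq_len(d[3L])) {
    sl <- x[, , k]
    v <- w00 * sl[k00] +
      w10 * sl[k00 + matrix(c(1L, 0L), nrow(k00), 2L, byrow = TRUE)] +
      w01 * sl[k00 + matrix(c(0L, 1L), nrow(k00), 2L, byrow = TRUE)] +
      w11 * sl[k00 + matrix(c(1L, 1L), nrow(k00), 2L, byrow = TRUE)]
    out[, , k] <- v
  }
  out
}
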
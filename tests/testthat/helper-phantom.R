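# Shared fixtures: compact phantom templates and an independent
# point-in-polygon oracle (even-odd ray casting, deliberately separate from
# the package's rasterization path).

small_template <- function(...) {
  phantom_spec(grid = c(80L, 80L, 8L),
               endo_radius_by_slice = seq(24, 2.5, length.out = 8),
               epi_radius_by_slice = seq(24, 2.5, length.out = 8) + 10,
               ...)
}

# single-radius annulus across slices (for symmetry / sector-fraction tests)
uniform_spec <- function(nslice = 6L, endo = 20, epi = 30, grid = 64L, ...) {
  phantom_spec(grid = c(grid, grid, nslice),
               endo_radius_by_slice = rep(endo, nslice),
               epi_radius_by_slice = rep(epi, nslice), ...)
}

pip_oracle <- function(poly, pts) {
  n <- nrow(poly)
  inside <- logical(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    x <- pts[k, 1]; y <- pts[k, 2]; cnt <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > y) != (yj > y)) {
        xint <- poly[i, 1] + (y - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi)
        if (x < xint) cnt <- cnt + 1L
      }
    }
    inside[k] <- cnt %% 2L == 1L
  }
  inside
}

# uniform-intensity stack over a given grid (for hand-built masks)
flat_stack <- function(nx = 20L, ny = 20L, ns = 1L, value = 100,
                       spacing = 1, thickness = 8) {
  image_stack(array(value, dim = c(nx, ny, ns)), spacing, thickness)
}

# single-slice stack whose first n_bright voxels in angular order carry the
# bright plateau (plus an optional grey band after them): exact-count sectors
two_level_stack <- function(n_bright = 120L, bright = 1000, remote = 100,
                            grey_n = 0L, grey = NA) {
  stack <- flat_stack(20, 20, 1, value = remote, spacing = 1)
  ord <- angular_order(stack)
  vals <- stack$data
  vals[ord[seq_len(n_bright)]] <- bright
  if (grey_n > 0) vals[ord[n_bright + seq_len(grey_n)]] <- grey
  stack$data <- vals
  stack
}

full_mask <- function(stack) array(TRUE, dim = dim(stack$data))

# angular order of the voxels of a single-slice full mask about its center,
# used to carve exact-count sectors
angular_order <- function(stack) {
  pts <- lgequant:::voxel_centers(stack)
  ctr <- colMeans(pts)
  th <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  order(((th * 180 / pi) %% 360))
}
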
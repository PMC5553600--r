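## Synthetic LGE phantom: an annular LV myocardium across short-axis slices
## with a transmural infarct sector (bright core, intermediate-signal grey
## shell at the rim, optional dark no-reflow core near the endocardium),
## bright blood pool, and air outside the heart. Intensities are tissue
## plateaus plus gaussian or rician (magnitude-MR) noise.

#' Phantom specification
#'
#' Geometry and intensity model of a synthetic short-axis LGE stack.
#'
#' @param grid integer length-3 `(nx, ny, nslices)` voxel grid.
#' @param pixel_spacing in-plane spacing, mm (length 1 or 2).
#' @param slice_thickness,slice_gap slice geometry, mm.
#' @param endo_radius_by_slice,epi_radius_by_slice per-slice endocardial and
#'   epicardial radii, mm (base first, apex last); endo < epi everywhere.
#' @param infarct_angular_extent angular width of the infarcted sector,
#'   degrees (0 = no infarct).
#' @param infarct_angular_center angular position of the sector center,
#'   degrees.
#' @param transmural_fraction fraction of the wall depth (from endocardium
#'   outward) occupied by the infarct, in `[0, 1]`.
#' @param grey_zone_width width of the intermediate-signal ("grey") shell at
#'   the infarct rim, as a fraction of the infarct's radial depth.
#' @param no_reflow_fraction fraction of the infarct core (innermost, by
#'   area) rendered as a dark no-reflow zone.
#' @param intensity_remote_mean,intensity_remote_sd remote (nulled) myocardium
#'   plateau and tissue heterogeneity, a.u.
#' @param intensity_infarct_plateau fully-bright infarct plateau, a.u. (the
#'   grey shell sits midway between remote mean and this plateau; the
#'   no-reflow zone at 0.4 x remote mean).
#' @param intensity_blood_pool blood-pool plateau, a.u.
#' @param noise_sd image noise SD, a.u.
#' @param noise_model `"rician"` (default, magnitude MR) or `"gaussian"`.
#' @return An object of class `lge_phantom_spec`.
#' @export
phantom_spec <- function(grid = c(128L, 128L, 10L),
                         pixel_spacing = c(1.5, 1.5),
                         slice_thickness = 7, slice_gap = 0,
                         endo_radius_by_slice = seq(24, 2.5, length.out = grid[3]),
                         epi_radius_by_slice = endo_radius_by_slice + 10,
                         infarct_angular_extent = 100,
                         infarct_angular_center = 90,
                         transmural_fraction = 1,
                         grey_zone_width = 0.4,
                         no_reflow_fraction = 0.15,
                         intensity_remote_mean = 100,
                         intensity_remote_sd = 5,
                         intensity_infarct_plateau = 600,
                         intensity_blood_pool = 550,
                         noise_sd = 20,
                         noise_model = c("rician", "gaussian")) {
  noise_model <- match.arg(noise_model)
  grid <- as.integer(grid)
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2L)
  spec <- structure(as.list(environment()), class = "lge_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid) != 3L || any(grid < 4L)) stopf("grid must be (nx, ny, nslices), all >= 4")
    if (length(endo_radius_by_slice) != grid[3] || length(epi_radius_by_slice) != grid[3])
      stopf("radius lists must have one entry per slice")
    if (any(endo_radius_by_slice <= 0) || any(endo_radius_by_slice >= epi_radius_by_slice))
      stopf("need 0 < endo_radius < epi_radius on every slice")
    for (f in c("transmural_fraction", "grey_zone_width", "no_reflow_fraction")) {
      v <- get(f)
      if (!is_scalar_num(v) || v < 0 || v > 1) stopf("%s must lie in [0, 1]", f)
    }
    if (intensity_infarct_plateau <= intensity_remote_mean)
      stopf("infarct plateau must exceed remote mean")
    if (noise_sd < 0 || intensity_remote_sd < 0) stopf("noise SDs must be >= 0")
    half <- c(grid[1] * pixel_spacing[1], grid[2] * pixel_spacing[2]) / 2
    if (max(epi_radius_by_slice) > min(half) - 2 * max(pixel_spacing))
      stopf("epicardium exceeds the voxel grid: enlarge the grid or shrink the radii")
  })
  invisible(spec)
}

# grid center (LV axis) in mm
phantom_center <- function(spec) {
  c(spec$grid[1] * spec$pixel_spacing[1], spec$grid[2] * spec$pixel_spacing[2]) / 2
}

# per-slice infarct radii: outer infarct radius r2, inner grey radius rg,
# outer no-reflow radius rnr
infarct_radii <- function(spec) {
  endo <- spec$endo_radius_by_slice; epi <- spec$epi_radius_by_slice
  r2 <- endo + spec$transmural_fraction * (epi - endo)
  rg <- r2 - spec$grey_zone_width * (r2 - endo)
  rnr <- sqrt(endo^2 + spec$no_reflow_fraction * (pmax(rg, endo)^2 - endo^2))
  list(endo = endo, epi = epi, r2 = r2, rg = rg, rnr = rnr)
}

#' Generate a synthetic LGE phantom
#'
#' Builds the image stack and the ground truth (tissue masks, true contours,
#' and the true infarct size with grey-zone voxels counted at weight 0.5).
#' Identical `(spec, seed)` pairs reproduce identical output.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @return A list with elements `stack` ([image_stack()]) and `truth`
#'   (class `lge_truth`: `myocardium_mask`, `infarct_core_mask`,
#'   `grey_zone_mask`, `no_reflow_mask`, `sector_mask`, `grey_depth`,
#'   `true_contours`, `true_infarct_percent_lv`, `true_infarct_grams`,
#'   `shell_width_mm`, `spec`).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  d <- spec$grid
  ctr <- phantom_center(spec)
  xs <- (seq_len(d[1]) - 0.5) * spec$pixel_spacing[1] - ctr[1]
  ys <- (seq_len(d[2]) - 0.5) * spec$pixel_spacing[2] - ctr[2]
  rr <- sqrt(outer(xs^2, ys^2, `+`))            # radius per in-plane voxel
  th <- ang_wrap(outer(xs, ys, function(x, y) atan2(y, x)) * 180 / pi)
  in_sector <- ang_dist(th, spec$infarct_angular_center) <=
    spec$infarct_angular_extent / 2 & spec$infarct_angular_extent > 0

  rad <- infarct_radii(spec)
  zero <- array(FALSE, dim = d)
  myo <- core <- grey <- nr <- sector <- zero
  depth <- array(0, dim = d)
  blood <- zero

  for (s in seq_len(d[3])) {
    m <- rr >= rad$endo[s] & rr < rad$epi[s]
    myo[, , s] <- m
    blood[, , s] <- rr < rad$endo[s]
    sector[, , s] <- in_sector
    inf <- m & in_sector & rr < rad$r2[s]
    g <- inf & rr >= rad$rg[s]
    n0 <- inf & !g & rr < rad$rnr[s]
    core[, , s] <- inf & !g & !n0
    grey[, , s] <- g
    nr[, , s] <- n0
    if (any(g)) {
      dp <- (rr - rad$rg[s]) / max(rad$r2[s] - rad$rg[s], 1e-9)
      depth[, , s][g] <- pmin(pmax(dp[g], 0), 1)
    }
  }

  ## intensities: tissue plateau + noise
  grey_plateau <- (spec$intensity_remote_mean + spec$intensity_infarct_plateau) / 2
  nr_plateau <- 0.4 * spec$intensity_remote_mean
  signal <- array(0, dim = d)
  signal[blood] <- spec$intensity_blood_pool
  signal[myo] <- spec$intensity_remote_mean
  signal[core] <- spec$intensity_infarct_plateau
  signal[grey] <- grey_plateau
  signal[nr] <- nr_plateau

  img <- with_seed(seed, {
    remote <- myo & !core & !grey & !nr
    if (spec$intensity_remote_sd > 0)
      signal[remote] <- signal[remote] + rnorm(sum(remote), 0, spec$intensity_remote_sd)
    if (spec$noise_sd > 0) {
      if (spec$noise_model == "gaussian") {
        signal + array(rnorm(length(signal), 0, spec$noise_sd), dim = d)
      } else {
        n1 <- array(rnorm(length(signal), 0, spec$noise_sd), dim = d)
        n2 <- array(rnorm(length(signal), 0, spec$noise_sd), dim = d)
        sqrt((signal + n1)^2 + n2^2)
      }
    } else signal
  })
  img[img < 0] <- 0

  endo_polys <- lapply(seq_len(d[3]), function(s)
    circle_polygon(ctr, rad$endo[s], n = 96L))
  epi_polys <- lapply(seq_len(d[3]), function(s)
    circle_polygon(ctr, rad$epi[s], n = 96L))
  contours <- contour_set(endo_polys, epi_polys, provenance = "truth")

  stack <- image_stack(img, spec$pixel_spacing, spec$slice_thickness, spec$slice_gap)
  wsum <- sum(core) + sum(nr) + 0.5 * sum(grey)
  truth <- structure(list(
    myocardium_mask = myo, infarct_core_mask = core, grey_zone_mask = grey,
    no_reflow_mask = nr, sector_mask = sector, grey_depth = depth,
    blood_mask = blood, true_contours = contours,
    true_infarct_percent_lv = 100 * wsum / sum(myo),
    true_infarct_grams = wsum * voxel_volume_ml(stack) * MYO_DENSITY,
    shell_width_mm = mean(rad$r2 - rad$rg),
    spec = spec), class = "lge_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.lge_truth <- function(x, ...) {
  cat(sprintf("<lge_truth> true infarct %.2f %%LV (%.1f g); myocardium %d voxels (core %d, grey %d, no-reflow %d)\n",
              x$true_infarct_percent_lv, x$true_infarct_grams,
              sum(x$myocardium_mask), sum(x$infarct_core_mask),
              sum(x$grey_zone_mask), sum(x$no_reflow_mask)))
  invisible(x)
}

#' Simulated-reader model
#'
#' Parameters of the contour-tracing and classification behavior of one
#' simulated core-laboratory reader. Contour errors are smooth periodic
#' random radial fields (human tracing errors are spatially smooth, not
#' white).
#'
#' @param contour_error_sd radial SD of the contour perturbation, mm.
#' @param contour_error_correlation_length angular correlation length of the
#'   perturbation field, degrees.
#' @param contour_bias signed systematic radial offset, mm (+ = outward).
#' @param grey_boundary_jitter_sd SD of the reader's grey-zone boundary
#'   placement, mm.
#' @param correction_completeness probability that each correctable region is
#'   actually corrected during user correction, in `[0, 1]`.
#' @param reader_id label.
#' @return An object of class `lge_reader`.
#' @export
reader_model <- function(contour_error_sd = 1,
                         contour_error_correlation_length = 40,
                         contour_bias = 0,
                         grey_boundary_jitter_sd = 0.5,
                         correction_completeness = 0.9,
                         reader_id = "R1") {
  if (contour_error_sd < 0 || grey_boundary_jitter_sd < 0)
    stopf("error SDs must be >= 0")
  if (correction_completeness < 0 || correction_completeness > 1)
    stopf("correction_completeness must lie in [0, 1]")
  if (contour_error_correlation_length <= 0)
    stopf("correlation length must be positive")
  structure(list(contour_error_sd = contour_error_sd,
                 contour_error_correlation_length = contour_error_correlation_length,
                 contour_bias = contour_bias,
                 grey_boundary_jitter_sd = grey_boundary_jitter_sd,
                 correction_completeness = correction_completeness,
                 reader_id = reader_id), class = "lge_reader")
}

# Smooth periodic unit-variance gaussian field sampled at `theta` (degrees),
# built on K control angles with squared-exponential correlation of length
# `L` degrees and interpolated periodically.
periodic_field <- function(theta, L, K = 64L) {
  phi <- (seq_len(K) - 1) * 360 / K
  C <- exp(-0.5 * (outer(phi, phi, ang_dist) / L)^2)
  ## squared-exponential covariances are numerically rank-deficient: factor
  ## by eigendecomposition with clamped eigenvalues rather than Cholesky
  e <- eigen(C, symmetric = TRUE)
  L_half <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  f <- as.vector(L_half %*% rnorm(K))
  # periodic linear interpolation onto theta
  t <- ang_wrap(theta) / (360 / K)
  i0 <- floor(t); w <- t - i0
  f0 <- f[(i0 %% K) + 1]; f1 <- f[((i0 + 1) %% K) + 1]
  (1 - w) * f0 + w * f1
}

# perturb one polygon radially about its centroid
perturb_polygon <- function(poly, sd, L, bias) {
  ctr <- colMeans(poly)
  dx <- poly[, 1] - ctr[1]; dy <- poly[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  th <- ang_wrap(atan2(dy, dx) * 180 / pi)
  disp <- bias + if (sd > 0) sd * periodic_field(th, L) else 0
  rn <- pmax(r + disp, 0.5)
  cbind(ctr[1] + rn * cos(th * pi / 180), ctr[2] + rn * sin(th * pi / 180))
}

#' Perturb contours with a simulated-reader tracing model
#'
#' Applies a smooth periodic random radial displacement field (SD
#' `contour_error_sd`, angular correlation length
#' `contour_error_correlation_length`) plus the systematic bias to every
#' contour. Perturbations that would invert the endo/epi ordering are
#' resampled a bounded number of times.
#'
#' @param contours a [contour_set()] (closed, non-self-intersecting).
#' @param reader an [reader_model()].
#' @param seed integer RNG seed.
#' @return A new [contour_set()] with provenance `"reader"`.
#' @export
perturb_contours <- function(contours, reader, seed = 1L) {
  ns <- length(contours$endo)
  endo <- vector("list", ns); epi <- vector("list", ns)
  with_seed(seed, {
    for (s in seq_len(ns)) {
      if (is.null(contours$endo[[s]])) next
      ok <- FALSE
      for (try in 1:25) {
        e <- perturb_polygon(contours$endo[[s]], reader$contour_error_sd,
                             reader$contour_error_correlation_length,
                             reader$contour_bias)
        p <- perturb_polygon(contours$epi[[s]], reader$contour_error_sd,
                             reader$contour_error_correlation_length,
                             reader$contour_bias)
        if (all(points_in_polygon(p, e))) { ok <- TRUE; break }
      }
      if (!ok)
        stopf("slice %d: could not perturb contours without inverting endo/epi ordering", s)
      endo[[s]] <- e; epi[[s]] <- p
    }
  })
  contour_set(endo, epi, provenance = "reader")
}
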
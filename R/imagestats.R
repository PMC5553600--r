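## SNR and CNR from regions of interest, with a helper that places the
## phantom's standard ROIs (centroid-anchored disks in the infarct core,
## remote myocardium, and air).

#' Signal-to-noise ratio
#'
#' Mean tissue signal intensity divided by the SD of the air ("noise") ROI
#' (sample SD, n-1 denominator; no rician noise-floor correction).
#'
#' @param stack an [image_stack()].
#' @param tissue_roi,air_roi integer vectors of voxel (linear) indices.
#' @return SNR (ratio).
#' @export
snr <- function(stack, tissue_roi, air_roi) {
  if (length(tissue_roi) == 0 || length(air_roi) < 2)
    stopf("ROIs must be nonempty (air needs >= 2 voxels)")
  s <- sd(stack$data[air_roi])
  if (s == 0) stopf("air ROI has zero SD (degenerate noiseless input)")
  mean(stack$data[tissue_roi]) / s
}

#' Contrast-to-noise ratio
#'
#' Infarct SNR minus remote-myocardium SNR.
#'
#' @param stack an [image_stack()].
#' @param infarct_roi,remote_roi,air_roi integer vectors of voxel indices.
#' @return CNR (ratio).
#' @export
cnr <- function(stack, infarct_roi, remote_roi, air_roi) {
  snr(stack, infarct_roi, air_roi) - snr(stack, remote_roi, air_roi)
}

#' Standard phantom ROIs
#'
#' Disk ROIs of radius `radius_mm`: in the infarct core (its centroid on the
#' slice with most core voxels), in remote myocardium (mid-wall, opposite
#' the infarct sector, same slice), and in air (grid corner, offset inward).
#'
#' @param truth an `lge_truth`.
#' @param stack the aligned [image_stack()].
#' @param radius_mm ROI disk radius, mm.
#' @return List of integer index vectors: `infarct_roi`, `remote_roi`,
#'   `air_roi`.
#' @export
phantom_rois <- function(truth, stack, radius_mm = 4) {
  d <- dim(stack$data)
  spec <- truth$spec
  ctr <- phantom_center(spec)
  pts <- voxel_centers(stack)
  disk <- function(center, slice) {
    r <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
    which(r <= radius_mm) + (slice - 1L) * d[1] * d[2]
  }
  core_per_slice <- apply(truth$infarct_core_mask, 3, sum)
  if (all(core_per_slice == 0)) stopf("phantom has no infarct core to place an ROI in")
  s <- which.max(core_per_slice)
  idx <- which(truth$infarct_core_mask[, , s])
  core_ctr <- colMeans(pts[idx, , drop = FALSE])
  rad <- infarct_radii(spec)
  mid_wall <- (rad$endo[s] + rad$epi[s]) / 2
  opp <- (spec$infarct_angular_center + 180) * pi / 180
  remote_ctr <- ctr + mid_wall * c(cos(opp), sin(opp))
  air_ctr <- c(1, 1) * (radius_mm + 2 * max(spec$pixel_spacing))
  list(infarct_roi = disk(core_ctr, s),
       remote_roi = disk(remote_ctr, s),
       air_roi = disk(air_ctr, s))
}
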
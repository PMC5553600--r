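## Automated infarct-border determination: weighted signal-intensity
## thresholding (a declared surrogate for the commercial weighted algorithm:
## linear ramp between the detection threshold and a plateau estimate) and
## the full-width-at-half-maximum (FWHM) algorithm, plus the user-correction
## step and its simulated-reader stand-in.

#' Weighted-threshold algorithm parameters
#'
#' @param k number of remote-myocardium SDs above the remote mean for the
#'   detection threshold.
#' @param remote_window angular width (degrees) of the sector used to locate
#'   remote myocardium automatically (the minimal-mean sector).
#' @param plateau_quantile quantile of supra-threshold intensities defining
#'   the "fully infarcted" plateau (the plateau is the mean of intensities at
#'   or above this quantile, robust to single-voxel maxima).
#' @return An object of class `lge_weighted_params`.
#' @export
weighted_threshold_params <- function(k = 1.8, remote_window = 60,
                                      plateau_quantile = 0.75) {
  if (k <= 0) stopf("k must be positive")
  if (remote_window <= 0 || remote_window > 360) stopf("remote_window must lie in (0, 360]")
  if (plateau_quantile <= 0 || plateau_quantile > 1) stopf("plateau_quantile must lie in (0, 1]")
  structure(list(k = k, remote_window = remote_window,
                 plateau_quantile = plateau_quantile),
            class = "lge_weighted_params")
}

#' FWHM algorithm parameters
#'
#' @param reference `"half_max"` (threshold at M/2) or `"half_range"`
#'   (threshold midway between the remote mean and the maximum M).
#' @param max_estimator `"top_percentile"` (default) or `"global_max"`.
#' @param percentile percentile used when `max_estimator = "top_percentile"`
#'   (resists hot-pixel noise).
#' @param remote_window angular width of the automatic remote sector
#'   (degrees), used for the remote statistics of `half_range` mode and the
#'   no-credible-hyperenhancement guard.
#' @return An object of class `lge_fwhm_params`.
#' @export
fwhm_params <- function(reference = c("half_max", "half_range"),
                        max_estimator = c("top_percentile", "global_max"),
                        percentile = 99, remote_window = 60) {
  reference <- match.arg(reference)
  max_estimator <- match.arg(max_estimator)
  if (percentile <= 0 || percentile > 100) stopf("percentile must lie in (0, 100]")
  structure(list(reference = reference, max_estimator = max_estimator,
                 percentile = percentile, remote_window = remote_window),
            class = "lge_fwhm_params")
}

#' Automatic remote-myocardium statistics
#'
#' Locates remote (non-hyperenhanced) myocardium with no user input as the
#' angular sector of given width with minimal mean intensity (per-slice
#' angles about the slice myocardial centroid, pooled across slices), and
#' returns its intensity mean and SD.
#'
#' @param stack an [image_stack()].
#' @param mask logical myocardium volume.
#' @param window sector width, degrees.
#' @return List: `mu`, `sigma` (sample SD), `sector_start` (degrees), and
#'   `remote` (logical volume of the remote voxels).
#' @export
remote_stats <- function(stack, mask, window = 60) {
  d <- dim(stack$data)
  if (!any(mask)) stopf("empty myocardium mask")
  nb <- 72L                                   # 5-degree bins
  theta <- array(NA_real_, dim = d)
  pts <- voxel_centers(stack)
  for (s in seq_len(d[3])) {
    m <- mask[, , s]
    if (!any(m)) next
    idx <- which(m)
    ctr <- colMeans(pts[idx, , drop = FALSE])
    th <- ang_wrap(atan2(pts[idx, 2] - ctr[2], pts[idx, 1] - ctr[1]) * 180 / pi)
    sl <- theta[, , s]; sl[idx] <- th; theta[, , s] <- sl
  }
  bin <- floor(ang_wrap(theta[mask]) / (360 / nb)) + 1L
  vals <- stack$data[mask]
  sums <- tapply(vals, factor(bin, levels = seq_len(nb)), sum, default = 0)
  cnts <- tapply(rep(1, length(vals)), factor(bin, levels = seq_len(nb)), sum, default = 0)
  wbins <- max(1L, round(window / (360 / nb)))
  roll <- function(v) {                        # circular rolling sum over wbins
    cs <- cumsum(c(v, v))
    cs[seq_len(nb) + wbins - 1L] - c(0, cs)[seq_len(nb)]
  }
  wmean <- roll(as.numeric(sums)) / pmax(roll(as.numeric(cnts)), 1)
  start <- which.min(wmean)
  start_deg <- (start - 1L) * 360 / nb
  in_win <- ang_wrap(theta - start_deg) < window & !is.na(theta) & mask
  in_win[is.na(in_win)] <- FALSE
  rv <- stack$data[in_win]
  list(mu = mean(rv), sigma = sd(rv), sector_start = start_deg, remote = in_win)
}

#' Weighted-threshold infarct map
#'
#' Estimates remote statistics `(mu_r, sigma_r)` from the minimal-mean
#' angular sector, sets the detection threshold `t = mu_r + k * sigma_r` and
#' the fully-infarcted plateau `F` (mean of supra-threshold intensities at or
#' above the plateau quantile), and assigns each myocardial voxel the weight
#' `min(1, (SI - t) / (F - t))` above threshold, 0 otherwise.
#'
#' @param stack an [image_stack()].
#' @param mask logical myocardium volume.
#' @param params a [weighted_threshold_params()].
#' @param remote optional precomputed [remote_stats()] result.
#' @param method method tag for the returned map.
#' @return An [infarct_map()] with continuous weights.
#' @export
weighted_infarct <- function(stack, mask, params = weighted_threshold_params(),
                             remote = NULL, method = "AUTO_SEGMENT") {
  if (is.null(remote)) remote <- remote_stats(stack, mask, params$remote_window)
  sig <- if (is.na(remote$sigma)) 0 else remote$sigma
  thr <- remote$mu + params$k * sig
  w <- array(0, dim = dim(stack$data))
  vals <- stack$data[mask]
  supra <- vals > thr
  if (!any(supra)) {
    map <- infarct_map(w, method)
    attr(map, "status") <- "no infarct detected"
    return(map)
  }
  sv <- vals[supra]
  plateau <- mean(sv[sv >= quantile(sv, params$plateau_quantile)])
  wm <- numeric(length(vals))
  if (plateau <= thr) {
    warnf("degenerate contrast (plateau <= threshold): supra-threshold weights set to 1")
    wm[supra] <- 1
  } else {
    wm[supra] <- pmin(1, (sv - thr) / (plateau - thr))
  }
  w[mask] <- wm
  infarct_map(w, method)
}

#' FWHM infarct map
#'
#' Estimates the maximal infarct intensity `M` over the myocardium (99th
#' percentile by default), thresholds at `M/2` (`half_max`) or midway between
#' the remote mean and `M` (`half_range`), and classifies voxels
#' dichotomously. If the threshold does not exceed remote mean + 2 SD there
#' is no credible hyperenhancement and an all-zero map is returned with a
#' warning.
#'
#' @inheritParams weighted_infarct
#' @param params an [fwhm_params()].
#' @return An [infarct_map()] with weights in `{0, 1}`.
#' @export
fwhm_infarct <- function(stack, mask, params = fwhm_params(),
                         remote = NULL, method = "AUTO_FWHM") {
  if (is.null(remote)) remote <- remote_stats(stack, mask, params$remote_window)
  vals <- stack$data[mask]
  M <- if (params$max_estimator == "global_max") max(vals)
       else as.numeric(quantile(vals, params$percentile / 100))
  thr <- if (params$reference == "half_max") M / 2
         else remote$mu + (M - remote$mu) / 2
  sig <- if (is.na(remote$sigma)) 0 else remote$sigma
  w <- array(0, dim = dim(stack$data))
  if (thr <= remote$mu + 2 * sig) {
    warnf("no credible hyperenhancement (FWHM threshold within remote mean + 2 SD): zero map")
    map <- infarct_map(w, method)
    attr(map, "status") <- "no infarct detected"
    return(map)
  }
  w[mask] <- as.numeric(vals > thr)
  infarct_map(w, method)
}

#' Create a user-correction set
#'
#' Regions to add (set to weight 1: e.g. no-reflow zones) or remove (set to
#' 0: blood-pool, epicardial fat, artifacts). Each region may be given either
#' as a logical voxel volume or as a list of per-slice polygons
#' (`list(slice =, xy = N x 2 matrix in mm)`), matching the JSON interchange
#' format.
#'
#' @param add,remove lists of regions (masks or polygon descriptors); `NULL`
#'   or empty for none.
#' @param reader reader label.
#' @return An object of class `lge_corrections`.
#' @export
correction_set <- function(add = list(), remove = list(), reader = NA_character_) {
  structure(list(add = add, remove = remove, reader = reader),
            class = "lge_corrections")
}

# region (mask or polygon descriptor) -> logical volume
region_to_mask <- function(region, stack) {
  if (is.array(region)) {
    if (!all(dim(region) == dim(stack$data))) stopf("correction region mask misaligned")
    return(region > 0)
  }
  if (is.list(region) && !is.null(region$xy)) {
    m <- array(FALSE, dim = dim(stack$data))
    pts <- voxel_centers(stack)
    m[, , region$slice] <- points_in_polygon(region$xy, pts)
    return(m)
  }
  stopf("correction regions must be masks or list(slice=, xy=) polygons")
}

#' Apply user corrections to an infarct map
#'
#' Voxels in add-regions get weight 1; voxels in remove-regions get 0; all
#' other weights are unchanged. Overlapping add and remove regions are
#' rejected.
#'
#' @param map an [infarct_map()].
#' @param corrections a [correction_set()].
#' @param stack the aligned [image_stack()].
#' @param method method tag for the corrected map (default: input tag).
#' @return A corrected [infarct_map()].
#' @export
apply_corrections <- function(map, corrections, stack, method = NULL) {
  d <- dim(stack$data)
  addm <- array(FALSE, dim = d); remm <- array(FALSE, dim = d)
  for (r in corrections$add) addm <- addm | region_to_mask(r, stack)
  for (r in corrections$remove) remm <- remm | region_to_mask(r, stack)
  if (any(addm & remm)) stopf("add and remove correction regions overlap")
  w <- map$weights
  w[addm] <- 1
  w[remm] <- 0
  infarct_map(w, method %||% map$method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the reader's user-correction step
#'
#' Stand-in for manual correction of an automated infarct map: with
#' probability `correction_completeness` per region, the true no-reflow zone
#' is emitted as an add-region, and each connected false-positive blob (map
#' positives outside the true infarct, e.g. blood-pool included by an
#' imprecise endocardial contour) of at least `min_blob` voxels as a
#' remove-region.
#'
#' @param truth an `lge_truth` ground truth.
#' @param auto_map the automated [infarct_map()] to correct.
#' @param reader an [reader_model()].
#' @param seed integer RNG seed.
#' @param min_blob smallest false-positive component (voxels, per slice) a
#'   reader would bother to remove.
#' @return A [correction_set()] of mask regions.
#' @export
simulate_corrections <- function(truth, auto_map, reader, seed = 1L,
                                 min_blob = 5L) {
  d <- dim(auto_map$weights)
  if (!all(dim(truth$myocardium_mask) == d)) stopf("truth and map are misaligned")
  true_inf <- truth$infarct_core_mask | truth$grey_zone_mask | truth$no_reflow_mask
  fp <- auto_map$weights > 0 & !true_inf
  regions <- list()
  for (s in seq_len(d[3])) {
    sl <- fp[, , s]
    if (!any(sl)) next
    lab <- EBImage::bwlabel(sl)
    for (l in seq_len(max(lab))) {
      comp <- lab == l
      if (sum(comp) < min_blob) next
      m <- array(FALSE, dim = d); m[, , s] <- comp
      regions <- c(regions, list(m))
    }
  }
  add <- list(); remove <- list()
  with_seed(seed, {
    if (any(truth$no_reflow_mask) && runif(1) < reader$correction_completeness)
      add <- list(truth$no_reflow_mask)
    keep <- runif(length(regions)) < reader$correction_completeness
    remove <- regions[keep]
  })
  correction_set(add = add, remove = remove, reader = reader$reader_id)
}
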
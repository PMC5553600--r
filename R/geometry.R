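## Geometry: image stacks, contour sets, rasterization, LV mass and
## infarct-size bookkeeping.
##
## Coordinate conventions
##  - Volumes are 3-D arrays indexed [x, y, slice]; voxel centers sit at
##    physical coordinates ((i - 0.5) * dx, (j - 0.5) * dy) mm, origin at the
##    corner of the grid. Slice indices are 1-based in R; the JSON contour
##    interchange format uses 0-based slice indices.
##  - Contour polygons are N x 2 matrices of (x, y) vertices in mm, implicitly
##    closed (first vertex is not repeated).
##  - Voxel depth for volume/mass purposes is slice_thickness + slice_gap
##    (contiguous-coverage convention), so gapped acquisitions do not
##    under-count mass.

#' Create an LGE image stack
#'
#' A short-axis image volume with its physical spacing metadata.
#'
#' @param data 3-D numeric array `[x, y, slice]` of signal intensities (a.u.,
#'   finite and non-negative).
#' @param pixel_spacing in-plane voxel size in mm, length-2 `(dx, dy)` (a
#'   scalar is recycled).
#' @param slice_thickness slice thickness in mm.
#' @param slice_gap inter-slice gap in mm (default 0).
#' @return An object of class `lge_stack`.
#' @export
image_stack <- function(data, pixel_spacing, slice_thickness, slice_gap = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3-D array [x, y, slice]")
  if (any(!is.finite(data)) || any(data < 0))
    stopf("intensities must be finite and >= 0")
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2L)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0 || slice_gap < 0)
    stopf("spacing metadata must be positive (gap >= 0)")
  structure(list(data = data, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, slice_gap = slice_gap),
            class = "lge_stack")
}

#' @export
print.lge_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lge_stack> %d x %d x %d voxels, %.2f x %.2f mm pixels, %.1f mm slices (gap %.1f mm)\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_thickness, x$slice_gap))
  invisible(x)
}

#' @export
dim.lge_stack <- function(x) dim(x$data)

# voxel volume in mL, contiguous-coverage convention
voxel_volume_ml <- function(stack) {
  prod(stack$pixel_spacing) * (stack$slice_thickness + stack$slice_gap) / 1000
}

# physical (x, y) coordinates of all voxel centers of one slice, as an
# (nx*ny) x 2 matrix in mm (column-major over [x, y])
voxel_centers <- function(stack) {
  d <- dim(stack$data)
  xs <- (seq_len(d[1]) - 0.5) * stack$pixel_spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * stack$pixel_spacing[2]
  cbind(rep(xs, times = d[2]), rep(ys, each = d[1]))
}

#' Create a contour set
#'
#' Per-slice endocardial and epicardial closed polygons in physical mm
#' coordinates. Slices without contours carry `NULL`.
#'
#' @param endo,epi lists (one element per slice) of N x 2 vertex matrices, or
#'   `NULL` where the slice has no contour.
#' @param provenance `"truth"` or `"reader"`.
#' @return An object of class `lge_contours`.
#' @export
contour_set <- function(endo, epi, provenance = c("truth", "reader")) {
  provenance <- match.arg(provenance)
  if (length(endo) != length(epi))
    stopf("endo and epi must have one entry per slice")
  for (s in seq_along(endo)) {
    for (p in list(endo[[s]], epi[[s]])) {
      if (is.null(p)) next
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
        stopf("slice %d: polygons must be N x 2 matrices with N >= 3", s)
    }
    if (is.null(endo[[s]]) != is.null(epi[[s]]))
      stopf("slice %d: endo and epi must both be present or both absent", s)
  }
  structure(list(endo = endo, epi = epi, provenance = provenance),
            class = "lge_contours")
}

#' @export
print.lge_contours <- function(x, ...) {
  ns <- sum(!vapply(x$endo, is.null, logical(1)))
  cat(sprintf("<lge_contours> %s, contours on %d of %d slices\n",
              x$provenance, ns, length(x$endo)))
  invisible(x)
}

# point-in-polygon for an implicitly-closed polygon; pts is M x 2
points_in_polygon <- function(poly, pts) {
  bnd <- rbind(poly, poly[1L, , drop = FALSE])
  mgcv::in.out(bnd, pts)
}

#' Rasterize myocardial contours to a voxel mask
#'
#' A voxel belongs to the myocardium iff its center lies inside the epicardial
#' polygon and outside the endocardial polygon of its slice.
#'
#' @param contours an [contour_set()].
#' @param stack an [image_stack()] supplying the grid and spacing.
#' @return Logical array of the stack's dimensions (class `lge_mask` attribute
#'   kept implicit; it is a plain logical array).
#' @export
rasterize_contours <- function(contours, stack) {
  d <- dim(stack$data)
  if (length(contours$endo) != d[3])
    stopf("contour set has %d slices but stack has %d", length(contours$endo), d[3])
  pts <- voxel_centers(stack)
  mask <- array(FALSE, dim = d)
  for (s in seq_len(d[3])) {
    endo <- contours$endo[[s]]; epi <- contours$epi[[s]]
    if (is.null(endo)) next
    in_epi <- points_in_polygon(epi, pts)
    in_endo <- points_in_polygon(endo, pts)
    if (any(in_endo & !in_epi))
      stopf("slice %d: endocardial contour crosses outside the epicardial contour", s)
    sl <- in_epi & !in_endo
    if (!any(sl))
      stopf("slice %d: contours enclose no voxels (degenerate geometry)", s)
    mask[, , s] <- sl
  }
  mask
}

#' Left-ventricular myocardial mass
#'
#' Mass in grams from a myocardium mask: voxel count x voxel volume
#' (slice thickness + gap) x 1.05 g/mL.
#'
#' @param mask logical myocardium volume.
#' @param stack the aligned [image_stack()] (spacing metadata).
#' @return Mass in grams.
#' @export
lv_mass <- function(mask, stack) {
  if (!all(dim(mask) == dim(stack$data))) stopf("mask and stack are misaligned")
  n <- sum(mask)
  if (n == 0) {
    warnf("empty myocardium mask: LV mass is 0 g")
    return(0)
  }
  n * voxel_volume_ml(stack) * MYO_DENSITY
}

#' Create an infarct weight map
#'
#' Per-voxel infarct weight in `[0, 1]` over the stack grid. Dichotomous
#' methods use weights in `{0, 1}`.
#'
#' @param weights numeric array of the grid's dimensions.
#' @param method method tag (one of [LGE_METHODS] or a free label).
#' @return An object of class `lge_infarct_map`.
#' @export
infarct_map <- function(weights, method = "unknown") {
  if (!is.array(weights) || length(dim(weights)) != 3L)
    stopf("weights must be a 3-D array")
  if (any(weights < 0 | weights > 1))
    stopf("infarct weights must lie in [0, 1]")
  structure(list(weights = weights, method = method), class = "lge_infarct_map")
}

#' @export
print.lge_infarct_map <- function(x, ...) {
  cat(sprintf("<lge_infarct_map> method %s, weight sum %.1f over %d positive voxels\n",
              x$method, sum(x$weights), sum(x$weights > 0)))
  invisible(x)
}

#' Infarct size from a weight map
#'
#' Infarct size as a percentage of LV myocardium and in grams:
#' `percent_lv = 100 * sum(weights) / sum(mask)`;
#' `mass_g = sum(weights) * voxel volume * 1.05 g/mL`.
#'
#' @param map an [infarct_map()].
#' @param mask logical myocardium volume the map refers to.
#' @param stack the aligned [image_stack()].
#' @param patient,reader optional labels carried into the result.
#' @return A one-row data.frame (patient, reader, method, percent_lv, mass_g,
#'   lv_mass_g).
#' @export
infarct_size <- function(map, mask, stack, patient = NA_character_,
                         reader = NA_character_) {
  w <- map$weights
  if (!all(dim(w) == dim(mask))) stopf("map and mask are misaligned")
  nmyo <- sum(mask)
  if (nmyo == 0) stopf("empty myocardium mask")
  wsum <- sum(w)
  data.frame(patient = patient, reader = reader, method = map$method,
             percent_lv = 100 * wsum / nmyo,
             mass_g = wsum * voxel_volume_ml(stack) * MYO_DENSITY,
             lv_mass_g = nmyo * voxel_volume_ml(stack) * MYO_DENSITY,
             stringsAsFactors = FALSE)
}

# regular closed polygon approximating a circle (used for phantom truth
# contours and ROI disks)
circle_polygon <- function(center, radius, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
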
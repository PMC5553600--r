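## 17-segment visual scoring. Slices are split into basal/mid/apical thirds;
## basal and mid rings carry 6 sectors of 60 degrees, apical rings 4 sectors
## of 90 degrees, measured from the RV insertion angle; the apical cap
## (segment 17) is the apical-most slice when its cavity has nearly closed.
## Extent scores use the 5-point scale (0 = none, 1 = 1-25%, 2 = 26-50%,
## 3 = 51-75%, 4 = 76-100%) and VISUAL infarct size sums the per-segment
## midpoints (1 -> 13%, 2 -> 38%, 3 -> 63%, 4 -> 88%) over 17 segments.

EXTENT_MIDPOINT <- c(0, 13, 38, 63, 88)     # indexed by score + 1
SI_WEIGHT <- c(0, 0.13, 0.38, 0.63, 0.88)   # same midpoints as SI weighting

#' Assign AHA 17-segment labels to a myocardium mask
#'
#' Slices containing myocardium are split into basal/mid/apical thirds by
#' slice count (remainder slices allotted to the basal, then the mid third).
#' Basal segments are 1-6, mid 7-12 (6 sectors of 60 degrees each), apical
#' 13-16 (4 sectors of 90 degrees), counted counter-clockwise from
#' `rv_insertion_angle`. The apical-most slice becomes the apical cap
#' (segment 17) when its endocardial cavity area is below 10% of its
#' epicardial (filled) area; otherwise segment 17 stays unassigned with a
#' warning.
#'
#' @param mask logical myocardium volume.
#' @param stack the aligned [image_stack()].
#' @param rv_insertion_angle angular origin, degrees.
#' @return Integer array of segment labels 1-17 (`NA` outside the
#'   myocardium), with attribute `"cap_assigned"`.
#' @export
assign_segments <- function(mask, stack, rv_insertion_angle = 0) {
  d <- dim(mask)
  slices <- which(apply(mask, 3, any))
  if (length(slices) < 3L) stopf("need at least 3 slices with myocardium")
  n <- length(slices)
  q <- n %/% 3L; r <- n %% 3L
  nb <- q + (r >= 1L); nm <- q + (r >= 2L)
  ring <- rep(c(1L, 2L, 3L), times = c(nb, nm, q))   # slices ordered base -> apex
  pts <- voxel_centers(stack)
  labels <- array(NA_integer_, dim = d)

  apical_slice <- slices[n]
  m_ap <- mask[, , apical_slice]
  filled <- EBImage::fillHull(m_ap) > 0
  cavity <- sum(filled & !m_ap)
  cap <- cavity < 0.1 * sum(filled)
  if (!cap)
    warnf("apical cavity is %.0f%% of the filled area (>= 10%%): segment 17 (apical cap) unassigned",
          100 * cavity / sum(filled))

  for (i in seq_len(n)) {
    s <- slices[i]
    m <- mask[, , s]
    idx <- which(m)
    if (cap && s == apical_slice) {
      sl <- labels[, , s]; sl[idx] <- 17L; labels[, , s] <- sl
      next
    }
    ctr <- colMeans(pts[idx, , drop = FALSE])
    th <- ang_wrap(atan2(pts[idx, 2] - ctr[2], pts[idx, 1] - ctr[1]) * 180 / pi -
                     rv_insertion_angle)
    seg <- if (ring[i] == 1L) floor(th / 60) + 1L
           else if (ring[i] == 2L) floor(th / 60) + 7L
           else floor(th / 90) + 13L
    sl <- labels[, , s]; sl[idx] <- as.integer(seg); labels[, , s] <- sl
  }
  attr(labels, "cap_assigned") <- cap
  labels
}

#' Segmental extent score (5-point scale)
#'
#' 0 for no hyperenhancement; otherwise quartile bins of the hyperenhanced
#' area fraction: (0, 0.25] -> 1, (0.25, 0.50] -> 2, (0.50, 0.75] -> 3,
#' (0.75, 1] -> 4.
#'
#' @param hyper_fraction fraction(s) in `[0, 1]`.
#' @return Integer score(s) 0-4.
#' @export
extent_score <- function(hyper_fraction) {
  if (any(hyper_fraction < 0 | hyper_fraction > 1))
    stopf("hyperenhancement fraction must lie in [0, 1]")
  ifelse(hyper_fraction == 0, 0L,
         pmin(4L, as.integer(ceiling(hyper_fraction * 4))))
}

#' Segmental signal-intensity score
#'
#' Mean hyperenhanced signal intensity relative to the reference (brightest
#' infarct voxel or blood pool, whichever is higher), binned on the same
#' quartile edges as the extent score: (0, 0.25] -> 1 ... (0.75, 1] -> 4.
#'
#' @param mean_hyper_si mean signal intensity of the segment's hyperenhanced
#'   tissue, a.u.
#' @param reference_si reference intensity, a.u. (> 0, >= `mean_hyper_si`).
#' @return Integer score(s) 1-4.
#' @export
si_score <- function(mean_hyper_si, reference_si) {
  if (any(reference_si <= 0)) stopf("reference intensity must be positive")
  if (any(mean_hyper_si > reference_si))
    stopf("mean hyperenhanced intensity exceeds the reference")
  r <- mean_hyper_si / reference_si
  pmax(1L, pmin(4L, as.integer(ceiling(r * 4))))
}

#' Create a segment-score object
#'
#' @param extent integer vector of 17 extent scores in 0-4.
#' @param si optional integer vector of 17 signal-intensity scores (0 only
#'   where extent is 0, else 1-4).
#' @param patient,reader optional labels.
#' @return An object of class `lge_scores`.
#' @export
segment_scores <- function(extent, si = NULL, patient = NA_character_,
                           reader = NA_character_) {
  extent <- as.integer(extent)
  if (length(extent) != 17L || any(extent < 0L | extent > 4L))
    stopf("extent must be 17 scores in 0..4")
  if (!is.null(si)) {
    si <- as.integer(si)
    if (length(si) != 17L || any(si < 0L | si > 4L))
      stopf("si must be 17 scores in 0..4")
    if (any(si == 0L & extent > 0L) || any(si > 0L & extent == 0L))
      stopf("si must be >= 1 exactly where extent >= 1")
  }
  structure(list(extent = extent, si = si, patient = patient, reader = reader),
            class = "lge_scores")
}

#' VISUAL infarct size from extent scores
#'
#' `%LV = sum(midpoint(extent_s)) / 17` with midpoints
#' `{0: 0, 1: 13, 2: 38, 3: 63, 4: 88}`.
#'
#' @param scores an [segment_scores()].
#' @return Infarct size in %LV.
#' @export
visual_size <- function(scores) {
  sum(EXTENT_MIDPOINT[scores$extent + 1L]) / 17
}

#' VISUAL-ISI infarct size from extent and signal-intensity scores
#'
#' `%LV = sum(midpoint(extent_s) * w(si_s)) / 17` with the SI weights using
#' the same midpoint fractions as the extent scale
#' (`{1: 0.13, 2: 0.38, 3: 0.63, 4: 0.88}`).
#'
#' @param scores an [segment_scores()] with SI scores present.
#' @return Infarct size in %LV.
#' @export
visual_isi_size <- function(scores) {
  if (is.null(scores$si)) stopf("signal-intensity scores are missing")
  sum(EXTENT_MIDPOINT[scores$extent + 1L] * SI_WEIGHT[scores$si + 1L]) / 17
}

#' Score a classified stack on the 17-segment model
#'
#' Per segment, the hyperenhanced fraction (bright, grey and no-reflow
#' voxels) yields the extent score; the mean signal intensity of that tissue
#' (no-reflow voxels counted as fully bright, i.e. at the reference) against
#' the reference (the brightest hyperenhanced voxel or the blood-pool mean,
#' whichever is higher) yields the SI score.
#'
#' @param cls an [classify_regions()] result.
#' @param labels segment label array from [assign_segments()].
#' @param stack the aligned [image_stack()].
#' @param blood_pool_mean optional blood-pool reference intensity; when
#'   `NULL` it is the mean over the cavity (holes enclosed by the
#'   myocardium).
#' @param patient,reader optional labels.
#' @return An [segment_scores()] object.
#' @export
score_stack <- function(cls, labels, stack, blood_pool_mean = NULL,
                        patient = NA_character_, reader = NA_character_) {
  d <- dim(stack$data)
  if (!all(dim(labels) == d)) stopf("labels and stack are misaligned")
  hyper <- cls$bright | cls$grey | cls$no_reflow
  if (is.null(blood_pool_mean)) {
    myo <- !is.na(labels)
    cav <- array(FALSE, dim = d)
    for (s in seq_len(d[3])) {
      m <- myo[, , s]
      if (!any(m)) next
      cav[, , s] <- (EBImage::fillHull(m) > 0) & !m
    }
    blood_pool_mean <- if (any(cav)) mean(stack$data[cav]) else 0
  }
  bright_hyper <- (cls$bright | cls$grey) & !is.na(labels)
  ref <- max(c(blood_pool_mean,
               if (any(bright_hyper)) max(stack$data[bright_hyper]) else 0))
  si_vals <- stack$data
  si_vals[cls$no_reflow] <- ref
  si_vals <- pmin(si_vals, ref)

  extent <- integer(17); si <- integer(17)
  for (g in 1:17) {
    seg <- !is.na(labels) & labels == g
    nseg <- sum(seg)
    if (nseg == 0) next
    h <- seg & hyper
    extent[g] <- extent_score(sum(h) / nseg)
    if (extent[g] > 0) si[g] <- si_score(mean(si_vals[h]), ref)
  }
  segment_scores(extent, si, patient, reader)
}
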
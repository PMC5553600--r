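## Manual planimetry emulation. A RegionClassification partitions the
## hyperenhanced tissue a reader would trace into fully-bright, grey
## (intermediate signal intensity, ISI) and no-reflow regions. MANUAL counts
## all of it at full weight; MANUAL-ISI counts bright and no-reflow at full
## weight and grey at half weight.

#' Classify bright / grey / no-reflow regions
#'
#' Two modes:
#'
#' * **threshold mode** (no `truth`): display-reference classification
#'   emulating the preset window/level: with `R` the maximal myocardial
#'   intensity, bright is `SI >= bright_frac * R` and grey is
#'   `grey_frac * R <= SI < bright_frac * R`; no-reflow is dark voxels
#'   (below the remote mean) fully enclosed by bright tissue.
#' * **simulated-reader mode** (with `truth` and `reader`): ground-truth
#'   tissue classes restricted to the reader's myocardium mask, with the
#'   reader's handling of the ambiguous grey shell controlled by
#'   `ambiguity`: `"inclusion"` (the reader includes a seeded random
#'   fraction u ~ U(0.5, 1) of the shell depth as hyperenhanced - the MANUAL
#'   and VISUAL reading), `"jitter"` (the full shell with its outer boundary
#'   jittered by `grey_boundary_jitter_sd` mm - the ISI reading), or
#'   `"none"` (exact truth). Blood-pool voxels inside the reader's contours
#'   are read as bright only within the infarct's angular sector (the
#'   endocardial infarct border is the contour itself there).
#'
#' @param stack an [image_stack()].
#' @param mask logical myocardium volume (the reader's own, for
#'   simulated-reader mode).
#' @param truth optional `lge_truth`.
#' @param reader optional [reader_model()].
#' @param seed RNG seed for the reader's grey-shell decision.
#' @param ambiguity grey-shell handling, see above.
#' @param grey_frac,bright_frac display-reference thresholds for threshold
#'   mode, as fractions of the maximal myocardial intensity.
#' @return An object of class `lge_classification`: logical volumes
#'   `bright`, `grey`, `no_reflow`, and the `provenance` string.
#' @export
classify_regions <- function(stack, mask, truth = NULL, reader = NULL,
                             seed = NULL,
                             ambiguity = c("jitter", "inclusion", "none"),
                             grey_frac = 0.35, bright_frac = 0.7) {
  ambiguity <- match.arg(ambiguity)
  d <- dim(stack$data)
  if (!all(dim(mask) == d)) stopf("mask and stack are misaligned")
  if (is.null(truth)) {
    vals <- stack$data
    R <- max(vals[mask])
    bright <- mask & vals >= bright_frac * R
    grey <- mask & vals >= grey_frac * R & vals < bright_frac * R
    ## dark voxels enclosed by bright tissue (per slice) are no-reflow
    nr <- array(FALSE, dim = d)
    rem <- mask & !bright & !grey
    mu_rem <- if (any(rem)) mean(vals[rem]) else 0
    for (s in seq_len(d[3])) {
      b <- bright[, , s]
      if (!any(b)) next
      filled <- EBImage::fillHull(b) > 0
      cand <- filled & !b & vals[, , s] < mu_rem
      nr[, , s] <- cand
    }
    return(structure(list(bright = bright, grey = grey & !nr, no_reflow = nr,
                          provenance = "threshold"),
                     class = "lge_classification"))
  }
  if (!all(dim(truth$myocardium_mask) == d)) stopf("truth and stack are misaligned")
  ## simulated reader: truth classes within the reader's mask
  bright <- truth$infarct_core_mask & mask
  blood_in <- truth$blood_mask & mask & truth$sector_mask
  bright <- bright | blood_in
  nr <- truth$no_reflow_mask & mask
  shell <- truth$grey_zone_mask & mask
  grey <- shell
  if (ambiguity != "none" && any(shell)) {
    if (is.null(reader)) stopf("simulated-reader ambiguity needs a reader model")
    grey <- with_seed(seed, {
      if (ambiguity == "inclusion") {
        u <- runif(1, 0.5, 1)
        shell & truth$grey_depth <= u
      } else {
        delta <- rnorm(1, 0, reader$grey_boundary_jitter_sd) /
          max(truth$shell_width_mm, 1e-9)
        shell & truth$grey_depth <= 1 + delta
      }
    })
  }
  structure(list(bright = bright, grey = grey, no_reflow = nr,
                 provenance = "simulated-reader"),
            class = "lge_classification")
}

#' @export
print.lge_classification <- function(x, ...) {
  cat(sprintf("<lge_classification> %s: bright %d, grey %d, no-reflow %d voxels\n",
              x$provenance, sum(x$bright), sum(x$grey), sum(x$no_reflow)))
  invisible(x)
}

cls_to_map <- function(cls, d, grey_weight, method) {
  w <- array(0, dim = d)
  w[cls$grey] <- grey_weight
  w[cls$bright] <- 1
  w[cls$no_reflow] <- 1
  infarct_map(w, method)
}

#' Manual planimetry infarct size (MANUAL)
#'
#' All hyperenhanced tissue - fully bright, grey, and no-reflow - is
#' included at full weight.
#'
#' @param cls an [classify_regions()] result.
#' @param mask logical myocardium volume.
#' @param stack the aligned [image_stack()].
#' @param patient,reader optional labels.
#' @return A one-row measurement data.frame (see [infarct_size()]).
#' @export
manual_size <- function(cls, mask, stack, patient = NA_character_,
                        reader = NA_character_) {
  map <- cls_to_map(cls, dim(stack$data), grey_weight = 1, method = "MANUAL")
  infarct_size(map, mask, stack, patient, reader)
}

#' Manual planimetry with ISI adjustment (MANUAL-ISI)
#'
#' Fully bright and no-reflow regions at weight 1, grey (intermediate signal
#' intensity) regions at weight 0.5.
#'
#' @inheritParams manual_size
#' @return A one-row measurement data.frame.
#' @export
manual_isi_size <- function(cls, mask, stack, patient = NA_character_,
                            reader = NA_character_) {
  map <- cls_to_map(cls, dim(stack$data), grey_weight = 0.5, method = "MANUAL_ISI")
  infarct_size(map, mask, stack, patient, reader)
}
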
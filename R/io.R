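## External interchange formats: NIfTI volumes (spacing in the header),
## contour JSON (per-slice [x_mm, y_mm] vertex arrays, 0-based slice
## indices), measurement-table CSV, and report JSON.

#' Write an image stack (or aligned mask/weight volume) as NIfTI
#'
#' @param stack an [image_stack()].
#' @param path output `.nii`/`.nii.gz` path.
#' @param data optional alternative volume (mask or weights) aligned to the
#'   stack; defaults to the stack's intensities.
#' @return The path, invisibly.
#' @export
write_stack_nifti <- function(stack, path, data = NULL) {
  vol <- data %||% stack$data
  img <- RNifti::asNifti(vol * 1)
  RNifti::pixdim(img) <- c(stack$pixel_spacing,
                           stack$slice_thickness + stack$slice_gap)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as an image stack
#'
#' The third pixdim is taken as the slice thickness (gap 0; the writer folds
#' any gap into the voxel depth).
#'
#' @param path NIfTI file path.
#' @return An [image_stack()].
#' @export
read_stack_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  image_stack(array(as.numeric(img), dim = dim(img)),
              pixel_spacing = pd[1:2], slice_thickness = pd[3])
}

#' Write a contour set as JSON
#'
#' Per-slice arrays of `[x_mm, y_mm]` vertices under `endo` and `epi`, with
#' 0-based slice indices.
#'
#' @param contours an [contour_set()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_contours_json <- function(contours, path) {
  enc <- function(side) {
    out <- list()
    for (s in seq_along(side)) {
      if (is.null(side[[s]])) next
      out[[length(out) + 1L]] <- list(slice = s - 1L,
                                      vertices = unname(side[[s]]))
    }
    out
  }
  jsonlite::write_json(list(provenance = contours$provenance,
                            n_slices = length(contours$endo),
                            endo = enc(contours$endo), epi = enc(contours$epi)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour set from JSON
#'
#' @param path JSON path written by [write_contours_json()].
#' @return An [contour_set()].
#' @export
read_contours_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  dec <- function(side) {
    out <- vector("list", x$n_slices)
    if (length(side) == 0) return(out)
    for (i in seq_len(nrow(side))) {
      v <- side$vertices[[i]]
      out[[side$slice[i] + 1L]] <- matrix(as.numeric(v), ncol = 2L)
    }
    out
  }
  contour_set(dec(x$endo), dec(x$epi),
              provenance = if (identical(x$provenance, "reader")) "reader" else "truth")
}

#' Write / read a measurement table CSV
#'
#' Columns: patient, reader, method, percent_lv, mass_g, lv_mass_g.
#'
#' @param table measurement data.frame.
#' @param path CSV path.
#' @return The path (write) or the data.frame (read).
#' @export
write_measurements <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a reproducibility report as JSON
#'
#' @param report an [run_reproducibility()] result.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(value = report$value, methods = report$methods,
                            sample_sizes = report$sample_sizes),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Per patient: the image stack and ground-truth masks as NIfTI, the true
#' and per-reader contours as JSON; plus a cohort manifest CSV (patient,
#' reader, file paths, seed, true size).
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in seq_along(cohort$patients)) {
    pat <- cohort$patients[[p]]
    pid <- names(cohort$patients)[p]
    img_path <- file.path(dir, paste0(pid, "_lge.nii.gz"))
    write_stack_nifti(pat$stack, img_path)
    lab <- array(0L, dim = dim(pat$stack$data))
    lab[pat$truth$myocardium_mask] <- 1L
    lab[pat$truth$grey_zone_mask] <- 2L
    lab[pat$truth$infarct_core_mask] <- 3L
    lab[pat$truth$no_reflow_mask] <- 4L
    lab_path <- file.path(dir, paste0(pid, "_truth.nii.gz"))
    write_stack_nifti(pat$stack, lab_path, data = lab)
    tc_path <- file.path(dir, paste0(pid, "_contours_truth.json"))
    write_contours_json(pat$truth$true_contours, tc_path)
    for (r in names(pat$reader_contours)) {
      rc_path <- file.path(dir, paste0(pid, "_contours_", r, ".json"))
      write_contours_json(pat$reader_contours[[r]], rc_path)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pid, reader = r, image = basename(img_path),
        truth_labels = basename(lab_path), contours = basename(rc_path),
        seed = cohort$manifest$seed[p],
        true_percent_lv = cohort$manifest$true_percent_lv[p])
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Plot one slice of a stack
#'
#' Quick grayscale display with optional mask outline, for inspection.
#'
#' @param stack an [image_stack()].
#' @param slice slice index.
#' @param mask optional logical volume overlaid as contour shading.
#' @export
plot_slice <- function(stack, slice = ceiling(dim(stack$data)[3] / 2),
                       mask = NULL) {
  sl <- stack$data[, , slice]
  image(sl, col = grey.colors(128, 0, 1), asp = dim(sl)[2] / dim(sl)[1],
        axes = FALSE, main = sprintf("slice %d", slice))
  if (!is.null(mask)) {
    m <- mask[, , slice]
    if (any(m)) {
      xs <- (seq_len(nrow(m)) - 0.5) / nrow(m)
      ys <- (seq_len(ncol(m)) - 0.5) / ncol(m)
      graphics::contour(xs, ys, m * 1, levels = 0.5, add = TRUE,
                        drawlabels = FALSE, col = "red")
    }
  }
  invisible(NULL)
}
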
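test_that("extent scores follow the 5-point quartile scale", {
  expect_identical(extent_score(0), 0L)
  expect_identical(extent_score(0.40), 2L)
  expect_identical(extent_score(1.0), 4L)
  expect_identical(extent_score(c(0.25, 0.26, 0.5, 0.51, 0.75, 0.76)),
                   c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(extent_score(1.2), "\\[0, 1\\]")
  # monotone non-decreasing over a grid
  f <- seq(0, 1, by = 0.01)
  expect_true(all(diff(extent_score(f)) >= 0))
})

test_that("SI scores bin the intensity ratio on the same quartiles", {
  expect_identical(si_score(100, 100), 4L)
  expect_identical(si_score(55, 100), 3L)
  expect_identical(si_score(10, 100), 1L)
  expect_error(si_score(110, 100), "exceeds")
  expect_error(si_score(50, 0), "positive")
})

test_that("VISUAL size sums the printed midpoints over 17 segments", {
  expect_equal(visual_size(segment_scores(rep(1L, 17))), 13)
  expect_equal(visual_size(segment_scores(rep(0L, 17))), 0)
  sc <- segment_scores(c(rep(4L, 8), rep(0L, 9)))
  expect_equal(visual_size(sc), 8 * 88 / 17, tolerance = 1e-12)
  expect_error(segment_scores(c(rep(5L, 17))), "0\\.\\.4")
})

test_that("VISUAL-ISI weights extent midpoints by the SI weight", {
  sc <- segment_scores(rep(4L, 17), rep(4L, 17))
  expect_equal(visual_isi_size(sc), 88 * 0.88)

  # uniform si = 4 factorizes into 0.88 x visual_size
  set.seed(1)
  ext <- sample(0:4, 17, replace = TRUE)
  si <- ifelse(ext > 0, 4L, 0L)
  sc2 <- segment_scores(ext, si)
  expect_equal(visual_isi_size(sc2), 0.88 * visual_size(sc2), tolerance = 1e-12)

  # a zero-extent segment contributes nothing and si must then be 0
  expect_error(segment_scores(c(0L, rep(1L, 16)), rep(2L, 17)), "si must be")
  expect_error(visual_isi_size(segment_scores(rep(1L, 17))), "missing")

  # visual_isi <= visual for any valid scores
  for (i in 1:10) {
    ext <- sample(0:4, 17, replace = TRUE)
    si <- ifelse(ext > 0, sample(1:4, 17, replace = TRUE), 0L)
    sc3 <- segment_scores(ext, si)
    expect_lte(visual_isi_size(sc3), visual_size(sc3))
  }
})

test_that("visual_size is invariant to segment permutation", {
  set.seed(2)
  ext <- sample(0:4, 17, replace = TRUE)
  expect_equal(visual_size(segment_scores(ext)),
               visual_size(segment_scores(sample(ext))))
})

test_that("segment assignment is rotationally balanced on a uniform annulus", {
  spec <- uniform_spec(nslice = 9L, noise_sd = 0)
  ph <- generate_phantom(spec, seed = 1)
  mask <- ph$truth$myocardium_mask
  expect_warning(assign_segments(mask, ph$stack), "apical cap")
  labels <- suppressWarnings(assign_segments(mask, ph$stack))
  for (ring in list(1:6, 7:12, 13:16)) {
    counts <- vapply(ring, function(g) sum(labels == g, na.rm = TRUE), numeric(1))
    expect_lt(diff(range(counts)) / mean(counts), 0.02)
  }
  # every myocardial voxel is labelled
  expect_equal(sum(!is.na(labels)), sum(mask))
})

test_that("a basal voxel 30 degrees past the insertion angle lands in segment 1", {
  spec <- uniform_spec(nslice = 6L, noise_sd = 0)
  ph <- generate_phantom(spec, seed = 1)
  mask <- ph$truth$myocardium_mask
  labels <- suppressWarnings(assign_segments(mask, ph$stack,
                                             rv_insertion_angle = 20))
  ctr <- lgequant:::phantom_center(spec)
  a <- (20 + 30) * pi / 180
  p <- ctr + 25 * c(cos(a), sin(a))                 # mid-wall radius 25 mm
  ij <- round(p / spec$pixel_spacing + 0.5)
  expect_identical(labels[ij[1], ij[2], 1], 1L)
})

test_that("rotating anatomy and insertion angle together leaves labels fixed", {
  spec <- uniform_spec(nslice = 6L, noise_sd = 0)
  ph <- generate_phantom(spec, seed = 1)
  mask <- ph$truth$myocardium_mask
  l1 <- suppressWarnings(assign_segments(mask, ph$stack, rv_insertion_angle = 0))
  # rotate each slice by 90 degrees (x, y) -> (-y, x) and the origin with it
  rot <- function(a) {
    out <- array(a[1], dim = dim(a))
    for (s in seq_len(dim(a)[3])) out[, , s] <- t(a[, rev(seq_len(dim(a)[2])), s])
    out
  }
  stack2 <- image_stack(rot(ph$stack$data), spec$pixel_spacing,
                        spec$slice_thickness)
  l2 <- suppressWarnings(assign_segments(rot(mask), stack2,
                                         rv_insertion_angle = 90))
  expect_equal(rot(l1), l2, ignore_attr = TRUE)
})

test_that("the apical cap is assigned when the cavity has closed", {
  ph <- generate_phantom(small_template(), seed = 1)
  labels <- assign_segments(ph$truth$myocardium_mask, ph$stack)
  expect_true(attr(labels, "cap_assigned"))
  apical <- dim(labels)[3]
  expect_true(all(labels[, , apical][!is.na(labels[, , apical])] == 17L))
})

test_that("score_stack scores exactly the segment holding the infarct", {
  spec <- uniform_spec(nslice = 9L, noise_sd = 0)
  ph <- generate_phantom(spec, seed = 1)
  mask <- ph$truth$myocardium_mask
  labels <- suppressWarnings(assign_segments(mask, ph$stack))
  d <- dim(mask)
  mk <- function(x) array(x, dim = d)
  cls <- structure(list(bright = !is.na(labels) & labels == 8L,
                        grey = mk(FALSE), no_reflow = mk(FALSE),
                        provenance = "fixture"), class = "lge_classification")
  sc <- score_stack(cls, labels, ph$stack)
  expect_identical(sc$extent[8], 4L)
  expect_identical(sc$extent[-8], rep(0L, 16))
  expect_equal(visual_size(sc), 88 / 17)
})

test_that("an infarct-free phantom scores zero everywhere", {
  spec <- uniform_spec(nslice = 6L, transmural_fraction = 0, noise_sd = 0)
  ph <- generate_phantom(spec, seed = 1)
  mask <- ph$truth$myocardium_mask
  labels <- suppressWarnings(assign_segments(mask, ph$stack))
  cls <- classify_regions(ph$stack, mask, ph$truth,
                          reader_model(grey_boundary_jitter_sd = 0),
                          seed = 1, ambiguity = "none")
  sc <- score_stack(cls, labels, ph$stack)
  expect_true(all(sc$extent == 0L))
  expect_equal(visual_size(sc), 0)
})

test_that("a grey-only infarct is down-weighted by its SI score", {
  # grey plateau 350 vs blood-pool reference 800 -> ratio 0.44 -> si score 2
  spec <- uniform_spec(nslice = 6L, noise_sd = 0, intensity_remote_sd = 0,
                       grey_zone_width = 1, no_reflow_fraction = 0,
                       intensity_blood_pool = 800)
  ph <- generate_phantom(spec, seed = 1)
  mask <- ph$truth$myocardium_mask
  labels <- suppressWarnings(assign_segments(mask, ph$stack))
  cls <- classify_regions(ph$stack, mask, ph$truth,
                          reader_model(grey_boundary_jitter_sd = 0),
                          seed = 1, ambiguity = "none")
  sc <- score_stack(cls, labels, ph$stack)
  expect_true(all(sc$si[sc$extent > 0] == 2L))
  expect_lt(visual_isi_size(sc), visual_size(sc))
})

test_that("VISUAL stays within one midpoint bin of truth on clean phantoms", {
  for (ext_deg in c(45, 120, 200, 300)) {
    spec <- small_template(noise_sd = 0, intensity_remote_sd = 0,
                           grey_zone_width = 0, no_reflow_fraction = 0,
                           infarct_angular_extent = ext_deg)
    ph <- generate_phantom(spec, seed = 1)
    mask <- ph$truth$myocardium_mask
    labels <- suppressWarnings(assign_segments(mask, ph$stack))
    cls <- classify_regions(ph$stack, mask, ph$truth,
                            reader_model(grey_boundary_jitter_sd = 0),
                            seed = 1, ambiguity = "none")
    sc <- score_stack(cls, labels, ph$stack)
    expect_lt(abs(visual_size(sc) - ph$truth$true_infarct_percent_lv), 12)
  }
})
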
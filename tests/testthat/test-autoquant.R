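# Hand-built single-slice stacks with exact voxel counts (helpers in
# helper-phantom.R): the full grid is "myocardium" and bright sectors are
# carved in angular order, so expected sizes are exact voxel-count arithmetic.

test_that("weighted thresholding recovers a noiseless two-level sector exactly", {
  stack <- two_level_stack(n_bright = 120L)    # 30% of 400 voxels
  mask <- full_mask(stack)
  map <- weighted_infarct(stack, mask)
  expect_equal(infarct_size(map, mask, stack)$percent_lv, 30)
  expect_true(all(map$weights %in% c(0, 1)))
})

test_that("weighted thresholding half-weights a grey shell at (t+F)/2", {
  # t = remote mean = 100 (zero remote SD), F = 1000, grey at 550 -> w = 0.5
  stack <- two_level_stack(n_bright = 80L, grey_n = 40L, grey = 550)
  mask <- full_mask(stack)
  map <- weighted_infarct(stack, mask)
  expect_equal(infarct_size(map, mask, stack)$percent_lv, 25)  # 20*1 + 10*0.5
})

test_that("weighted thresholding reports no infarct on uniform myocardium", {
  stack <- flat_stack(20, 20, 1, value = 100)
  mask <- full_mask(stack)
  map <- weighted_infarct(stack, mask)
  expect_equal(sum(map$weights), 0)
  expect_equal(attr(map, "status"), "no infarct detected")
})

test_that("FWHM separates a binary phantom at half maximum", {
  stack <- two_level_stack(n_bright = 120L, bright = 1000, remote = 0)
  mask <- full_mask(stack)
  map <- fwhm_infarct(stack, mask, fwhm_params(max_estimator = "global_max"))
  expect_equal(infarct_size(map, mask, stack)$percent_lv, 30)
  expect_identical(map$weights > 0, stack$data > 500)
})

test_that("FWHM includes 0.6 M and excludes 0.4 M at the rim", {
  stack <- flat_stack(20, 20, 1, value = 0)
  ord <- angular_order(stack)
  stack$data[ord[1:40]] <- 1000
  stack$data[ord[41]] <- 600
  stack$data[ord[42]] <- 400
  mask <- full_mask(stack)
  map <- fwhm_infarct(stack, mask, fwhm_params(max_estimator = "global_max"))
  expect_equal(map$weights[ord[41]], 1)
  expect_equal(map$weights[ord[42]], 0)
})

test_that("FWHM refuses to call infarct on a uniform stack", {
  stack <- flat_stack(20, 20, 1, value = 100)
  mask <- full_mask(stack)
  expect_warning(map <- fwhm_infarct(stack, mask), "no credible")
  expect_equal(sum(map$weights), 0)
})

test_that("intensity-rescaling invariances hold on a noisy phantom", {
  spec <- uniform_spec(nslice = 4L, noise_sd = 15)
  ph <- generate_phantom(spec, seed = 21)
  mask <- ph$truth$myocardium_mask
  scale_stack <- function(stack, a, b)
    image_stack(a * stack$data + b, stack$pixel_spacing,
                stack$slice_thickness, stack$slice_gap)

  w1 <- weighted_infarct(ph$stack, mask)
  w2 <- weighted_infarct(scale_stack(ph$stack, 2, 50), mask)
  expect_equal(w1$weights, w2$weights, tolerance = 1e-9)

  hr <- fwhm_params(reference = "half_range")
  f1 <- fwhm_infarct(ph$stack, mask, hr)
  f2 <- fwhm_infarct(scale_stack(ph$stack, 2, 50), mask, hr)
  expect_equal(f1$weights, f2$weights)

  hm <- fwhm_params(reference = "half_max")
  g1 <- fwhm_infarct(ph$stack, mask, hm)
  g2 <- fwhm_infarct(scale_stack(ph$stack, 3, 0), mask, hm)
  expect_equal(g1$weights, g2$weights)
})

test_that("weighted size never exceeds FWHM size by more than half the grey mass", {
  spec <- uniform_spec(nslice = 4L, noise_sd = 0, intensity_remote_sd = 0,
                       grey_zone_width = 0.5, no_reflow_fraction = 0)
  ph <- generate_phantom(spec, seed = 2)
  mask <- ph$truth$myocardium_mask
  pw <- infarct_size(weighted_infarct(ph$stack, mask), mask, ph$stack)$percent_lv
  pf <- infarct_size(fwhm_infarct(ph$stack, mask), mask, ph$stack)$percent_lv
  grey_half <- 50 * sum(ph$truth$grey_zone_mask) / sum(mask)
  expect_lte(pw, pf + grey_half + 1e-9)
})

test_that("corrections add at weight 1, remove to 0, and reject overlap", {
  stack <- flat_stack(20, 20, 1)
  mask <- full_mask(stack)
  w <- array(0, dim = c(20, 20, 1)); w[1:80] <- 1
  map <- infarct_map(w, "AUTO_SEGMENT")

  expect_equal(apply_corrections(map, correction_set(), stack)$weights, w)

  add <- array(FALSE, dim = c(20, 20, 1)); add[101:120] <- TRUE  # 5% of 400
  p0 <- infarct_size(map, mask, stack)$percent_lv
  p1 <- infarct_size(apply_corrections(map, correction_set(add = list(add)),
                                       stack), mask, stack)$percent_lv
  expect_equal(p1 - p0, 5)

  rem <- w > 0
  p2 <- infarct_size(apply_corrections(map, correction_set(remove = list(rem)),
                                       stack), mask, stack)$percent_lv
  expect_equal(p2, 0)

  both <- add
  expect_error(apply_corrections(map, correction_set(add = list(add),
                                                     remove = list(both)), stack),
               "overlap")
})

test_that("polygon correction regions rasterize like masks", {
  stack <- flat_stack(20, 20, 1)
  mask <- full_mask(stack)
  map <- infarct_map(array(0, dim = c(20, 20, 1)), "AUTO_SEGMENT")
  poly <- lgequant:::circle_polygon(c(10, 10), 4, n = 64)
  out <- apply_corrections(map, correction_set(add = list(list(slice = 1L, xy = poly))),
                           stack)
  pts <- lgequant:::voxel_centers(stack)
  expected <- pip_oracle(poly, pts)
  expect_equal(as.vector(out$weights[, , 1] > 0), expected)
})

test_that("simulated corrections are gated by reader diligence", {
  spec <- uniform_spec(nslice = 4L, no_reflow_fraction = 0.3,
                       noise_sd = 0, intensity_remote_sd = 0)
  ph <- generate_phantom(spec, seed = 4)
  mask <- ph$truth$myocardium_mask
  map <- weighted_infarct(ph$stack, mask)

  full <- simulate_corrections(ph$truth, map,
                               reader_model(correction_completeness = 1), seed = 1)
  expect_length(full$add, 1L)
  none <- simulate_corrections(ph$truth, map,
                               reader_model(correction_completeness = 0), seed = 1)
  expect_length(none$add, 0L)
  expect_length(none$remove, 0L)

  # binomial Monte-Carlo on the no-reflow region across seeds
  rd <- reader_model(correction_completeness = 0.5)
  hits <- vapply(1:1000, function(s)
    length(simulate_corrections(ph$truth, map, rd, seed = s)$add) > 0, logical(1))
  expect_gte(mean(hits), 0.45)
  expect_lte(mean(hits), 0.55)
})
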
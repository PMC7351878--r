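test_that("surface area is exact pixel-count arithmetic", {
  pitch <- 4.5 / 320
  m <- matrix(FALSE, 320, 320)
  m[1:32, 1:32] <- TRUE                     # 1024 flow pixels
  expect_identical(surface_area(binary_flow_mask(m, pitch)), 1024 * pitch^2)
  expect_equal(surface_area(binary_flow_mask(m, pitch)), 0.2025)
  expect_identical(surface_area(binary_flow_mask(matrix(FALSE, 8, 8), pitch)),
                   0)
  # additivity over disjoint masks
  a <- matrix(FALSE, 64, 64); a[1:10, 1:10] <- TRUE
  b <- matrix(FALSE, 64, 64); b[40:50, 40:50] <- TRUE
  expect_equal(surface_area(binary_flow_mask(a | b, pitch)),
               surface_area(binary_flow_mask(a, pitch)) +
                 surface_area(binary_flow_mask(b, pitch)))
})

test_that("vessel density is the flow fraction of the region", {
  region <- matrix(FALSE, 40, 40); region[6:25, 6:35] <- TRUE    # 600 px
  flow <- matrix(FALSE, 40, 40); flow[6:15, 6:35] <- TRUE        # 300 px
  expect_identical(
    vessel_density(binary_flow_mask(flow, 0.01),
                   binary_flow_mask(region, 0.01)), 0.5)
  expect_identical(
    vessel_density(binary_flow_mask(region, 0.01),
                   binary_flow_mask(region, 0.01)), 1)
  # half-filled checkerboard: same density regardless of arrangement
  chk <- region & outer(1:40, 1:40, function(r, c) (r + c) %% 2 == 0)
  expect_equal(vessel_density(binary_flow_mask(chk, 0.01),
                              binary_flow_mask(region, 0.01)), 0.5)
  expect_error(
    vessel_density(binary_flow_mask(flow, 0.01),
                   binary_flow_mask(matrix(FALSE, 40, 40), 0.01)),
    "empty")
})

test_that("quantify_lesion composes the stages deterministically", {
  tr <- generate_vessel_tree(0.5, seed = 6)
  img <- rasterize_tree(tr, image_spec(noise_level = 0), seed = 1)
  q1 <- quantify_lesion(img)
  q2 <- quantify_lesion(img)
  expect_identical(q1[c("fd", "lac", "sa_mm2", "vd")],
                   q2[c("fd", "lac", "sa_mm2", "vd")])
  expect_true(q1$fd >= 0 && q1$fd <= 2)
  expect_true(q1$vd > 0 && q1$vd <= 1)
  expect_gte(q1$lac, 0)
})

test_that("a blank image yields a flagged empty-lesion record", {
  img <- enface_angiogram(matrix(0L, 128, 128), pixel_pitch_mm = 0.014)
  q <- suppressWarnings(quantify_lesion(img))
  expect_true("empty_lesion" %in% q$flags)
  expect_identical(q$sa_mm2, 0)
  expect_true(is.na(q$fd) && is.na(q$vd) && is.na(q$lac))
})

test_that("surface area is resolution-consistent on noise-free lesions", {
  # compared with a fixed mid-level threshold and without the pixel-scale
  # morphology stages, whose kernels are resolution-dependent by design
  tr <- generate_vessel_tree(0.45, seed = 10, radius_mm = 1.0)
  sa <- vapply(c(320L, 640L), function(w) {
    img <- rasterize_tree(tr, image_spec(width_px = w, noise_level = 0),
                          seed = 1)
    quantify_lesion(img, binarize_options = list(
      median_radius = 0, opening_radius = 0, min_object_px = 0,
      threshold = (0.08 + 0.85) / 2))$sa_mm2
  }, numeric(1))
  expect_lt(abs(sa[2] - sa[1]) / sa[1], 0.02)
})

test_that("intermediates are returned on request", {
  tr <- generate_vessel_tree(0.4, seed = 3)
  img <- rasterize_tree(tr, image_spec(), seed = 1)
  q <- quantify_lesion(img, keep_intermediates = TRUE)
  expect_s3_class(q$intermediates$skeleton, "skeleton_mask")
  expect_s3_class(q$intermediates$curve, "box_count_curve")
  expect_true(all(q$intermediates$skeleton$mask[
    !q$intermediates$lesion$mask$mask] == FALSE))
})
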
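test_that("degenerate images binarize to empty masks, not errors", {
  img <- enface_angiogram(matrix(0L, 64, 64), pixel_pitch_mm = 0.01)
  expect_warning(m <- binarize_flow(img), "constant")
  expect_false(any(m$mask))
})

test_that("a noise-free stroke is recovered within a 1-px boundary band", {
  seg <- data.frame(id = 1L, parent = 0L, x0 = 0.5, y0 = 2.25,
                    x1 = 4.0, y1 = 2.25, caliber_um = 60, generation = 0L)
  spec <- image_spec(noise_level = 0)
  img <- rasterize_tree(manual_tree(seg), spec, seed = 1)
  mask <- binarize_flow(img)$mask
  truth <- img$pixels > (0.5 * 255)       # mid-coverage stroke footprint
  grow <- function(m) {                    # one-pixel dilation
    out <- m
    H <- nrow(m); W <- ncol(m)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(seq_len(H) + dr, 1), H)
      cs <- pmin(pmax(seq_len(W) + dc, 1), W)
      out <- out | m[rs, cs]
    }
    out
  }
  expect_true(all(mask[!grow(truth)] == FALSE))   # mask within truth + 1 px
  expect_true(all(truth[!grow(mask)] == FALSE))   # truth within mask + 1 px
})

test_that("the inversion flag makes binarization contrast-symmetric", {
  tr <- generate_vessel_tree(0.5, seed = 4)
  img <- rasterize_tree(tr, image_spec(), seed = 1)
  inv <- img
  inv$pixels <- 255L - img$pixels
  expect_identical(binarize_flow(img)$mask,
                   binarize_flow(inv, invert = TRUE)$mask)
})

test_that("delineation keeps the dominant lesion and drops distant specks", {
  m <- matrix(FALSE, 120, 120)
  m[40:80, 40:80] <- TRUE                  # dominant lesion
  m[5:6, 5:7] <- TRUE                      # distant 6-px speck
  flow <- binary_flow_mask(m, 0.014)
  les <- delineate_lesion(flow, envelope_px = 20)
  expect_equal(les$n_components, 1L)
  expect_false(any(les$mask$mask[5:6, 5:7]))
  # hull of a rectangle is the rectangle itself
  expect_true(all(les$region$mask[40:80, 40:80]))
  expect_equal(sum(les$region$mask), sum(les$mask$mask))
})

test_that("two touching lobes stay in one delineation with one hull", {
  m <- matrix(FALSE, 100, 100)
  m[30:60, 20:50] <- TRUE
  m[45:75, 48:80] <- TRUE                  # overlapping second lobe
  les <- delineate_lesion(binary_flow_mask(m, 0.014))
  expect_equal(les$n_components, 1L)
  expect_true(all(les$region$mask[m]))     # region covers the flow
  # the hull is convex: it covers the bounding midline between the lobes
  expect_true(all(les$region$mask[45:60, 30:70]))
})

test_that("an empty mask delineates to a flagged empty lesion", {
  les <- delineate_lesion(binary_flow_mask(matrix(FALSE, 32, 32), 0.014))
  expect_true(les$empty)
  expect_equal(les$n_components, 0L)
})
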
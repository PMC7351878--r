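test_that("an empty tree with no noise rasterizes to uniform background", {
  tr <- manual_tree(data.frame(id = integer(), parent = integer(),
                               x0 = numeric(), y0 = numeric(),
                               x1 = numeric(), y1 = numeric(),
                               caliber_um = numeric(),
                               generation = integer())[0, ])
  spec <- image_spec(width_px = 64, noise_level = 0, background_level = 0.1)
  img <- rasterize_tree(tr, spec, seed = 1)
  expect_equal(length(unique(as.vector(img$pixels))), 1L)
  expect_equal(img$pixels[1, 1], as.integer(round(0.1 * 255)))
})

test_that("a single trunk round-trips to a one-component line of FD ~ 1", {
  seg <- data.frame(id = 1L, parent = 0L, x0 = 0.05, y0 = 2.25,
                    x1 = 4.45, y1 = 2.25, caliber_um = 50, generation = 0L)
  img <- rasterize_tree(manual_tree(seg), image_spec(noise_level = 0),
                        seed = 1)
  mask <- binarize_flow(img)
  expect_equal(octaquant:::count_components(mask$mask), 1L)
  skel <- skeletonize_mask(mask)
  fd <- estimate_fractal_dimension(box_count_multi_origin(skel))
  expect_equal(fd$fd, 1.0, tolerance = 0.05)
})

test_that("noise only perturbs pixels: binarization is stable across seeds", {
  tr <- generate_vessel_tree(0.5, seed = 9)
  spec <- image_spec(noise_level = 0.1)
  a <- rasterize_tree(tr, spec, seed = 1)
  b <- rasterize_tree(tr, spec, seed = 2)
  expect_false(identical(a$pixels, b$pixels))
  ma <- binarize_flow(a)$mask
  mb <- binarize_flow(b)$mask
  expect_lt(mean(ma != mb), 0.01)       # masks agree within a small margin
})

test_that("rasterization is deterministic per seed and validates the field", {
  tr <- generate_vessel_tree(0.4, seed = 2)
  spec <- image_spec()
  expect_identical(rasterize_tree(tr, spec, seed = 5)$pixels,
                   rasterize_tree(tr, spec, seed = 5)$pixels)
  bad <- manual_tree(data.frame(id = 1L, parent = 0L, x0 = -1, y0 = 1,
                                x1 = 1, y1 = 1, caliber_um = 30,
                                generation = 0L))
  expect_error(rasterize_tree(bad, spec, seed = 1), "outside the field")
})

test_that("angiograms survive a PNG and TIFF round trip", {
  tr <- generate_vessel_tree(0.4, seed = 2)
  img <- rasterize_tree(tr, image_spec(), seed = 1)
  for (ext in c("png", "tiff")) {
    path <- file.path(tempdir(), paste0("oq_roundtrip.", ext))
    write_angiogram(img, path)
    back <- read_angiogram(path, field_mm = 4.5)
    expect_identical(back$pixels, img$pixels)
    expect_equal(back$pixel_pitch_mm, img$pixel_pitch_mm)
    unlink(path)
  }
})
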
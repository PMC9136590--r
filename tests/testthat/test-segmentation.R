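test_that("illumination flattening is the identity on a constant image", {
  img <- grayscale_image(matrix(0.5, 256, 256))
  g <- plate_geometry(c(128, 128), 100)
  out <- preprocess(img, g, small_config())
  expect_lt(diff(range(out$pixels)), 1e-3)
})

test_that("a pure vignette flattens to a near-constant plate interior", {
  gen <- generate_synthetic_plate(
    small_spec(worms_per_quadrant = c(0L, 0L, 0L, 0L), center_worms = 0L,
               debris_count = 0L, noise_sd = 0, vignette_strength = 0.5))
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  m <- build_region_map(g, dim(flat$pixels))
  expect_lt(diff(range(flat$pixels[m > 0])), 0.05)
})

test_that("flattening preserves blob/background contrast under vignette", {
  spec <- small_spec(seed = 6, noise_sd = 0, vignette_strength = 0.5)
  gen <- generate_synthetic_plate(spec)
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  fg <- gen$truth$foreground_mask
  m <- build_region_map(g, dim(flat$pixels))
  bg_in <- !fg & m > 0
  raw_contrast <- mean(gen$image$pixels[bg_in]) - mean(gen$image$pixels[fg])
  flat_contrast <- mean(flat$pixels[bg_in]) - mean(flat$pixels[fg])
  expect_gt(flat_contrast, 0.8 * raw_contrast)
})

test_that("a blank noiseless plate yields an empty mask with a warning", {
  gen <- generate_synthetic_plate(
    small_spec(worms_per_quadrant = c(0L, 0L, 0L, 0L), center_worms = 0L,
               debris_count = 0L, noise_sd = 0, vignette_strength = 0))
  g <- gen$truth$true_geometry
  expect_warning(mask <- segment_foreground(gen$image, g, small_config()),
                 "degenerate")
  expect_identical(sum(mask), 0L)
})

test_that("an object-free noisy plate segments empty, and scores CI as NA", {
  gen <- generate_synthetic_plate(
    small_spec(worms_per_quadrant = c(0L, 0L, 0L, 0L), center_worms = 0L,
               debris_count = 0L, noise_sd = 0.02))
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  expect_warning(mask <- segment_foreground(flat, g, small_config()),
                 "no object/background separation")
  expect_identical(sum(mask), 0L)
  suppressWarnings(row <- score_image(gen$image, small_config()))
  expect_true(is.na(row$ci))
})

test_that("thresholding recovers blob area within 10% at strong contrast", {
  for (seed in c(3, 14)) {
    gen <- generate_synthetic_plate(small_spec(seed = seed))
    g <- gen$truth$true_geometry
    flat <- preprocess(gen$image, g, small_config())
    mask <- segment_foreground(flat, g, small_config())
    truth <- sum(gen$truth$foreground_mask)
    expect_lt(abs(sum(mask) - truth) / truth, 0.10)
  }
})

test_that("polarity flag on an inverted image gives the identical mask", {
  gen <- generate_synthetic_plate(small_spec(seed = 10))
  g <- gen$truth$true_geometry
  inv <- grayscale_image(1 - gen$image$pixels)
  m_dark <- segment_foreground(gen$image, g, small_config(polarity = "dark"))
  m_light <- segment_foreground(inv, g, small_config(polarity = "light"))
  expect_identical(m_dark, m_light)
})

test_that("specks below the area floor are filtered and counted", {
  mask <- matrix(FALSE, 128, 128)
  mask[60, 60:61] <- TRUE                    # 2-px speck
  g <- plate_geometry(c(64, 64), 50)
  res <- filter_objects(mask, g, small_config(min_area_px = 10))
  expect_identical(sum(res$mask), 0L)
  expect_identical(res$filtered_pixels, 2L)
})

test_that("debris pixels are filtered while worm area is preserved exactly", {
  gen <- generate_synthetic_plate(small_spec(seed = 12, debris_count = 5L,
                                             noise_sd = 0))
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  raw <- segment_foreground(flat, g, small_config())
  res <- filter_objects(raw, g, small_config())
  expect_identical(res$filtered_pixels, 15L)   # 5 specks x 3 px
  expect_identical(sum(res$mask), sum(gen$truth$worm_mask))
})

test_that("the spot-edge ring is filtered, not scored as worm area", {
  spec <- small_spec(seed = 15, noise_sd = 0, debris_count = 0L,
                     spot_ring = list(quadrant = 1, radius = 14,
                                      thickness = 2))
  gen <- generate_synthetic_plate(spec)
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  raw <- segment_foreground(flat, g, small_config())
  res <- filter_objects(raw, g, small_config())
  expect_identical(res$filtered_pixels,
                   as.integer(gen$truth$true_ring_pixels))
  regions <- build_region_map(g, dim(gen$image$pixels))
  areas <- measure_quadrant_areas(res$mask, regions)
  expect_identical(areas$q1, as.integer(gen$truth$true_area_per_quadrant[1]))
  # ... and survives when the ring filter is disabled for parity runs
  res_off <- filter_objects(raw, g, small_config(ring_filter = FALSE))
  expect_identical(res_off$filtered_pixels, 0L)
})

test_that("kept + filtered pixels conserve the raw foreground exactly", {
  gen <- generate_synthetic_plate(small_spec(seed = 16))
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  raw <- segment_foreground(flat, g, small_config())
  res <- filter_objects(raw, g, small_config())
  expect_identical(sum(res$mask) + res$filtered_pixels, sum(raw))
})

test_that("raising the area floor never decreases filtered pixels", {
  gen <- generate_synthetic_plate(small_spec(seed = 17))
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  raw <- segment_foreground(flat, g, small_config())
  prev <- -1L
  for (floor_px in c(0, 5, 15, 40, 80, 200)) {
    res <- filter_objects(raw, g, small_config(min_area_px = floor_px))
    expect_gte(res$filtered_pixels, prev)
    prev <- res$filtered_pixels
  }
})

test_that("filtering its own kept mask removes nothing", {
  gen <- generate_synthetic_plate(small_spec(seed = 18))
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  raw <- segment_foreground(flat, g, small_config())
  res <- filter_objects(raw, g, small_config())
  again <- filter_objects(res$mask, g, small_config())
  expect_identical(again$filtered_pixels, 0L)
  expect_identical(again$mask, res$mask)
})

test_that("kept objects report area, bounding box and elongation", {
  gen <- generate_synthetic_plate(small_spec(seed = 19, debris_count = 0L,
                                             center_worms = 0L,
                                             noise_sd = 0))
  g <- gen$truth$true_geometry
  flat <- preprocess(gen$image, g, small_config())
  raw <- segment_foreground(flat, g, small_config())
  res <- filter_objects(raw, g, small_config())
  expect_gt(nrow(res$objects), 0)
  expect_identical(sum(res$objects$area), sum(res$mask))
  # random-walk worms are elongated, far from disc-compact
  expect_true(all(res$objects$elongation > 1))
})
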
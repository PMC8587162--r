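test_that("binarization handles all-sky, all-canopy and half-and-half scenes", {
  white <- flat_rgb(64, 64, c(1, 1, 1))
  black <- flat_rgb(64, 64, c(0, 0, 0))
  expect_warning(gm_w <- binarize_canopy(white), "degenerate")
  expect_equal(sum(gm_w$sky_mask) / gm_w$total_pixels, 1)
  expect_warning(gm_b <- binarize_canopy(black), "degenerate")
  expect_equal(sum(gm_b$sky_mask) / gm_b$total_pixels, 0)

  sc <- make_canopy_scene(ff_true = 0.5, phi_true = 0, n_large_gaps = 1,
                          size = 128, rng_seed = 4)
  gm <- binarize_canopy(sc$image)
  expect_equal(sum(gm$sky_mask) / gm$total_pixels, 0.5, tolerance = 0.01)

  # fixed threshold requires the threshold argument
  expect_error(binarize_canopy(sc$image, method = "fixed"), "fixed_threshold")
  # isodata agrees with otsu on a well-separated scene
  gm_iso <- binarize_canopy(sc$image, method = "isodata")
  expect_equal(mean(gm$sky_mask == gm_iso$sky_mask), 1, tolerance = 1e-3)
})

test_that("gap classification separates large between-crown gaps from speckle", {
  # one gap covering 40% of the image, threshold 0.10 -> large
  img <- flat_rgb(100, 100, c(0.1, 0.3, 0.1))
  img <- paint_rect(img, 1:100, 1:40, c(0.95, 0.95, 0.95))
  gm <- classify_gaps(binarize_canopy(img), large_gap_threshold = 0.10)
  expect_equal(nrow(gm$components), 1L)
  expect_equal(gm$components$label, "large")

  # 100 isolated single-pixel gaps in 256x256, threshold 0.01 -> all small
  img2 <- flat_rgb(256, 256, c(0.1, 0.3, 0.1))
  rc <- expand.grid(r = seq(5, 250, by = 25), c = seq(5, 250, by = 25))[1:100, ]
  for (i in 1:100) img2[rc$r[i], rc$c[i], ] <- c(0.95, 0.95, 0.95)
  gm2 <- classify_gaps(binarize_canopy(img2), large_gap_threshold = 0.01)
  expect_equal(nrow(gm2$components), 100L)
  expect_true(all(gm2$components$label == "small"))

  # generator scene: 2 between-crown gaps of 8% each plus fine speckle
  sc <- make_canopy_scene(ff_true = 0.84, phi_true = 0.08, n_large_gaps = 2,
                          size = 256, rng_seed = 9)
  gm3 <- classify_gaps(binarize_canopy(sc$image), large_gap_threshold = 0.01)
  expect_equal(sum(gm3$components$label == "large"), 2L)
})

test_that("gap components are 8-connected and counts tally with the mask", {
  # diagonal speckle merges into single components
  img <- flat_rgb(64, 64, c(0.1, 0.3, 0.1))
  for (i in 0:5) img[10 + i, 10 + i, ] <- c(0.95, 0.95, 0.95)
  gm <- classify_gaps(binarize_canopy(img), large_gap_threshold = 0.01)
  expect_equal(nrow(gm$components), 1L)
  expect_equal(gm$components$pixel_count, 6L)

  sc <- make_canopy_scene(0.75, 0.2, rng_seed = 2, size = 128)
  gm2 <- classify_gaps(binarize_canopy(sc$image))
  expect_equal(sum(gm2$components$pixel_count), sum(gm2$sky_mask))
})

test_that("metrics satisfy the porosity identity and degenerate conventions", {
  for (seed in 1:5) {
    sc <- make_canopy_scene(runif(1, 0.6, 0.9), runif(1, 0.05, 0.3),
                            size = 128, rng_seed = seed)
    m <- analyze_canopy_image(sc$image)
    expect_equal(m$phi, 1 - m$fc / m$ff, tolerance = 1e-9)
    expect_true(m$fc <= m$ff)
    expect_equal(m$lai_e, m$omega * m$lai, tolerance = 1e-9)
  }
  # fc = ff (no within-crown gaps): porosity at the lower clamp
  sc0 <- make_canopy_scene(0.8, 0, size = 128, rng_seed = 1)
  m0 <- analyze_canopy_image(sc0$image)
  expect_lt(m0$phi, 1e-5)
  # all-canopy image: porosity clamped, lai finite and large, warning recorded
  expect_warning(m1 <- analyze_canopy_image(flat_rgb(64, 64, c(0.1, 0.3, 0.1))))
  expect_equal(m1$fc, 1)
  expect_equal(m1$ff, 1)
  expect_true(is.finite(m1$lai) && m1$lai > 5)
  # all-sky image: fc = 0, lai = 0
  expect_warning(m2 <- analyze_canopy_image(flat_rgb(64, 64, c(1, 1, 1))))
  expect_equal(m2$fc, 0)
  expect_equal(m2$lai, 0)
})

test_that("lai is monotone: decreasing in porosity, proportional to crown cover", {
  phis <- seq(0.05, 0.9, by = 0.05)
  lais <- lai_from_cover(0.8, phis)
  expect_true(all(diff(lais) <= 0))
  ffs <- seq(0.1, 1, by = 0.1)
  expect_equal(lai_from_cover(ffs, 0.2) / ffs,
               rep(lai_from_cover(1, 0.2), length(ffs)), tolerance = 1e-12)
})

test_that("pipeline gap fractions equal brute-force pixel counting", {
  for (seed in 1:3) {
    sc <- make_canopy_scene(0.7 + 0.05 * seed, 0.1 + 0.03 * seed,
                            size = 128, rng_seed = seed)
    gm <- classify_gaps(binarize_canopy(sc$image))
    m <- compute_metrics(gm)
    expect_equal(1 - m$fc, gap_fraction_oracle(gm$sky_mask), tolerance = 1e-12)
  }
})

test_that("scene recovery hits the generator ground truth", {
  sc <- make_canopy_scene(ff_true = 0.80, phi_true = 0.20, rng_seed = 21)
  m <- analyze_canopy_image(sc$image)
  expect_lt(abs(m$ff - sc$truth$ff), 0.02)
  expect_lt(abs(m$phi - sc$truth$phi), 0.03)
})

test_that("manifest batching averages the two side images per plant", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "east.png"); p2 <- file.path(dir, "west.png")
  write_rgb_image(make_canopy_scene(0.85, 0.15, rng_seed = 1, size = 128)$image, p1)
  write_rgb_image(make_canopy_scene(0.75, 0.25, rng_seed = 2, size = 128)$image, p2)
  manifest <- data.frame(source_id = c("e", "w"), path = c(p1, p2),
                         plant_id = "plant1", side = c("east", "west"))
  res <- analyze_canopy_manifest(manifest)
  expect_equal(nrow(res$per_image), 2L)
  expect_equal(nrow(res$per_plant), 1L)
  expect_equal(res$per_plant$ff, mean(res$per_image$ff), tolerance = 1e-12)
})
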
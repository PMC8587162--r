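test_that("berry detection finds the ellipse and applies the largest-component rule", {
  b <- make_berry_image(1, size = 192, rng_seed = 3)
  mask <- detect_berry_mask(b$image)
  expect_equal(mask$area_px, b$truth$interior_px,
               tolerance = 0.01 * b$truth$interior_px / mask$area_px)
  expect_gt(nrow(mask$contour), 10L)

  expect_error(detect_berry_mask(flat_rgb(96, 96, c(0.02, 0.02, 0.02))),
               "no berry detected")

  # two blobs, areas ~10A and A: the big one wins
  img <- flat_rgb(200, 200, c(0.03, 0.03, 0.03))
  img <- paint_rect(img, 20:119, 20:119, c(0.4, 0.8, 0.3))   # 100x100
  img <- paint_rect(img, 150:181, 150:181, c(0.4, 0.8, 0.3)) # 32x32
  m2 <- detect_berry_mask(img)
  expect_true(m2$mask[60, 60])
  expect_false(m2$mask[160, 160])
  expect_equal(m2$area_px, 100 * 100)
})

test_that("living-tissue segmentation recovers the painted fraction", {
  b <- make_berry_image(0.70, size = 192, rng_seed = 5)
  berry <- detect_berry_mask(b$image)
  lt <- segment_living_tissue(b$image, berry)
  expect_true(all(!(lt & !berry$mask)))
  expect_equal(sum(lt) / berry$area_px, 0.70, tolerance = 0.02)

  b1 <- make_berry_image(1, size = 128, rng_seed = 1)
  berry1 <- detect_berry_mask(b1$image)
  expect_equal(sum(segment_living_tissue(b1$image, berry1)) / berry1$area_px,
               1, tolerance = 0.02)

  b0 <- make_berry_image(0, size = 128, rng_seed = 1)
  berry0 <- detect_berry_mask(b0$image)
  expect_equal(sum(segment_living_tissue(b0$image, berry0)), 0L)
})

test_that("vitality arithmetic matches brute-force pixel bookkeeping", {
  berry <- structure(
    list(mask = matrix(TRUE, 100, 100), contour = matrix(0, 0, 2),
         area_px = 10000L),
    class = "berry_mask"
  )
  all_lt <- matrix(TRUE, 100, 100)
  no_lt <- matrix(FALSE, 100, 100)
  r_all <- compute_vitality(all_lt, berry)
  expect_equal(c(r_all$lt_percent, r_all$bcd_percent), c(100, 0))
  r_none <- compute_vitality(no_lt, berry)
  expect_equal(c(r_none$lt_percent, r_none$bcd_percent), c(0, 100))

  # LT 55% of berry, seed polygon = 10% of area lying wholly in dead tissue:
  # lt% = 100 * 0.55 / 0.90 = 61.11
  lt55 <- matrix(FALSE, 100, 100); lt55[1:55, ] <- TRUE
  seed_poly <- rbind(c(90.5, 0.5), c(90.5, 100.5), c(100.5, 100.5), c(100.5, 0.5))
  r <- compute_vitality(lt55, berry, seed_poly)
  expect_equal(r$seed_area_px, 1000L)
  expect_equal(r$lt_percent, 100 * 0.55 / 0.90, tolerance = 1e-9)
  expect_equal(r$lt_percent + r$bcd_percent, 100, tolerance = 1e-9)

  # seed covering the whole berry is rejected
  whole <- rbind(c(0.5, 0.5), c(0.5, 100.5), c(100.5, 100.5), c(100.5, 0.5))
  expect_error(compute_vitality(lt55, berry, whole), "empty effective area")
  expect_error(compute_vitality(matrix(TRUE, 100, 100) | TRUE,
                                structure(list(mask = matrix(FALSE, 100, 100),
                                               area_px = 0L),
                                          class = "berry_mask")),
               "subset")
})

test_that("seed exclusion shifts lt% in the expected direction", {
  berry <- structure(list(mask = matrix(TRUE, 60, 60), contour = matrix(0, 0, 2),
                          area_px = 3600L), class = "berry_mask")
  lt <- matrix(FALSE, 60, 60); lt[1:30, ] <- TRUE  # top half living
  base <- compute_vitality(lt, berry)$lt_percent
  seed_in_dead <- rbind(c(40.5, 10.5), c(40.5, 30.5), c(50.5, 30.5), c(50.5, 10.5))
  seed_in_live <- rbind(c(10.5, 10.5), c(10.5, 30.5), c(20.5, 30.5), c(20.5, 10.5))
  expect_gt(compute_vitality(lt, berry, seed_in_dead)$lt_percent, base)
  expect_lt(compute_vitality(lt, berry, seed_in_live)$lt_percent, base)
})

test_that("vitality is equivariant to rotation and mirroring", {
  b <- make_berry_image(0.55, size = 160, rng_seed = 8)
  base <- analyze_berry_image(b$image)$result$lt_percent
  rot <- array(0, c(160, 160, 3))
  for (ch in 1:3) rot[, , ch] <- t(b$image[, , ch])[, 160:1]
  mir <- b$image[, 160:1, ]
  expect_lt(abs(analyze_berry_image(rot)$result$lt_percent - base), 0.5)
  expect_lt(abs(analyze_berry_image(mir)$result$lt_percent - base), 0.5)
})

test_that("pipeline recovery matches generator ground truth within 2 points", {
  b <- make_berry_image(0.55, with_seed = TRUE, size = 192, rng_seed = 2)
  a <- analyze_berry_image(b$image, seed_polygon = b$truth$seed_polygon)
  expect_lt(abs(a$result$lt_percent - 100 * b$truth$lt_fraction_effective), 2)
  expect_equal(a$result$lt_percent + a$result$bcd_percent, 100, tolerance = 1e-9)
})

test_that("mask export round-trips losslessly in PNG and approximately in JPG", {
  b <- make_berry_image(0.4, size = 128, rng_seed = 6)
  a <- analyze_berry_image(b$image)
  dir <- withr::local_tempdir()
  paths <- export_masks(a$result, a$berry, a$lt_mask, dir, "b1", format = "png")
  lt_back <- read_rgb_image(paths[["lt"]])[, , 1] > 0.5
  berry_back <- read_rgb_image(paths[["berry"]])[, , 1] > 0.5
  berry2 <- structure(list(mask = berry_back, contour = a$berry$contour,
                           area_px = sum(berry_back)), class = "berry_mask")
  r2 <- compute_vitality(lt_back, berry2)
  expect_equal(r2$lt_percent, a$result$lt_percent, tolerance = 1e-9)

  pj <- export_masks(a$result, a$berry, a$lt_mask, dir, "b1j", format = "jpg")
  ltj <- read_rgb_image(pj[["lt"]])[, , 1] > 0.5
  berryj <- read_rgb_image(pj[["berry"]])[, , 1] > 0.5
  berry3 <- structure(list(mask = berryj, contour = a$berry$contour,
                           area_px = sum(berryj)), class = "berry_mask")
  r3 <- compute_vitality(ltj & berryj, berry3)
  expect_lt(abs(r3$lt_percent - a$result$lt_percent), 0.5)

  row <- utils::read.csv(paths[["csv"]])
  expect_equal(row$lt_percent + row$bcd_percent, 100, tolerance = 1e-9)
})
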
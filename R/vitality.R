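#' Living/dead tissue quantification from FDA fluorescence images
#'
#' A halved grape berry stained with fluorescein diacetate (FDA) fluoresces
#' green where mesocarp cells are alive. The berry outline is segmented on
#' overall brightness, living tissue (LT) is segmented inside it on a
#' green-dominance score, an optional manually supplied seed polygon is
#' excluded, and percent living tissue and percent berry cell death
#' (BCD = 100 - LT) are computed over the effective (seed-free) berry area.
#'
#' @name berry_vitality
NULL

#' Detect the berry outline in a fluorescence image
#'
#' Thresholds overall brightness (Otsu), applies morphological closing and
#' hole filling, and keeps the largest 8-connected foreground component.
#'
#' @param image `rows x cols x 3` array in \[0, 1\] (or `fluorescence_image`).
#' @param min_area_frac smallest acceptable berry area as a fraction of the
#'   image (default 0.01); below it the function errors ("no berry detected").
#' @param closing_radius radius in pixels of the closing brush (default 3).
#' @return object of class `berry_mask`: list with `mask` (logical matrix),
#'   `contour` (ordered `row, col` matrix), `area_px`.
#' @export
detect_berry_mask <- function(image, min_area_frac = 0.01, closing_radius = 3L) {
  px <- if (is.list(image) && !is.null(image$pixels)) image$pixels else image
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  bright <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  if (max(bright) - min(bright) < 1e-9) stop("no berry detected")
  thr <- otsu_threshold(as.vector(bright))
  fg <- bright > thr
  brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
  fg <- EBImage::closing(fg * 1, brush) > 0.5
  fg <- EBImage::fillHull(fg * 1) > 0.5
  lab <- label_components8(fg)
  if (max(lab) == 0L) stop("no berry detected")
  counts <- tabulate(lab[lab > 0], nbins = max(lab))
  biggest <- which.max(counts)
  if (counts[biggest] < min_area_frac * length(bright)) stop("no berry detected")
  mask <- lab == biggest
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  # EBImage works in (x, y) = (row-index-as-x); convert to (row, col)
  contour <- if (length(oc) > 0) cbind(oc[[1]][, 1] + 1L, oc[[1]][, 2] + 1L) else
    matrix(integer(0), 0, 2)
  structure(
    list(mask = mask, contour = contour, area_px = sum(mask)),
    class = "berry_mask"
  )
}

#' Segment living tissue inside a berry mask
#'
#' Scores each pixel by green dominance `g - max(r, b)`; pixels inside the
#' berry whose score exceeds an Otsu (or fixed) threshold — and is strictly
#' positive — are living tissue. Zero living pixels is a valid outcome.
#'
#' @param image `rows x cols x 3` array in \[0, 1\].
#' @param berry a `berry_mask` from [detect_berry_mask()].
#' @param threshold `"otsu"` or a fixed numeric score cut in (-1, 1).
#' @return logical matrix, subset of `berry$mask`.
#' @export
segment_living_tissue <- function(image, berry, threshold = "otsu") {
  px <- if (is.list(image) && !is.null(image$pixels)) image$pixels else image
  stopifnot(inherits(berry, "berry_mask"))
  score <- px[, , 2] - pmax(px[, , 1], px[, , 3])
  inside <- score[berry$mask]
  if (identical(threshold, "otsu")) {
    if (length(inside) == 0L || max(inside) <= 0) return(berry$mask & FALSE)
    # map scores [-1, 1] -> [0, 1] for the histogram threshold
    thr <- otsu_threshold((inside + 1) / 2) * 2 - 1
    # a unimodal score distribution (all-living or all-dead interior) makes
    # Otsu split noise in half; fall back to the sign rule when the classes
    # it proposes are not really separated
    m0 <- mean(inside[inside <= thr]); m1 <- mean(inside[inside > thr])
    if (!is.finite(m0) || !is.finite(m1) || (m1 - m0) < 0.15) thr <- 0
    thr <- max(thr, 0)
  } else {
    thr <- threshold
  }
  berry$mask & (score > thr)
}

#' Compute percent living tissue and berry cell death
#'
#' The effective area is the berry minus the seed region; LT% is the share
#' of effective-area pixels that are living, and BCD% is its complement
#' (the BCD mask is the inverted LT mask within the effective area).
#'
#' @param lt_mask logical matrix, living-tissue pixels (subset of berry mask).
#' @param berry a `berry_mask`.
#' @param seed_polygon optional two-column matrix (row, col) of seed-region
#'   vertices; `NULL` for no seed.
#' @return object of class `vitality_result`: list with `lt_percent`,
#'   `bcd_percent`, `berry_area_px`, `seed_area_px`, `lt_area_px`.
#' @export
compute_vitality <- function(lt_mask, berry, seed_polygon = NULL) {
  stopifnot(inherits(berry, "berry_mask"))
  if (any(lt_mask & !berry$mask)) stop("lt_mask must be a subset of the berry mask")
  seed_mask <- polygon_mask(seed_polygon, nrow(berry$mask), ncol(berry$mask)) &
    berry$mask
  effective <- berry$mask & !seed_mask
  eff_area <- sum(effective)
  if (eff_area == 0L) stop("empty effective area")
  lt_area <- sum(lt_mask & effective)
  lt_percent <- 100 * lt_area / eff_area
  structure(
    list(
      lt_percent = lt_percent,
      bcd_percent = 100 - lt_percent,
      berry_area_px = berry$area_px,
      seed_area_px = sum(seed_mask),
      lt_area_px = lt_area
    ),
    class = "vitality_result"
  )
}

#' Analyze one berry image end to end
#'
#' @inheritParams detect_berry_mask
#' @inheritParams segment_living_tissue
#' @param seed_polygon optional seed polygon (row, col vertices).
#' @return list with `result` (`vitality_result`), `berry`, `lt_mask`.
#' @export
analyze_berry_image <- function(image, seed_polygon = NULL, threshold = "otsu",
                                min_area_frac = 0.01, closing_radius = 3L) {
  berry <- detect_berry_mask(image, min_area_frac, closing_radius)
  lt_mask <- segment_living_tissue(image, berry, threshold)
  result <- compute_vitality(lt_mask, berry, seed_polygon)
  list(result = result, berry = berry, lt_mask = lt_mask)
}

#' Export vitality masks and a result row
#'
#' Writes berry, LT and BCD masks as images plus one CSV row. PNG is the
#' default (binary masks survive the round trip losslessly); JPG is also
#' supported for compatibility with legacy archives.
#'
#' @param result a `vitality_result`.
#' @param berry a `berry_mask`.
#' @param lt_mask logical LT matrix.
#' @param dir output directory (created if missing).
#' @param berry_id identifier used in file names.
#' @param format `"png"` (default) or `"jpg"`.
#' @return invisibly, named character vector of written paths.
#' @export
export_masks <- function(result, berry, lt_mask, dir, berry_id = "berry",
                         format = c("png", "jpg")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bcd_mask <- berry$mask & !lt_mask
  paths <- c(
    berry = file.path(dir, sprintf("%s_berry.%s", berry_id, format)),
    lt = file.path(dir, sprintf("%s_lt.%s", berry_id, format)),
    bcd = file.path(dir, sprintf("%s_bcd.%s", berry_id, format)),
    csv = file.path(dir, sprintf("%s_vitality.csv", berry_id))
  )
  write_rgb_image(berry$mask * 1, paths[["berry"]])
  write_rgb_image(lt_mask * 1, paths[["lt"]])
  write_rgb_image(bcd_mask * 1, paths[["bcd"]])
  utils::write.csv(
    data.frame(
      berry_id = berry_id,
      lt_percent = result$lt_percent,
      bcd_percent = result$bcd_percent,
      berry_area_px = result$berry_area_px,
      seed_area_px = result$seed_area_px,
      lt_area_px = result$lt_area_px
    ),
    paths[["csv"]], row.names = FALSE
  )
  invisible(paths)
}

#' Batch vitality analysis over a manifest
#'
#' @param manifest data.frame with columns `berry_id`, `path`, optionally
#'   `seed_path` (CSV of `row, col` polygon vertices; empty/NA = no seed).
#' @param ... passed to [analyze_berry_image()].
#' @return tibble with one row per berry.
#' @export
analyze_berry_manifest <- function(manifest, ...) {
  stopifnot(all(c("berry_id", "path") %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_rgb_image(manifest$path[i])
    seed <- NULL
    if ("seed_path" %in% names(manifest) &&
        !is.na(manifest$seed_path[i]) && nzchar(manifest$seed_path[i])) {
      seed <- as.matrix(utils::read.csv(manifest$seed_path[i]))
    }
    a <- analyze_berry_image(img, seed_polygon = seed, ...)
    tibble::tibble(
      berry_id = manifest$berry_id[i],
      lt_percent = a$result$lt_percent,
      bcd_percent = a$result$bcd_percent,
      berry_area_px = a$result$berry_area_px,
      seed_area_px = a$result$seed_area_px,
      lt_area_px = a$result$lt_area_px
    )
  })
  do.call(rbind, rows)
}
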
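#' Canopy architecture from upward-looking cover photographs
#'
#' Gap-fraction analysis of an upward-looking RGB photograph of a grapevine
#' canopy against the sky. The sky is segmented on the blue channel (best
#' sky/leaf contrast in upward photos), connected sky components are split
#' into "large" between-crown gaps and small within-crown gaps, and six
#' canopy-architecture parameters are derived:
#'
#' * canopy cover `fc = 1 - gT` (total gap fraction `gT`),
#' * crown cover `ff = 1 - gL` (large-gap fraction `gL`),
#' * crown porosity `phi = 1 - fc/ff`,
#' * leaf area index `lai = -ff * log(phi) / k` (Beer-Lambert, extinction
#'   coefficient `k`, default 0.7),
#' * clumping index `omega = (1 - phi) * log(1 - fc) / (log(phi) * fc)`,
#' * effective leaf area index `lai_e = omega * lai`.
#'
#' @name canopy_architecture
NULL

#' Construct a canopy image object
#'
#' @param pixels numeric array `rows x cols x 3`, values in \[0, 1\].
#' @param source_id identifier for the photograph.
#' @param capture_side one of `"east"`, `"west"`, `"unknown"`.
#' @return object of class `canopy_image`.
#' @export
canopy_image <- function(pixels, source_id = "", capture_side = "unknown") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 64L || dim(pixels)[2] < 64L) {
    stop("canopy_image: image must be at least 64 x 64 pixels")
  }
  capture_side <- match.arg(capture_side, c("east", "west", "unknown"))
  structure(
    list(pixels = pixels, source_id = source_id, capture_side = capture_side),
    class = "canopy_image"
  )
}

#' Binarize a canopy photograph into sky and canopy
#'
#' Thresholds a scalar channel (default blue) so that sky pixels — brighter
#' than foliage in upward photographs — map to `TRUE` in the sky mask.
#' A degenerate image (a single intensity everywhere) yields a flagged
#' all-sky or all-canopy mask with a warning rather than an error.
#'
#' @param image a [canopy_image()] or a bare `rows x cols x 3` array.
#' @param method `"otsu"` (default), `"isodata"`, or `"fixed"`.
#' @param fixed_threshold intensity in \[0, 1\]; required iff `method = "fixed"`.
#' @param channel `"blue"`, `"red"`, `"green"`, or `"luminance"`.
#' @return object of class `gap_map`: list with `sky_mask` (logical matrix),
#'   `total_pixels`, `threshold`, `components` (`NULL` until
#'   [classify_gaps()]), and `warnings`.
#' @export
binarize_canopy <- function(image, method = c("otsu", "isodata", "fixed"),
                            fixed_threshold = NULL, channel = "blue") {
  method <- match.arg(method)
  px <- if (inherits(image, "canopy_image")) image$pixels else image
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  ch <- switch(channel,
    red = px[, , 1], green = px[, , 2], blue = px[, , 3],
    luminance = (px[, , 1] + px[, , 2] + px[, , 3]) / 3,
    stop("unknown channel: ", channel)
  )
  warnings <- character(0)
  if (method == "fixed") {
    if (is.null(fixed_threshold)) {
      stop("binarize_canopy: fixed_threshold required when method = 'fixed'")
    }
    thr <- fixed_threshold
  } else if (max(ch) - min(ch) < 1e-9) {
    warnings <- "degenerate image: single intensity, gap fraction forced to 0 or 1"
    warning(warnings)
    thr <- 0.5
  } else {
    thr <- switch(method, otsu = otsu_threshold(as.vector(ch)),
                  isodata = isodata_threshold(as.vector(ch)))
  }
  structure(
    list(
      sky_mask = ch > thr,
      total_pixels = length(ch),
      threshold = thr,
      method = method,
      large_gap_threshold = NA_real_,
      components = NULL,
      warnings = warnings
    ),
    class = "gap_map"
  )
}

#' Classify sky gaps into large (between-crown) and small (within-crown)
#'
#' Enumerates 8-connected components of the sky mask; a component is
#' labelled `"large"` iff its pixel count is at least
#' `large_gap_threshold * total_pixels`.
#'
#' @param gapmap a `gap_map` from [binarize_canopy()].
#' @param large_gap_threshold fraction of image area in (0, 1); default 0.01.
#' @return the `gap_map` with `components` (data.frame `component_id`,
#'   `pixel_count`, `label`) and `large_mask` filled in.
#' @export
classify_gaps <- function(gapmap, large_gap_threshold = 0.01) {
  stopifnot(inherits(gapmap, "gap_map"),
            large_gap_threshold > 0, large_gap_threshold < 1)
  lab <- label_components8(gapmap$sky_mask)
  n_lab <- max(lab)
  if (n_lab == 0L) {
    gapmap$components <- data.frame(component_id = integer(0),
                                    pixel_count = integer(0),
                                    label = character(0))
    gapmap$large_mask <- matrix(FALSE, nrow(lab), ncol(lab))
  } else {
    counts <- tabulate(lab[lab > 0], nbins = n_lab)
    is_large <- counts >= large_gap_threshold * gapmap$total_pixels
    gapmap$components <- data.frame(
      component_id = seq_len(n_lab),
      pixel_count = counts,
      label = ifelse(is_large, "large", "small")
    )
    large_ids <- which(is_large)
    gapmap$large_mask <- matrix(lab %in% large_ids, nrow(lab), ncol(lab))
  }
  gapmap$large_gap_threshold <- large_gap_threshold
  gapmap
}

#' Crown porosity from canopy and crown cover
#'
#' `phi = 1 - fc/ff`, clamped to `[1e-6, 1 - 1e-6]` before any logarithm.
#' @param fc canopy cover fraction.
#' @param ff crown cover fraction.
#' @return crown porosity fraction.
#' @export
crown_porosity <- function(fc, ff) {
  phi <- ifelse(ff > 0, 1 - fc / ff, 0)
  clamp(phi, 1e-6, 1 - 1e-6)
}

#' Leaf area index from crown cover and porosity (Beer-Lambert)
#'
#' `lai = -ff * log(phi) / k` with extinction coefficient `k`.
#' @param ff crown cover fraction.
#' @param phi crown porosity fraction in (0, 1).
#' @param k extinction coefficient (default 0.7).
#' @return leaf area index (m2 leaf per m2 ground).
#' @export
lai_from_cover <- function(ff, phi, k = 0.7) {
  phi <- clamp(phi, 1e-6, 1 - 1e-6)
  -ff * log(phi) / k
}

#' Foliage clumping index
#'
#' `omega = (1 - phi) * log(1 - fc) / (log(phi) * fc)` for `0 < fc < 1`;
#' by limit convention `omega = 1` when `fc` is 0 or 1.
#' @param fc canopy cover fraction.
#' @param phi crown porosity fraction.
#' @return clumping index.
#' @export
clumping_index <- function(fc, phi) {
  phi <- clamp(phi, 1e-6, 1 - 1e-6)
  ifelse(fc > 0 & fc < 1,
         (1 - phi) * log(1 - fc) / (log(phi) * fc),
         1)
}

#' Canopy metrics from cover fractions
#'
#' The equation engine shared by the image pipeline and by direct
#' recomputation from published cover fractions. Either supply `phi`
#' (e.g. a printed group mean) or let it be derived as `1 - fc/ff`.
#'
#' @param fc canopy cover fraction.
#' @param ff crown cover fraction.
#' @param phi optional crown porosity; derived from `fc`, `ff` when `NULL`.
#' @param k extinction coefficient.
#' @return a [tibble::tibble()] row with `fc, ff, phi, lai, omega, lai_e, k`.
#' @export
canopy_metrics_from_cover <- function(fc, ff, phi = NULL, k = 0.7) {
  if (is.null(phi)) phi <- crown_porosity(fc, ff)
  phi <- clamp(phi, 1e-6, 1 - 1e-6)
  lai <- lai_from_cover(ff, phi, k)
  omega <- clumping_index(fc, phi)
  tibble::tibble(fc = fc, ff = ff, phi = phi, lai = lai,
                 omega = omega, lai_e = omega * lai, k = k)
}

#' Canopy metrics from a classified gap map
#'
#' @param gapmap a `gap_map` with labelled components (see [classify_gaps()]).
#' @param k extinction coefficient (default 0.7).
#' @return object of class `canopy_metrics`: tibble row with
#'   `fc, ff, phi, lai, omega, lai_e, k, warnings`.
#' @export
compute_metrics <- function(gapmap, k = 0.7) {
  stopifnot(inherits(gapmap, "gap_map"), !is.null(gapmap$components),
            gapmap$total_pixels > 0)
  warnings <- gapmap$warnings
  n_sky <- sum(gapmap$sky_mask)
  n_large <- sum(gapmap$components$pixel_count[gapmap$components$label == "large"])
  gT <- n_sky / gapmap$total_pixels
  gL <- n_large / gapmap$total_pixels
  fc <- 1 - gT
  ff <- 1 - gL
  if (ff <= 0) {
    warnings <- c(warnings, "image entirely large gap: fc = ff = 0, lai = 0")
    out <- tibble::tibble(fc = 0, ff = 0, phi = 1 - 1e-6, lai = 0,
                          omega = 1, lai_e = 0, k = k)
    out$warnings <- list(warnings)
    class(out) <- c("canopy_metrics", class(out))
    return(out)
  }
  phi_raw <- 1 - fc / ff
  phi <- clamp(phi_raw, 1e-6, 1 - 1e-6)
  if (phi != phi_raw) {
    warnings <- c(warnings, sprintf("crown porosity clamped from %.3g", phi_raw))
  }
  out <- canopy_metrics_from_cover(fc, ff, phi = phi, k = k)
  out$warnings <- list(warnings)
  class(out) <- c("canopy_metrics", class(out))
  out
}

#' Analyze one canopy photograph end to end
#'
#' Binarize, classify gaps, compute metrics; intermediate gap fractions are
#' kept for audit in the `gap_fractions` attribute.
#'
#' @param image a [canopy_image()] or `rows x cols x 3` array.
#' @param k extinction coefficient.
#' @param method binarization method (see [binarize_canopy()]).
#' @param large_gap_threshold large-gap area fraction (see [classify_gaps()]).
#' @param fixed_threshold passed through when `method = "fixed"`.
#' @return `canopy_metrics` tibble row.
#' @export
analyze_canopy_image <- function(image, k = 0.7, method = "otsu",
                                 large_gap_threshold = 0.01,
                                 fixed_threshold = NULL) {
  gm <- binarize_canopy(image, method = method, fixed_threshold = fixed_threshold)
  gm <- classify_gaps(gm, large_gap_threshold = large_gap_threshold)
  metrics <- compute_metrics(gm, k = k)
  attr(metrics, "gap_fractions") <- c(
    total = sum(gm$sky_mask) / gm$total_pixels,
    large = sum(gm$components$pixel_count[gm$components$label == "large"]) /
      gm$total_pixels
  )
  metrics
}

#' Batch canopy analysis over a manifest
#'
#' One row of metrics per image, plus per-plant means over the (typically
#' two, east/west) images of each plant.
#'
#' @param manifest data.frame with columns `source_id`, `path`, `plant_id`,
#'   `side` (and optionally `date`).
#' @param ... passed to [analyze_canopy_image()].
#' @return list with `per_image` and `per_plant` tibbles.
#' @export
analyze_canopy_manifest <- function(manifest, ...) {
  stopifnot(all(c("source_id", "path", "plant_id") %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_rgb_image(manifest$path[i])
    m <- analyze_canopy_image(img, ...)
    m$source_id <- manifest$source_id[i]
    m$plant_id <- manifest$plant_id[i]
    m$warnings <- vapply(m$warnings, paste, character(1), collapse = "; ")
    m
  })
  per_image <- do.call(rbind, rows)
  num_cols <- c("fc", "ff", "phi", "lai", "omega", "lai_e")
  per_plant <- do.call(rbind, lapply(split(per_image, per_image$plant_id), function(d) {
    out <- as.data.frame(lapply(d[num_cols], mean))
    out$k <- d$k[1]
    out$plant_id <- d$plant_id[1]
    out$n_images <- nrow(d)
    out
  }))
  list(per_image = per_image, per_plant = tibble::as_tibble(per_plant))
}
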
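#' Seeded synthetic-data generators with known ground truth
#'
#' Every input kind the pipeline consumes can be generated with its latent
#' truth recorded: FDA-stained berry images with a known living-tissue
#' fraction, upward canopy scenes with known crown cover and porosity, NIR
#' spectra whose 1620 nm band tracks berry cell death, and a vineyard
#' feature table where canopy parameters map smoothly (plus noise) onto
#' vitality and sensory targets. All generators are pure functions of their
#' seed.
#'
#' @name synthetic_data
NULL

ellipse_mask <- function(nrow, ncol, center, semi_axes) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  c <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  ((r - center[1]) / semi_axes[1])^2 + ((c - center[2]) / semi_axes[2])^2 <= 1
}

ellipse_polygon <- function(center, semi_axes, n_vertices = 48L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1] + semi_axes[1] * sin(th), center[2] + semi_axes[2] * cos(th))
}

smooth_field <- function(nrow, ncol, sigma) {
  f <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  as.matrix(EBImage::gblur(EBImage::Image(f), sigma = sigma))
}

#' Write a generator's ground truth to JSON
#' @param truth ground-truth list from a generator.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  truth <- truth[!vapply(truth, is.matrix, logical(1))]  # drop pixel masks
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Generate a synthetic FDA-stained berry image
#'
#' Dark background, elliptical berry whose interior is partitioned by a
#' smoothed random field into fluorescent-green living tissue and dull-brown
#' dead tissue; the living pixel count is adjusted to hit `lt_fraction`
#' exactly (up to rounding of one pixel). Optionally a pale seed ellipse is
#' painted over the interior; Gaussian pixel noise is added last.
#'
#' @param lt_fraction target living-tissue fraction of the interior in \[0, 1\].
#' @param with_seed paint a seed ellipse at the berry centre?
#' @param size image side length in pixels (default 192).
#' @param noise_sd Gaussian pixel noise (default 0.02).
#' @param rng_seed integer seed.
#' @return list with `image` (`size x size x 3` array) and `truth`
#'   (realized fractions, per-pixel class matrix, seed polygon, seed).
#' @export
make_berry_image <- function(lt_fraction, with_seed = FALSE, size = 192L,
                             noise_sd = 0.02, rng_seed = 1L) {
  stopifnot(lt_fraction >= 0, lt_fraction <= 1)
  with_seed(rng_seed, {
    center <- c(size / 2, size / 2)
    axes <- c(0.40, 0.33) * size
    berry <- ellipse_mask(size, size, center, axes)
    n_int <- sum(berry)
    field <- smooth_field(size, size, sigma = size / 16)
    k <- round(lt_fraction * n_int)
    classes <- matrix("bg", size, size)
    classes[berry] <- "dead"
    if (k > 0) {
      interior_idx <- which(berry)
      lt_idx <- interior_idx[order(field[berry], decreasing = TRUE)[seq_len(k)]]
      classes[lt_idx] <- "lt"
    }
    seed_polygon <- NULL
    if (with_seed) {
      seed_axes <- c(0.12, 0.07) * size
      seed_polygon <- ellipse_polygon(center, seed_axes)
      seed_mask <- ellipse_mask(size, size, center, seed_axes) & berry
      classes[seed_mask] <- "seed"
    }
    cols <- list(
      bg = c(0.04, 0.04, 0.05),
      lt = c(0.25, 0.85, 0.22),
      dead = c(0.45, 0.34, 0.22),
      seed = c(0.75, 0.70, 0.45)
    )
    img <- array(0, c(size, size, 3))
    for (cl in names(cols)) {
      sel <- classes == cl
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- cols[[cl]][ch]
        img[, , ch] <- plane
      }
    }
    img <- clamp(img + stats::rnorm(length(img), 0, noise_sd), 0, 1)
    n_seed <- sum(classes == "seed")
    n_lt <- sum(classes == "lt")
    truth <- list(
      lt_fraction_target = lt_fraction,
      lt_fraction_interior = k / n_int,           # pre-seed partition
      lt_fraction_effective = if (n_int - n_seed > 0) {
        n_lt / (n_int - n_seed)                   # after seed exclusion
      } else NA_real_,
      interior_px = n_int, lt_px = n_lt, seed_px = n_seed,
      classes = classes,
      seed_polygon = seed_polygon,
      noise_sd = noise_sd, rng_seed = rng_seed
    )
    list(image = img, truth = truth)
  })
}

#' Generate a synthetic upward canopy scene
#'
#' White sky with `n_large_gaps` full-height between-crown gap strips whose
#' pixel count realizes `1 - ff_true` exactly, and within-crown sky speckle
#' (drawn away from crown borders so it never merges with the large gaps)
#' realizing porosity `phi_true` exactly. The implied canopy cover is
#' `fc = ff * (1 - phi)` by construction.
#'
#' @param ff_true crown cover fraction in (0, 1\].
#' @param phi_true crown porosity fraction in \[0, 1).
#' @param n_large_gaps number of between-crown gap strips (default 2).
#' @param size image side length in pixels (default 256).
#' @param noise_sd Gaussian pixel noise (default 0.01).
#' @param rng_seed integer seed.
#' @return list with `image` and `truth` (realized `ff`, `phi`, `fc`,
#'   sky/crown masks, seed).
#' @export
make_canopy_scene <- function(ff_true, phi_true, n_large_gaps = 2L,
                              size = 256L, noise_sd = 0.01, rng_seed = 1L) {
  stopifnot(ff_true > 0, ff_true <= 1, phi_true >= 0, phi_true < 1)
  with_seed(rng_seed, {
    n_px <- size * size
    gap_px <- round((1 - ff_true) * n_px)
    gap_mask <- matrix(FALSE, size, size)
    if (gap_px > 0) {
      n_gaps <- max(1L, n_large_gaps)
      total_cols <- gap_px %/% size
      rem <- gap_px %% size
      if (total_cols < n_gaps) {
        stop("infeasible scene: gap area too small for ", n_gaps, " gap strips")
      }
      widths <- rep(total_cols %/% n_gaps, n_gaps)
      extra <- total_cols %% n_gaps
      if (extra > 0) widths[seq_len(extra)] <- widths[seq_len(extra)] + 1L
      sector <- size %/% n_gaps
      if (any(widths + 2L >= sector)) {
        stop("infeasible scene: gap strips would touch; reduce gap area or count")
      }
      for (g in seq_len(n_gaps)) {
        start <- (g - 1L) * sector + 2L
        gap_mask[, start:(start + widths[g] - 1L)] <- TRUE
        if (g == 1L && rem > 0) {
          gap_mask[seq_len(rem), start + widths[g]] <- TRUE
        }
      }
    }
    crown <- !gap_mask
    n_crown <- sum(crown)
    speckle_px <- round(phi_true * n_crown)
    speckle <- matrix(FALSE, size, size)
    if (speckle_px > 0) {
      # keep speckle >= 2 px (Chebyshev) from any non-crown pixel so it can
      # never 8-connect with a between-crown gap
      zone <- as.matrix(EBImage::erode(crown * 1,
                                       EBImage::makeBrush(5L, "box"))) > 0.5
      if (sum(zone) < speckle_px) {
        stop("infeasible scene: porosity too high for the crown interior")
      }
      field <- smooth_field(size, size, sigma = 1)
      zone_idx <- which(zone)
      pick <- zone_idx[order(field[zone], decreasing = TRUE)[seq_len(speckle_px)]]
      speckle[pick] <- TRUE
    }
    sky <- gap_mask | speckle
    img <- array(0, c(size, size, 3))
    sky_col <- c(0.93, 0.95, 0.97)
    crown_col <- c(0.13, 0.33, 0.10)
    for (ch in 1:3) {
      plane <- matrix(crown_col[ch], size, size)
      plane[sky] <- sky_col[ch]
      img[, , ch] <- plane
    }
    img <- clamp(img + stats::rnorm(length(img), 0, noise_sd), 0, 1)
    truth <- list(
      ff = 1 - gap_px / n_px,
      phi = if (n_crown > 0) speckle_px / n_crown else 0,
      fc = 1 - (gap_px + speckle_px) / n_px,
      n_large_gaps = if (gap_px > 0) max(1L, n_large_gaps) else 0L,
      sky_mask = sky, large_gap_mask = gap_mask,
      noise_sd = noise_sd, rng_seed = rng_seed
    )
    list(image = img, truth = truth)
  })
}

#' Generate a synthetic NIR berry dataset
#'
#' Three replicate absorbance spectra per berry on the 1596-2396 nm
#' instrument grid (8 nm step): a smooth baseline, fixed Gaussian overtone
#' bands, and one band centred at 1620 nm (the hydrogen-peroxide overtone
#' region associated with cell death) whose amplitude is affine in the
#' berry's BCD truth, plus iid Gaussian noise.
#'
#' @param n_berries number of berries (>= 10).
#' @param bcd_truth optional numeric vector of per-berry BCD percentages;
#'   drawn uniformly in \[5, 95\] when `NULL`.
#' @param noise_sigma absorbance noise SD (default 0.004 AU).
#' @param rng_seed integer seed.
#' @return list with `spectra` (a [spectra_set()], 3 rows per berry) and
#'   `truth` (`bcd`, `lt`, band parameters, seed).
#' @export
make_nir_dataset <- function(n_berries = 432L, bcd_truth = NULL,
                             noise_sigma = 0.004, rng_seed = 1L) {
  stopifnot(n_berries >= 10L)
  with_seed(rng_seed, {
    wl <- seq(1596, 2396, by = 8)
    if (is.null(bcd_truth)) bcd_truth <- stats::runif(n_berries, 5, 95)
    stopifnot(length(bcd_truth) == n_berries)
    gauss <- function(center, width, amp) amp * exp(-0.5 * ((wl - center) / width)^2)
    baseline <- 0.35 + 1.5e-4 * (wl - 1596) + 0.05 * sin((wl - 1596) / 180)
    fixed_bands <- gauss(1730, 28, 0.12) + gauss(1940, 42, 0.22) +
      gauss(2100, 38, 0.10) + gauss(2270, 33, 0.15)
    death_center <- 1620; death_width <- 24
    amp0 <- 0.02; amp_slope <- 0.10
    ids <- rep(sprintf("b%03d", seq_len(n_berries)), each = 3L)
    reps <- rep(1:3, times = n_berries)
    A <- matrix(0, n_berries * 3L, length(wl))
    for (i in seq_len(n_berries)) {
      clean <- baseline + fixed_bands +
        gauss(death_center, death_width, amp0 + amp_slope * bcd_truth[i] / 100)
      for (r in 1:3) {
        A[(i - 1L) * 3L + r, ] <- clean +
          stats::rnorm(length(wl), 0, noise_sigma)
      }
    }
    truth <- list(bcd = bcd_truth, lt = 100 - bcd_truth,
                  death_band = list(center = death_center, width = death_width,
                                    amp0 = amp0, amp_slope = amp_slope),
                  noise_sigma = noise_sigma, rng_seed = rng_seed)
    list(spectra = spectra_set(wl, A, ids, reps), truth = truth)
  })
}

sensory_labels <- list(
  chardonnay = c("Clarity", "Color", "AFloral", "ACitrus", "ASpicy", "AOak",
                 "ASmoke", "ASweet", "ACut Hay", "OQuality"),
  shiraz = c("Clarity", "Color", "AFloral", "ARedFruits", "ABlackFruits",
             "ASweet", "APepper", "AOak", "AMushrooms", "OQuality")
)

#' Generate a synthetic vineyard feature table
#'
#' Canopy-architecture features are drawn in the regime of field-measured
#' grapevine group means (crown cover 0.55-0.90, porosity 0.13-0.31) and
#' satisfy the cover-photography identities exactly
#' (`fc = ff * (1 - phi)`, `lai = -ff * log(phi) / 0.7`,
#' `lai_e = omega * lai`). Vitality targets (LT, DT = 100 - LT) and ten
#' sensory descriptor intensities (0-15 cm scale, named as on the tasting
#' questionnaire) come from fixed bounded smooth teacher maps of the canopy
#' features, plus Gaussian noise — so 3-10-neuron networks can realize them.
#'
#' @param n_samples number of rows (>= 50).
#' @param cultivar `"shiraz"` or `"chardonnay"` (sets descriptor names).
#' @param noise_sigma_vitality SD of the LT noise in percentage points
#'   (default 1; calibrated so a 432-sample canopy-to-vitality model sits in
#'   the R ~ 0.98 accuracy regime).
#' @param noise_sigma_sensory SD of the sensory noise in cm (default 0.2).
#' @param rng_seed integer seed.
#' @return list with `data` (tibble: `sample_id`, `cultivar`, six canopy
#'   features, `LT`, `DT`, ten descriptor columns) and `truth` (noise-free
#'   targets, noise SDs, seed).
#' @export
make_vineyard_dataset <- function(n_samples = 432L,
                                  cultivar = c("shiraz", "chardonnay"),
                                  noise_sigma_vitality = 1,
                                  noise_sigma_sensory = 0.2,
                                  rng_seed = 1L) {
  cultivar <- match.arg(cultivar)
  stopifnot(n_samples >= 50L)
  with_seed(rng_seed, {
    ff <- stats::runif(n_samples, 0.55, 0.90)
    phi <- stats::runif(n_samples, 0.13, 0.31)
    fc <- ff * (1 - phi)
    lai <- lai_from_cover(ff, phi, k = 0.7)
    omega <- clumping_index(fc, phi)
    lai_e <- omega * lai
    lt_clean <- 55 + 18 * tanh(1.5 * (lai - 1.7)) +
      10 * tanh(8 * (phi - 0.22)) - 6 * tanh(10 * (omega - 0.78))
    lt <- clamp(lt_clean + stats::rnorm(n_samples, 0, noise_sigma_vitality),
                0, 100)
    labels <- sensory_labels[[cultivar]]
    i <- seq_along(labels)
    coef_a <- 0.9 * cos(i)
    coef_b <- 5.0 * sin(1.3 * i)
    coef_c <- 4.0 * cos(2.1 * i)
    mid <- 5 + 4 * (sin(0.7 * i) + 1) / 2
    amp <- 1.8 + (i %% 3) * 0.5
    sensory_clean <- sapply(i, function(d) {
      mid[d] + amp[d] * tanh(coef_a[d] * (lai - 1.7) + coef_b[d] * (phi - 0.22) +
                               coef_c[d] * (omega - 0.78))
    })
    sensory <- clamp(
      sensory_clean + stats::rnorm(length(sensory_clean), 0, noise_sigma_sensory),
      0, 15
    )
    colnames(sensory) <- labels
    data <- tibble::tibble(
      sample_id = sprintf("v%03d", seq_len(n_samples)),
      cultivar = cultivar,
      lai = lai, lai_e = lai_e, fc = fc, ff = ff, phi = phi, omega = omega,
      LT = lt, DT = 100 - lt
    )
    data <- cbind(data, tibble::as_tibble(sensory))
    truth <- list(
      lt_clean = lt_clean, sensory_clean = sensory_clean,
      teacher = list(a = coef_a, b = coef_b, c = coef_c, mid = mid, amp = amp),
      noise_sigma_vitality = noise_sigma_vitality,
      noise_sigma_sensory = noise_sigma_sensory,
      cultivar = cultivar, rng_seed = rng_seed
    )
    list(data = tibble::as_tibble(data), truth = truth)
  })
}

#' Generate data from a random teacher network
#'
#' Draws a teacher `ann_network` with the given layer sizes and returns
#' noisy samples from it — the standard teacher-student recovery setup for
#' testing the trainers.
#'
#' @param n_samples rows to draw.
#' @param n_inputs,n_hidden,n_outputs teacher layer sizes.
#' @param noise_sd additive output noise (default 0.05).
#' @param rng_seed integer seed.
#' @return list with `X`, `Y`, `teacher` (`ann_network`), `noise_sd`.
#' @export
make_teacher_dataset <- function(n_samples, n_inputs = 6L, n_hidden = 10L,
                                 n_outputs = 2L, noise_sd = 0.05,
                                 rng_seed = 1L) {
  with_seed(rng_seed, {
    X <- matrix(stats::runif(n_samples * n_inputs, -1, 1), n_samples)
    W1 <- matrix(stats::rnorm(n_hidden * n_inputs, 0, 1.2), n_hidden)
    b1 <- stats::rnorm(n_hidden, 0, 0.5)
    W2 <- matrix(stats::rnorm(n_outputs * n_hidden, 0, 1), n_outputs)
    b2 <- stats::rnorm(n_outputs, 0, 0.2)
    ident <- list(min = rep(-1, n_inputs), range = rep(2, n_inputs))
    ident_out <- list(min = rep(-1, n_outputs), range = rep(2, n_outputs))
    teacher <- structure(
      list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
           input_scaler = ident, target_scaler = ident_out,
           config = network_config(n_inputs, n_hidden, n_outputs)),
      class = "ann_network"
    )
    Y <- predict(teacher, X) + stats::rnorm(n_samples * n_outputs, 0, noise_sd)
    list(X = X, Y = Y, teacher = teacher, noise_sd = noise_sd,
         rng_seed = rng_seed)
  })
}
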
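# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
# Keeps every generator and trainer a pure function of its seed argument.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance over a 256-bin histogram of `v`
#' (assumed in `[0, 1]`). Returns a cut value; foreground is `v > t`.
#' @param v numeric vector in \[0, 1\].
#' @param n_bins histogram resolution.
#' @return scalar threshold.
#' @keywords internal
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsu_threshold: no finite values")
  if (max(v) - min(v) < 1e-12) return(v[1])
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- tabulate(findInterval(clamp(v, 0, 1), breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, 0)
  # upper edge of the argmax bin, so values inside that bin stay background
  breaks[which.max(bcv) + 1L]
}

# Isodata (intermeans) threshold: iterate t <- mean of class means.
isodata_threshold <- function(v, tol = 1e-6, max_iter = 200L) {
  v <- v[is.finite(v)]
  if (max(v) - min(v) < 1e-12) return(v[1])
  t0 <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (length(lo) == 0L || length(hi) == 0L) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}

#' Label connected components with 8-connectivity
#'
#' Thin extension of [EBImage::bwlabel()] (4-connected) that merges labels
#' touching diagonally, so diagonal speckle joins a single component.
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background).
#' @keywords internal
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n_lab <- max(lab)
  if (n_lab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour label pairs (down-right and down-left shifts)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  # union-find over label ids
  parent <- seq_len(n_lab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n_lab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Rasterize a simple polygon onto a pixel grid
#'
#' Even-odd ray casting at pixel centres. Vertices are given in pixel
#' coordinates `(row, col)`; the polygon is closed implicitly.
#' @param polygon two-column matrix (row, col) of vertices.
#' @param nrow,ncol raster dimensions.
#' @return logical matrix, `TRUE` inside the polygon.
#' @keywords internal
polygon_mask <- function(polygon, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  if (is.null(polygon) || NROW(polygon) < 3L) return(out)
  py <- polygon[, 1]; px <- polygon[, 2]
  r0 <- max(1L, floor(min(py))); r1 <- min(nrow, ceiling(max(py)))
  c0 <- max(1L, floor(min(px))); c1 <- min(ncol, ceiling(max(px)))
  if (r0 > r1 || c0 > c1) return(out)
  rows <- r0:r1; cols <- c0:c1
  xg <- matrix(rep(cols, each = length(rows)), length(rows))
  yg <- matrix(rep(rows, times = length(cols)), length(rows))
  inside <- matrix(FALSE, length(rows), length(cols))
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > yg) != (py[j] > yg)) &
      (xg < (px[j] - px[i]) * (yg - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  out[rows, cols] <- inside
  out
}

#' Read an RGB image from PNG or JPEG
#'
#' @param path file path ending in .png, .jpg or .jpeg.
#' @return numeric array `rows x cols x 3` with values in \[0, 1\].
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Write an RGB or grayscale image
#' @param img matrix or rows x cols x 3 array in \[0, 1\].
#' @param path output path (.png or .jpg).
#' @param quality JPEG quality in \[0, 1\].
#' @export
write_rgb_image <- function(img, path, quality = 0.92) {
  ext <- tolower(tools::file_ext(path))
  img <- clamp(img, 0, 1)
  switch(ext,
    png = png::writePNG(img, path),
    jpg = ,
    jpeg = jpeg::writeJPEG(img, path, quality = quality),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}
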
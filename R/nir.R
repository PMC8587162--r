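#' NIR spectral preprocessing
#'
#' Handheld-NIR absorbance spectra on a fixed 1596-2396 nm grid are turned
#' into a chemometric feature matrix: Savitzky-Golay first derivative on the
#' full instrument range, band selection to the modelling window
#' (1596-1919 nm by default), and pointwise averaging of the three replicate
#' readings per berry. The derivative is computed before the band is sliced
#' so filter edge transients stay outside the modelling window, and
#' replicates are averaged after the (linear) derivative.
#'
#' @name nir_chemometrics
NULL

#' Construct a spectra set
#'
#' @param wavelengths strictly increasing uniform grid in nm.
#' @param absorbance numeric matrix, one row per reading, `length(wavelengths)`
#'   columns (a single spectrum may be given as a vector).
#' @param berry_id character vector, one per reading.
#' @param replicate integer vector, one per reading.
#' @param units label for the value axis (default `"AU"`).
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, berry_id = NULL,
                        replicate = NULL, units = "AU") {
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1L)
  stopifnot(ncol(absorbance) == length(wavelengths))
  d <- diff(wavelengths)
  if (any(d <= 0)) stop("wavelength grid must be strictly increasing")
  if (length(d) > 1L && max(d) - min(d) > 1e-6) {
    stop("wavelength grid must be uniform (required by the derivative filter)")
  }
  n <- nrow(absorbance)
  if (is.null(berry_id)) berry_id <- sprintf("b%03d", seq_len(n))
  if (is.null(replicate)) replicate <- rep(1L, n)
  stopifnot(length(berry_id) == n, length(replicate) == n)
  structure(
    list(wavelengths = as.numeric(wavelengths), absorbance = absorbance,
         berry_id = as.character(berry_id), replicate = as.integer(replicate),
         units = units),
    class = "spectra_set"
  )
}

#' Savitzky-Golay first derivative of a spectra set
#'
#' Local least-squares polynomial fits over a sliding window
#' (via [signal::sgolayfilt()]); edge points come from the polynomial fitted
#' in the terminal window. Output units are `AU/nm` on the same grid.
#'
#' @param set a [spectra_set()].
#' @param window odd window length in points (default 9).
#' @param polyorder polynomial order, `1 <= polyorder < window` (default 2).
#' @return a `spectra_set` of derivatives.
#' @export
sg_first_derivative <- function(set, window = 9L, polyorder = 2L) {
  stopifnot(inherits(set, "spectra_set"))
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder < 1L || polyorder >= window) {
    stop("require window > polyorder >= 1")
  }
  p <- length(set$wavelengths)
  if (p < window) stop("spectrum shorter than the filter window")
  step <- set$wavelengths[2] - set$wavelengths[1]
  deriv <- t(apply(set$absorbance, 1, function(x) {
    signal::sgolayfilt(x, p = polyorder, n = window, m = 1L, ts = step)
  }))
  spectra_set(set$wavelengths, deriv, set$berry_id, set$replicate,
              units = paste0(set$units, "/nm"))
}

#' Select a wavelength band
#'
#' Inclusive slice `lo <= wavelength <= hi` of the grid.
#'
#' @param set a [spectra_set()].
#' @param lo,hi band limits in nm, `lo < hi`.
#' @return a `spectra_set` restricted to the band.
#' @export
select_band <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectra_set"))
  if (lo >= hi) stop("band limits inverted: require lo < hi")
  keep <- set$wavelengths >= lo & set$wavelengths <= hi
  if (!any(keep)) stop("empty band: no grid points in [lo, hi]")
  spectra_set(set$wavelengths[keep], set$absorbance[, keep, drop = FALSE],
              set$berry_id, set$replicate, units = set$units)
}

#' Average replicate readings per berry
#'
#' Pointwise mean of all readings sharing a `berry_id`; the replicate count
#' per berry is recorded in the `"n_replicates"` attribute.
#'
#' @param set a [spectra_set()].
#' @return a `spectra_set` with one spectrum per berry.
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  ids <- unique(set$berry_id)
  means <- t(vapply(ids, function(id) {
    colMeans(set$absorbance[set$berry_id == id, , drop = FALSE])
  }, numeric(length(set$wavelengths))))
  counts <- vapply(ids, function(id) sum(set$berry_id == id), integer(1))
  out <- spectra_set(set$wavelengths, means, ids, rep(1L, length(ids)),
                     units = set$units)
  attr(out, "n_replicates") <- counts
  out
}

#' NIR feature matrix for modelling
#'
#' Full preprocessing chain: derivative, band selection, replicate
#' averaging. Returns the feature matrix used as network inputs.
#'
#' @param set a raw-absorbance [spectra_set()].
#' @param window,polyorder Savitzky-Golay parameters.
#' @param band two-element numeric, modelling band in nm
#'   (default `c(1596, 1919)`).
#' @return numeric matrix (rows = berries, columns named by wavelength),
#'   with `rownames` = berry ids.
#' @export
nir_features <- function(set, window = 9L, polyorder = 2L,
                         band = c(1596, 1919)) {
  out <- sg_first_derivative(set, window, polyorder)
  out <- select_band(out, band[1], band[2])
  out <- average_replicates(out)
  X <- out$absorbance
  rownames(X) <- out$berry_id
  colnames(X) <- sprintf("d1_%g", out$wavelengths)
  X
}

#' Read spectra from a wide CSV
#'
#' Expects the de-facto handheld-NIR export dialect: first column
#' `berry_id`, optional `replicate` column, remaining column headers the
#' wavelengths in nm.
#'
#' @param path CSV file path.
#' @return a [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("berry_id" %in% names(df))
  rep_col <- if ("replicate" %in% names(df)) df$replicate else NULL
  wl_cols <- setdiff(names(df), c("berry_id", "replicate"))
  wl <- as.numeric(wl_cols)
  if (anyNA(wl)) stop("non-numeric wavelength headers in ", path)
  spectra_set(wl, as.matrix(df[, wl_cols]), df$berry_id, rep_col)
}

#' Write spectra to a wide CSV
#' @param set a [spectra_set()].
#' @param path output CSV path.
#' @export
write_spectra_csv <- function(set, path) {
  df <- data.frame(berry_id = set$berry_id, replicate = set$replicate,
                   check.names = FALSE)
  m <- as.data.frame(set$absorbance)
  names(m) <- as.character(set$wavelengths)
  utils::write.csv(cbind(df, m), path, row.names = FALSE)
  invisible(path)
}
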
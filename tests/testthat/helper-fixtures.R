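# Small fixture builders shared across test files.

# Uniform-color RGB array.
flat_rgb <- function(nrow, ncol, rgb = c(1, 1, 1)) {
  array(rep(rgb, each = nrow * ncol), c(nrow, ncol, 3))
}

# Paint a rectangle (rows r, cols c) in a given color.
paint_rect <- function(img, rows, cols, rgb) {
  for (ch in 1:3) img[rows, cols, ch] <- rgb[ch]
  img
}

# Independent brute-force gap-fraction oracle: plain pixel counting.
gap_fraction_oracle <- function(mask) sum(mask) / length(mask)

# Closed-form OLS slope/intercept oracle (normal equations, written out).
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  list(slope = b, intercept = mean(y) - b * mean(x),
       r = sxy / sqrt(sxx * sum((y - mean(y))^2)))
}
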
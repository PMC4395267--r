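# Separable FIR filtering with reflected boundaries.
#
# All image filtering in the package (anisotropic Gaussian smoothing, the
# Laplacian of Gaussian) runs through these helpers, which pad with reflected
# samples and delegate the inner loop to stats::filter (C-level convolution).
# Reflection avoids the spurious edge ridges that zero padding would create.

# Sampled Gaussian kernel, normalised to unit sum so DC gain is exactly 1.
gauss_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Second derivative of the (unit-sum) sampled Gaussian; re-centred to sum to
# zero so the response to a constant image is exactly zero.
gauss_d2_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)
}

# Map arbitrary (1-based) indices into [1, n] by symmetric reflection with the
# edge sample repeated; period 2n, so any pad width is valid even when the
# kernel is wider than the image.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, p - j)
}

# Convolve each column of `x` (i.e. along the row/time axis) with a symmetric
# odd-length kernel under reflected boundary handling.
conv_cols <- function(x, kern) {
  m <- nrow(x)
  r <- (length(kern) - 1L) %/% 2L
  if (r == 0L) return(x * kern)
  xp <- x[reflect_index(seq.int(1L - r, m + r), m), , drop = FALSE]
  out <- stats::filter(xp, kern, method = "convolution", sides = 2L)
  matrix(out[seq.int(r + 1L, r + m), ], nrow = m, ncol = ncol(x))
}

conv_rows <- function(x, kern) {
  t(conv_cols(t(x), kern))
}

# Smooth a numeric vector with a 1D Gaussian (reflected boundaries).
smooth_vector <- function(y, sigma) {
  if (sigma <= 0) return(y)
  drop(conv_cols(matrix(y, ncol = 1L), gauss_kernel(sigma)))
}

# Round half away from zero; platform-independent, unlike base round()'s
# round-half-to-even.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
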
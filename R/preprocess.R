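#' Gaussian smoothing of a kymograph
#'
#' Smooths the image with an anisotropic 2D Gaussian kernel to suppress random
#' intensity fluctuations before ridge detection. The kernel is wide along the
#' channel axis (`sigma_h`) and narrow along the time axis (`sigma_v`) because
#' DNA bands are broad in x but must stay temporally local. Boundaries are
#' handled by reflection.
#'
#' @param kymo A [kymograph] or numeric matrix.
#' @param sigma_h Horizontal (channel-axis) standard deviation in pixels.
#' @param sigma_v Vertical (time-axis) standard deviation in pixels.
#' @return A [kymograph] of the same dimensions.
#' @export
smooth_kymograph <- function(kymo, sigma_h = 10, sigma_v = 3) {
  if (sigma_h <= 0 || sigma_v <= 0) stop("smoothing sigmas must be positive")
  kymo <- as_kymograph(kymo)
  out <- conv_rows(kymo$intensity, gauss_kernel(sigma_h))
  out <- conv_cols(out, gauss_kernel(sigma_v))
  kymograph(out, pixel_size = kymo$pixel_size,
            frame_interval = kymo$frame_interval)
}

#' Laplacian response of a smoothed kymograph
#'
#' Applies an isotropic Laplacian-of-Gaussian filter and rescales the result
#' so that dark bands (intensity valleys) carry positive values in (0, 1] and
#' bright bands (ridges) carry negative values in [-1, 0). Positive entries
#' are divided by the largest positive response and negative entries by the
#' magnitude of the most negative response; an exactly constant input yields
#' an all-zero response.
#'
#' The LoG is computed separably as `I * (g'' x g) + I * (g x g'')` with a
#' sampled Gaussian `g` of standard deviation `sigma_log`, reflected
#' boundaries, and kernels re-centred so the response to a constant is exactly
#' zero.
#'
#' @param smoothed A smoothed [kymograph] (see [smooth_kymograph()]).
#' @param sigma_log LoG standard deviation in pixels.
#' @param norm Optional fixed normalisation `list(pos =, neg =)`: positive
#'   entries are divided by `pos` and negative entries by `neg` (both > 0),
#'   then clamped to \[-1, 1\]. Used during recursive alignment so that
#'   sub-region responses stay on the global contrast scale; the default
#'   (`NULL`) rescales by the response's own extremes.
#' @return Numeric matrix of the same size with values in \[-1, 1\].
#' @export
laplacian_response <- function(smoothed, sigma_log = 10, norm = NULL) {
  if (sigma_log <= 0) stop("sigma_log must be positive")
  img <- as_kymograph(smoothed)$intensity
  k <- laplacian_raw(img, sigma_log)
  # round-off guard: a constant image must give an exactly zero response, so
  # residue far below the image scale is flushed to zero before rescaling
  k[abs(k) < 1e-11 * (max(abs(img)) + 1)] <- 0
  rescale_response(k, norm)
}

# Unrescaled LoG: d2/dx2 along the channel axis plus d2/dy2 along time,
# computed separably; positive in dark bands, negative in bright bands.
laplacian_raw <- function(img, sigma_log) {
  g <- gauss_kernel(sigma_log)
  g2 <- gauss_d2_kernel(sigma_log)
  conv_cols(conv_rows(img, g2), g) + conv_cols(conv_rows(img, g), g2)
}

rescale_response <- function(k, norm = NULL) {
  pos <- k > 0
  neg <- k < 0
  if (is.null(norm)) {
    if (any(pos)) k[pos] <- k[pos] / max(k[pos])
    if (any(neg)) k[neg] <- k[neg] / abs(min(k[neg]))
  } else {
    stopifnot(norm$pos > 0, norm$neg > 0)
    k[pos] <- k[pos] / norm$pos
    k[neg] <- k[neg] / norm$neg
    k <- pmin(pmax(k, -1), 1)
  }
  k
}

#' Bright/dark cost images from a Laplacian response
#'
#' Splits the rescaled Laplacian response `K` into two non-negative cost
#' landscapes so that ridge and valley features are searched separately and a
#' single detected feature cannot be partly bright and partly dark:
#' `K_B = 1 + K` where `K < 0` (else 1) emphasises bright bands, and
#' `K_D = 1 - K` where `K > 0` (else 1) emphasises dark bands. In both, the
#' most pronounced feature locations approach 0 and all non-feature pixels sit
#' at the barrier value 1. This affine barrier mapping is one concrete choice
#' satisfying the required properties (non-negative everywhere, minima at the
#' strongest features, barriers at 1) and can be swapped out via `strategy`.
#'
#' @param k Laplacian response matrix with entries in \[-1, 1\].
#' @param strategy Function `(k) -> list(bright=, dark=)` replacing the default
#'   mapping, or `NULL` for the default.
#' @return List with elements `bright` and `dark`, matrices in \[0, 1\].
#' @export
cost_images <- function(k, strategy = NULL) {
  if (!is.matrix(k) || !is.numeric(k)) stop("`k` must be a numeric matrix")
  if (min(k) < -1 - 1e-9 || max(k) > 1 + 1e-9) {
    stop("Laplacian response entries must lie in [-1, 1]")
  }
  if (!is.null(strategy)) return(strategy(k))
  kb <- matrix(1, nrow(k), ncol(k))
  kd <- kb
  neg <- k < 0
  pos <- k > 0
  kb[neg] <- 1 + k[neg]
  kd[pos] <- 1 - k[pos]
  kb <- pmin(pmax(kb, 0), 1)
  kd <- pmin(pmax(kd, 0), 1)
  list(bright = kb, dark = kd)
}

#' Full preprocessing: smoothing, LoG, cost images
#'
#' Convenience wrapper running [smooth_kymograph()], [laplacian_response()]
#' and [cost_images()] in the documented order (the LoG is applied to the
#' already-smoothed image).
#'
#' @param kymo A [kymograph] or matrix.
#' @param sigma_h,sigma_v,sigma_log Filter scales in pixels.
#' @param norm Optional fixed rescaling passed to [laplacian_response()].
#' @return List with `smoothed`, `laplacian`, `bright`, `dark`.
#' @export
preprocess_kymograph <- function(kymo, sigma_h = 10, sigma_v = 3,
                                 sigma_log = 10, norm = NULL) {
  sm <- smooth_kymograph(kymo, sigma_h = sigma_h, sigma_v = sigma_v)
  k <- laplacian_response(sm, sigma_log = sigma_log, norm = norm)
  ci <- cost_images(k)
  list(smoothed = sm, laplacian = k, bright = ci$bright, dark = ci$dark)
}
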
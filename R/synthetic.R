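#' Synthetic barcode profile
#'
#' Builds a ground-truth 1D barcode: a constant baseline plus `n_features`
#' Gaussian bumps (bright bands) whose centres are rejection-sampled to be at
#' least `2 * feature_width_px` apart, with widths `feature_width_px / 2.355`
#' (FWHM convention) and amplitudes drawn uniformly from `amplitude_range`.
#' Band centres keep a guard margin of `margin` pixels (default two feature
#' widths) from the frame edges so that bands remain in the field of view
#' under typical thermal drift — a molecule leaving the frame is an anomalous
#' event outside the alignment model. Deterministic given `seed`.
#'
#' @param n Barcode width in pixels.
#' @param n_features Number of bands (0 gives a flat baseline).
#' @param feature_width_px Typical band FWHM in pixels.
#' @param margin Minimum distance of band centres from the frame edges, px.
#' @param amplitude_range Length-2 vector of positive band amplitudes.
#' @param baseline Background intensity level.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return Object of class `kymo_barcode`: list with `profile` (length-`n`
#'   vector), `centers`, `amplitudes`, and the generating parameters.
#' @export
generate_barcode <- function(n = 170L, n_features = 4L, feature_width_px = 10,
                             amplitude_range = c(50, 100), baseline = 100,
                             seed = 1L, margin = 2 * feature_width_px) {
  n <- as.integer(n); n_features <- as.integer(n_features)
  if (n < 1L) stop("`n` must be >= 1")
  if (n_features < 0L) stop("`n_features` must be >= 0")
  if (any(amplitude_range <= 0)) stop("amplitudes must be positive")
  if (n_features > 0L && n_features * feature_width_px >= n) {
    stop("barcode too narrow for the requested number of features")
  }
  withr::with_seed(seed, {
    centers <- numeric(0)
    amplitudes <- numeric(0)
    if (n_features > 0L) {
      if (n - 2 * margin < 1) stop("barcode too narrow for feature margins")
      ok <- FALSE
      for (try in seq_len(1000L)) {
        centers <- sort(stats::runif(n_features, 1 + margin, n - margin))
        if (n_features == 1L ||
            min(diff(centers)) >= 2 * feature_width_px) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place ", n_features,
             " features with spacing >= 2 * feature_width_px in width ", n)
      }
      amplitudes <- stats::runif(n_features, amplitude_range[1L],
                                 amplitude_range[2L])
    }
    x <- seq_len(n)
    sd <- feature_width_px / 2.355
    profile <- rep(baseline, n)
    for (i in seq_along(centers)) {
      profile <- profile + amplitudes[i] * exp(-(x - centers[i])^2 / (2 * sd^2))
    }
    structure(list(profile = profile, centers = centers,
                   amplitudes = amplitudes, baseline = baseline,
                   feature_width_px = feature_width_px, n = n, seed = seed),
              class = "kymo_barcode")
  })
}

#' Simulate a kymograph from a barcode
#'
#' Emulates the thermal dynamics that misalign real nanochannel kymographs:
#' each frame `t` samples the continuous barcode at warped coordinates
#' `phi_t(x) = x + c_t + d_t(x)`, where `c_t` is a cumulative random walk
#' (centre-of-mass diffusion, Normal(0, `com_step_sd`) increments per frame)
#' and `d_t(x)` is a smooth zero-mean local displacement field (white noise
#' smoothed to correlation length `stretch_corr_len`, scaled to standard
#' deviation `stretch_sd`) representing local conformational stretching.
#' Warps are kept strictly increasing (the field is shrunk if it ever folds
#' the coordinate over, and an error is raised if that fails). Barcode values
#' at fractional positions come from natural cubic-spline interpolation with
#' coordinates clamped to the barcode support, and i.i.d. Gaussian camera
#' noise of standard deviation `noise_sd` is added. Deterministic given
#' `seed`.
#'
#' @param barcode A `kymo_barcode` (or plain numeric profile vector).
#' @param m Number of time frames.
#' @param com_step_sd Centre-of-mass random-walk step, px/frame.
#' @param stretch_sd Local displacement field magnitude, px.
#' @param stretch_corr_len Correlation length of the field, px.
#' @param noise_sd Additive intensity noise (camera units).
#' @param seed Integer seed.
#' @param pixel_size,frame_interval Metadata for the resulting [kymograph].
#' @return List with `kymograph` and `truth`; `truth` holds the barcode, the
#'   `m x n` warp matrix `phi` (`phi[t, x]` = barcode coordinate sampled at
#'   pixel `x` in frame `t`), the per-frame offsets, and `centers`, an
#'   `m x n_features` matrix of true band-centre positions per frame.
#' @export
generate_kymograph <- function(barcode, m = 200L, com_step_sd = 0.5,
                               stretch_sd = 1, stretch_corr_len = 40,
                               noise_sd = 5, seed = 1L,
                               pixel_size = 0.16, frame_interval = 0.1) {
  if (!inherits(barcode, "kymo_barcode")) {
    barcode <- structure(list(profile = as.numeric(barcode), centers = numeric(0),
                              amplitudes = numeric(0),
                              baseline = stats::median(as.numeric(barcode)),
                              feature_width_px = 10,
                              n = length(barcode), seed = NA_integer_),
                         class = "kymo_barcode")
  }
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  if (com_step_sd < 0 || stretch_sd < 0 || noise_sd < 0) {
    stop("dynamics standard deviations must be >= 0")
  }
  n <- barcode$n
  x <- seq_len(n)
  spl <- stats::splinefun(x, barcode$profile, method = "natural")

  withr::with_seed(seed, {
    # the simulated crop follows the molecule's time-averaged position, as an
    # experimental crop does, so the COM walk is centred on its mean
    offsets <- cumsum(stats::rnorm(m, 0, com_step_sd))
    offsets <- offsets - mean(offsets)
    phi <- matrix(0, m, n)
    for (t in seq_len(m)) {
      d <- numeric(n)
      if (stretch_sd > 0) {
        d <- smooth_vector(stats::rnorm(n), stretch_corr_len)
        sdd <- stats::sd(d)
        if (sdd > 0) d <- (d - mean(d)) / sdd * stretch_sd
        # shrink the field until the warp is strictly increasing
        tries <- 0L
        while (any(diff(x + d) <= 0) && tries < 30L) {
          d <- d * 0.5
          tries <- tries + 1L
        }
        if (any(diff(x + d) <= 0)) {
          stop("could not build a monotone warp for frame ", t)
        }
      }
      phi[t, ] <- x + offsets[t] + d
    }
    img <- matrix(0, m, n)
    for (t in seq_len(m)) {
      img[t, ] <- spl(pmin(pmax(phi[t, ], 1), n))
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(m * n, 0, noise_sd), m, n)
    }
    img <- pmax(img, 0)

    centers <- matrix(NA_real_, m, length(barcode$centers))
    for (t in seq_len(m)) {
      if (length(barcode$centers)) {
        # band at barcode coordinate c appears at the pixel x solving
        # phi_t(x) = c; phi is strictly increasing so the inverse is unique
        centers[t, ] <- stats::approx(phi[t, ], x,
                                      xout = barcode$centers, rule = 2)$y
      }
    }

    list(kymograph = kymograph(img, pixel_size = pixel_size,
                               frame_interval = frame_interval),
         truth = structure(list(barcode = barcode, phi = phi,
                                offsets = offsets, centers = centers,
                                dynamics = list(m = m,
                                                com_step_sd = com_step_sd,
                                                stretch_sd = stretch_sd,
                                                stretch_corr_len = stretch_corr_len,
                                                noise_sd = noise_sd,
                                                seed = seed)),
                           class = "kymo_truth"))
  })
}

#' Alignment error against simulator ground truth
#'
#' Measures how well an alignment straightened a simulated kymograph:
#' \itemize{
#'   \item `center_rms`: per-band root-mean-square deviation of the aligned
#'     true band centres from constancy across frames (population sd of each
#'     tracked centre after replaying the alignment's warps on it), in px;
#'   \item `variance_reduction`: mean column-wise variance of the raw
#'     kymograph divided by that of the aligned one;
#'   \item `match_fraction`: fraction of true bands whose mean aligned centre
#'     lies within one feature width of some detected feature position.
#' }
#'
#' @param result A `kymo_alignment` from [align_kymograph()].
#' @param truth The `truth` component returned by [generate_kymograph()].
#' @return List with `center_rms` (per band), `mean_center_rms`,
#'   `variance_reduction` and `match_fraction`.
#' @export
alignment_error <- function(result, truth) {
  if (!inherits(result, "kymo_alignment")) stop("`result` must be a kymo_alignment")
  if (!inherits(truth, "kymo_truth")) stop("`truth` must be simulator ground truth")
  m <- nrow(result$aligned$intensity)
  if (m != nrow(truth$phi) ||
      ncol(result$aligned$intensity) != ncol(truth$phi)) {
    stop("alignment and truth dimensions do not match")
  }
  nb <- ncol(truth$centers)
  if (nb > 0L) {
    aligned_centers <- replay_warps(result, truth$centers)
    center_rms <- apply(aligned_centers, 2L, function(p) {
      sqrt(mean((p - mean(p))^2))
    })
    det_pos <- vapply(result$features, function(f) f$mean_position, numeric(1L))
    fw <- truth$barcode$feature_width_px
    mean_centers <- colMeans(aligned_centers)
    match_fraction <- if (length(det_pos)) {
      mean(vapply(mean_centers, function(p) any(abs(det_pos - p) <= fw),
                  logical(1L)))
    } else 0
  } else {
    center_rms <- numeric(0)
    match_fraction <- NA_real_
  }
  v_raw <- time_trace(result$raw)$mean_variance
  v_aligned <- time_trace(result$aligned)$mean_variance
  list(center_rms = center_rms,
       mean_center_rms = if (length(center_rms)) mean(center_rms) else NA_real_,
       variance_reduction = v_raw / v_aligned,
       match_fraction = match_fraction)
}
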
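#' Time trace and column-wise variance of a kymograph
#'
#' The time trace is the column-wise time average
#' `<I(x)> = (1/m) * sum_y I(x, y)` — the 1D consensus barcode an aligned
#' kymograph exists to produce. Residual noise is quantified by the
#' column-wise variance `sigma^2(x) = (1/m) * sum_y (I(x, y) - <I(x)>)^2`
#' (population convention, dividing by `m`), and summarised by its mean over
#' columns, `<sigma^2(x)>`.
#'
#' @param kymo A [kymograph] or numeric matrix.
#' @return An object of class `time_trace`: list with `mean_intensity`
#'   (length-`n` vector), `column_variance` (length-`n` non-negative vector)
#'   and `mean_variance` (scalar mean of `column_variance`).
#' @examples
#' tt <- time_trace(matrix(c(0, 2), nrow = 2))
#' tt$column_variance  # 1
#' @export
time_trace <- function(kymo) {
  mat <- as_kymograph(kymo)$intensity
  m <- nrow(mat)
  mu <- colMeans(mat)
  v <- colMeans(mat * mat) - mu * mu
  v <- pmax(v, 0)
  structure(list(mean_intensity = mu,
                 column_variance = v,
                 mean_variance = mean(v)),
            class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("time trace: %d columns, mean variance %.6g\n",
              length(x$mean_intensity), x$mean_variance))
  invisible(x)
}

#' Robust peak/valley intensity differences of a time trace
#'
#' Extracts the absolute intensity differences `|dI_k|` between neighbouring
#' peaks and valleys of the mean-intensity trace, the contrasts that enter the
#' information score. The trace is first smoothed with a 1D Gaussian
#' (`smoothing_sigma`, default 2 px; 0 disables smoothing). All interior
#' points where the direction of travel changes form the alternating
#' extremum sequence, extended to the trace endpoints; a trace with no
#' interior extrema yields an empty list. Adjacent extrema whose contrast
#' falls below `min_prominence` are then pruned pairwise (smallest contrast
#' first, endpoint extrema retained), so only differences that clear the
#' noise scale survive — the floor defaults to `0.5 * sqrt(sigma2 + chi)`
#' when computed via [barcode_information()].
#'
#' @param trace A `time_trace`, or a numeric vector of mean intensities.
#' @param smoothing_sigma Gaussian smoothing scale in pixels.
#' @param min_prominence Minimum |dI| an adjacent extremum pair must reach.
#' @return Numeric vector of `|dI_k|` values (possibly empty).
#' @export
extrema_differences <- function(trace, smoothing_sigma = 2,
                                min_prominence = 0) {
  y <- if (inherits(trace, "time_trace")) trace$mean_intensity
       else as.numeric(trace)
  n <- length(y)
  if (n < 3L) stop("trace must have at least 3 points")
  y <- smooth_vector(y, smoothing_sigma)

  # interior direction changes (plateaus inherit the previous direction)
  d <- sign(diff(y))
  run <- 0L
  turns <- integer(0)
  for (i in seq_along(d)) {
    if (d[i] == 0) next
    if (run != 0L && d[i] != run) turns <- c(turns, i)
    run <- d[i]
  }
  if (length(turns) == 0L) return(numeric(0))
  idx <- c(1L, turns, n)
  vals <- y[idx]

  # pairwise prominence pruning, keeping the alternation intact: repeatedly
  # remove the adjacent extremum pair with the smallest contrast; when that
  # pair touches an endpoint, keep the endpoint and merge the two same-type
  # extrema it leaves behind (retaining the more extreme one)
  repeat {
    if (length(vals) < 2L) break
    dv <- abs(diff(vals))
    j <- which.min(dv)
    if (dv[j] >= min_prominence) break
    nv <- length(vals)
    if (j == 1L && nv > 2L) {
      # vals[1] and vals[3] share a type: minima if vals[2] sits above them
      keepf <- if (vals[2L] >= vals[1L]) min else max
      vals <- c(keepf(vals[1L], vals[3L]), vals[-(1:3)])
    } else if (j == nv - 1L && nv > 2L) {
      keepf <- if (vals[nv - 1L] >= vals[nv]) min else max
      vals <- c(vals[seq_len(nv - 3L)], keepf(vals[nv - 2L], vals[nv]))
    } else {
      vals <- vals[-c(j, j + 1L)]
    }
  }
  if (length(vals) < 2L) return(numeric(0))
  abs(diff(vals))
}

#' Self-information score of a barcode
#'
#' Scores the information content of a time trace from its peak/valley
#' contrasts and the kymograph noise: each contrast contributes the negative
#' log of a Gaussian density in `log|dI_k|` whose variance is `log(sigma2 +
#' chi)`, i.e.
#' `IS = sum_k [ 0.5 * log(2*pi*log(sigma2 + chi)) +
#'               log(|dI_k|)^2 / (2 * log(sigma2 + chi)) ]`.
#' Information grows as contrasts between neighbouring peaks and valleys grow
#' (for `|dI| >= 1`) and shrinks as kymograph noise grows. The regulariser
#' `chi >= 1` keeps the score real at all noise levels; logarithms are
#' natural (the score is in nats) unless `base` is changed. A noiseless
#' kymograph with `chi = 1` makes the log-variance zero; the score is then
#' reported as `Inf` (a perfect, noise-free barcode). An empty contrast list
#' scores 0.
#'
#' @param delta_i Numeric vector of positive contrasts `|dI_k|`.
#' @param sigma2 Kymograph noise, the mean column-wise variance of the
#'   aligned kymograph; `>= 0`.
#' @param chi Regularisation, `>= 1`.
#' @param base Logarithm base (default `exp(1)`, nats).
#' @return The information score (scalar; `Inf` in the noiseless case).
#' @examples
#' information_score(exp(1), sigma2 = exp(1) - 1)  # 0.5*log(2*pi) + 0.5
#' @export
information_score <- function(delta_i, sigma2, chi = 1, base = exp(1)) {
  if (length(delta_i) == 0L) return(0)
  if (any(!is.finite(delta_i)) || any(delta_i <= 0)) {
    stop("all contrasts |dI_k| must be positive and finite")
  }
  if (!is.numeric(sigma2) || sigma2 < 0) stop("`sigma2` must be >= 0")
  if (!is.numeric(chi) || chi < 1) stop("`chi` must be >= 1")
  lg <- function(x) log(x, base = base)
  s <- lg(sigma2 + chi)
  if (s == 0) return(Inf)
  sum(0.5 * lg(2 * pi * s) + lg(delta_i)^2 / (2 * s))
}

#' Information score of an aligned kymograph
#'
#' End-to-end barcode scoring: computes the time trace, extracts robust
#' peak/valley contrasts (prominence floor `0.5 * sqrt(sigma2 + chi)` unless
#' overridden), and evaluates [information_score()] with `sigma2` taken as
#' the mean column-wise variance of the kymograph.
#'
#' @param kymo A [kymograph] or matrix (normally an aligned one).
#' @param chi Regularisation parameter, `>= 1`.
#' @param smoothing_sigma Trace smoothing in pixels (see
#'   [extrema_differences()]).
#' @param min_prominence Contrast floor; `NULL` uses the noise-scale default.
#' @return List with `score`, `delta_i`, `sigma2`, `n_extrema`, `trace` and
#'   the parameters used.
#' @export
barcode_information <- function(kymo, chi = 1, smoothing_sigma = 2,
                                min_prominence = NULL) {
  tt <- time_trace(kymo)
  sigma2 <- tt$mean_variance
  if (is.null(min_prominence)) min_prominence <- 0.5 * sqrt(sigma2 + chi)
  di <- extrema_differences(tt, smoothing_sigma = smoothing_sigma,
                            min_prominence = min_prominence)
  list(score = information_score(di, sigma2 = sigma2, chi = chi),
       delta_i = di,
       sigma2 = sigma2,
       n_extrema = if (length(di)) length(di) + 1L else 0L,
       trace = tt,
       parameters = list(chi = chi, smoothing_sigma = smoothing_sigma,
                         min_prominence = min_prominence))
}

#' Column-wise variance ratio of two alignments
#'
#' Harness for comparing two alignments of the same kymograph: the per-column
#' ratio of their column-wise variances, and the mean of a Gaussian fit to
#' that ratio distribution (sample mean and sd of the finite ratios, the
#' maximum-likelihood Gaussian fit), plus the fraction of columns where the
#' first alignment achieves lower variance.
#'
#' @param a,b Aligned [kymograph]s (or matrices) of identical dimensions.
#' @return List with `ratio` (per-column `a`/`b` variance ratio), `mu`, `sd`
#'   and `fraction_improved`.
#' @export
variance_ratio <- function(a, b) {
  va <- time_trace(a)$column_variance
  vb <- time_trace(b)$column_variance
  if (length(va) != length(vb)) stop("kymographs differ in width")
  ratio <- va / vb
  ok <- is.finite(ratio)
  list(ratio = ratio,
       mu = mean(ratio[ok]),
       sd = stats::sd(ratio[ok]),
       fraction_improved = mean(va[ok] < vb[ok]))
}
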
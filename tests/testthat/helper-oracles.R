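# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (stats::filter, the row-wise DP) so that agreement
# is evidence, not tautology.

# Exhaustive enumeration over all complete, continuity-constrained paths.
# Mirrors the graph contract: steps bounded by k, pixels with cost >= barrier
# inadmissible. Returns the minimal cost (Inf if no admissible path) and all
# minimising paths.
enum_paths <- function(cost, k, barrier = 1) {
  m <- nrow(cost); n <- ncol(cost)
  open1 <- which(cost[1L, ] < barrier)
  if (length(open1) == 0L) return(list(cost = Inf, paths = NULL))
  paths <- matrix(open1, ncol = 1L)
  if (m >= 2L) {
    for (y in 2:m) {
      p <- nrow(paths)
      last <- paths[, ncol(paths)]
      nxt <- rep(last, each = 2L * k + 1L) + rep(seq.int(-k, k), p)
      rows <- rep(seq_len(p), each = 2L * k + 1L)
      keep <- nxt >= 1L & nxt <= n
      nxt <- nxt[keep]; rows <- rows[keep]
      keep2 <- cost[cbind(rep(y, length(nxt)), nxt)] < barrier
      if (!any(keep2)) return(list(cost = Inf, paths = NULL))
      paths <- cbind(paths[rows[keep2], , drop = FALSE], nxt[keep2])
    }
  }
  costs <- apply(paths, 1L, function(pp) sum(cost[cbind(seq_len(m), pp)]))
  best <- min(costs)
  list(cost = best, paths = paths[costs <= best + 1e-12, , drop = FALSE])
}

# Dense direct 2D Gaussian convolution with reflected (edge-repeating)
# boundaries; quadratic-time reference for the separable filters.
dense_gauss2d <- function(img, sigma_h, sigma_v,
                          rh = ceiling(4 * sigma_h),
                          rv = ceiling(4 * sigma_v)) {
  m <- nrow(img); n <- ncol(img)
  kh <- exp(-(-rh:rh)^2 / (2 * sigma_h^2)); kh <- kh / sum(kh)
  kv <- exp(-(-rv:rv)^2 / (2 * sigma_v^2)); kv <- kv / sum(kv)
  refl <- function(i, nn) {
    p <- 2L * nn
    j <- ((i - 1L) %% p + p) %% p
    ifelse(j < nn, j + 1L, p - j)
  }
  out <- matrix(0, m, n)
  for (yy in seq_len(m)) {
    for (xx in seq_len(n)) {
      acc <- 0
      for (dv in -rv:rv) {
        ys <- refl(yy + dv, m)
        for (dh in -rh:rh) {
          acc <- acc + kv[dv + rv + 1L] * kh[dh + rh + 1L] *
            img[ys, refl(xx + dh, n)]
        }
      }
      out[yy, xx] <- acc
    }
  }
  out
}

# Small simulated kymograph with default-style dynamics, for property tests.
small_sim <- function(seed, m = 30L, n = 80L, n_features = 2L) {
  bc <- generate_barcode(n = n, n_features = n_features, seed = seed)
  generate_kymograph(bc, m = m, seed = seed)
}

# Rigid slowly-varying shift of a barcode profile (one sinusoidal period,
# amplitude in pixels); motion every method parameter can follow.
rigid_shift_kymo <- function(profile, m, amplitude = 3) {
  n <- length(profile)
  sh <- amplitude * sin(2 * pi * seq_len(m) / m)
  spl <- stats::splinefun(seq_len(n), profile, method = "natural")
  list(img = t(vapply(sh, function(s) spl(pmin(pmax(seq_len(n) + s, 1), n)),
                      numeric(n))),
       shifts = sh)
}
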
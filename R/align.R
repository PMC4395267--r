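# Per-row coordinate maps used to straighten a detected feature.
#
# Each row's warp is piecewise linear: column 1 stays at 1, the feature column
# f moves to the region-wide mean position c_star, and column W stays at W.
# warp_nodes() returns the breakpoints of that map, handling the degenerate
# cases where the feature sits on a region edge (the empty side then passes
# through unchanged). The same nodes serve both directions: resampling the
# row (inverse map, output -> source) and tracking where a true band centre
# lands (forward map, source -> output).
warp_nodes <- function(f, c_star, W) {
  ident <- list(xin = c(1, W), xout = c(1, W))
  if (W < 3L || f == c_star) return(ident)
  if (f <= 1L) {
    if (c_star >= W) return(ident)
    return(list(xin = c(1, W), xout = c(c_star, W)))
  }
  if (f >= W) {
    if (c_star <= 1L) return(ident)
    return(list(xin = c(1, W), xout = c(1, c_star)))
  }
  if (c_star <= 1L) return(list(xin = c(f, W), xout = c(1, W)))
  if (c_star >= W) return(list(xin = c(1, f), xout = c(1, W)))
  list(xin = c(1, f, W), xout = c(1, c_star, W))
}

# Source coordinate for every output column 1..W; output columns outside the
# mapped range (degenerate edge cases) sample their own column unchanged.
warp_source_coords <- function(f, c_star, W) {
  nd <- warp_nodes(f, c_star, W)
  src <- stats::approx(nd$xout, nd$xin, xout = seq_len(W), rule = 1)$y
  miss <- is.na(src)
  if (any(miss)) src[miss] <- seq_len(W)[miss]
  src
}

# Forward map: where source positions p (possibly fractional) land after the
# row is straightened. Positions outside the region clamp to its ends.
warp_forward <- function(p, f, c_star, W) {
  nd <- warp_nodes(f, c_star, W)
  stats::approx(nd$xin, nd$xout, xout = p, rule = 2)$y
}

#' Straighten one feature within a region
#'
#' Warps each row of `region` so that the detected feature trajectory `F(y)`
#' sits at its mean position `c_star = round(mean(F))` in every row: pixels
#' left and right of the feature are stretched or compressed linearly, and
#' intensities at the resulting fractional positions are obtained by natural
#' cubic-spline interpolation of that row. Pinning the feature at its mean
#' places it at its thermodynamic-equilibrium position rather than at an
#' arbitrary frame's position. Output dimensions equal input dimensions.
#'
#' @param region Numeric matrix or [kymograph] (the region being aligned).
#' @param feature A `kymo_feature` from [detect_best_feature()], or an integer
#'   vector of per-row columns.
#' @param c_star Target column; defaults to the half-away-from-zero round of
#'   the mean path position.
#' @return Numeric matrix of the same dimensions with the feature straight.
#' @export
align_single_feature <- function(region, feature, c_star = NULL) {
  mat <- as_kymograph(region)$intensity
  m <- nrow(mat); W <- ncol(mat)
  path <- if (inherits(feature, "kymo_feature")) feature$path
          else as.integer(feature)
  if (length(path) != m) {
    stop("feature path must define one column for every row of the region")
  }
  if (any(path < 1L | path > W)) {
    stop("feature path leaves the region bounds")
  }
  if (is.null(c_star)) c_star <- as.integer(round_half_away(mean(path)))
  if (W < 3L) return(mat)
  xs <- seq_len(W)
  out <- mat
  for (y in seq_len(m)) {
    f <- path[y]
    if (f == c_star) next
    src <- warp_source_coords(f, c_star, W)
    spl <- stats::splinefun(xs, mat[y, ], method = "natural")
    out[y, ] <- spl(src)
  }
  out
}

#' Align a full kymograph
#'
#' Recursive weighted-path alignment: detect the most pronounced bright or
#' dark feature in the current region ([detect_best_feature()]), straighten it
#' to its mean position ([align_single_feature()]), split the region at the
#' aligned column, exclude `w` columns on each side of the split from further
#' search, and recurse left then right. Recursion stops in regions narrower
#' than `2w` (the width of a typical feature) or when the best path is not
#' distinct enough (rejected regions are recorded). The `2w + 1` columns
#' consumed at each split guarantee termination.
#'
#' Column removal applies to the feature *search* only: the output kymograph
#' always has the full input dimensions, with the aligned and excluded columns
#' written through unchanged.
#'
#' Sub-region detection runs on the current (partially aligned) image, with
#' two refinements over a standalone [detect_best_feature()] call: the
#' region's convolutions are padded with the surrounding image content
#' (reflection only at the true image edges), so interior cuts create no
#' artificial boundary extrema, and the Laplacian response is rescaled by the
#' whole kymograph's normalisation constants rather than the region's own
#' extremes, so `theta` rejects regions with no genuine contrast (flat
#' stretches and large dark gaps) instead of amplifying their numerical
#' noise into spurious features.
#'
#' @param kymo A [kymograph] or numeric matrix.
#' @param params An [align_params] object.
#' @return An object of class `kymo_alignment`: list with `aligned` (a
#'   [kymograph]), `features` (list ordered by region position, each carrying
#'   the absolute path, polarity, cost, mean position and region bounds),
#'   `rejected_regions`, `events` (the same features in application order,
#'   used to replay warps), `n_regions` (regions examined), `params`, and
#'   `raw` (the input).
#' @export
align_kymograph <- function(kymo, params = align_params()) {
  kymo <- as_kymograph(kymo)
  mat <- kymo$intensity
  m <- nrow(mat); n <- ncol(mat)
  events <- list()
  rejected <- list()
  n_regions <- 0L

  if (m >= 2L) {
    # global contrast scale: LoG extremes of the full smoothed input, used to
    # rescale every sub-region response onto one absolute scale
    sm0 <- smooth_kymograph(kymo, sigma_h = params$sigma_h,
                            sigma_v = params$sigma_v)
    k0 <- laplacian_raw(sm0$intensity, params$sigma_log)
    norm <- list(pos = if (any(k0 > 0)) max(k0) else 1,
                 neg = if (any(k0 < 0)) abs(min(k0)) else 1)
    pad <- as.integer(ceiling(4 * max(params$sigma_h, params$sigma_log)))

    detect_in_context <- function(lo, hi) {
      elo <- max(1L, lo - pad)
      ehi <- min(n, hi + pad)
      pp <- preprocess_kymograph(mat[, elo:ehi, drop = FALSE],
                                 sigma_h = params$sigma_h,
                                 sigma_v = params$sigma_v,
                                 sigma_log = params$sigma_log, norm = norm)
      sel <- seq.int(lo - elo + 1L, hi - elo + 1L)
      best_feature_from_costs(pp$bright[, sel, drop = FALSE],
                              pp$dark[, sel, drop = FALSE], params)
    }

    recurse <- function(lo, hi) {
      W <- hi - lo + 1L
      if (W < 2L * params$w) return(invisible(NULL))
      n_regions <<- n_regions + 1L
      sub <- mat[, lo:hi, drop = FALSE]
      feat <- detect_in_context(lo, hi)
      if (is.null(feat)) {
        rejected[[length(rejected) + 1L]] <<- c(lo, hi)
        return(invisible(NULL))
      }
      c_star <- feat$mean_position
      mat[, lo:hi] <<- align_single_feature(sub, feat$path, c_star)
      c_abs <- c_star + lo - 1L
      events[[length(events) + 1L]] <<- list(
        region = c(lo, hi),
        path = feat$path + lo - 1L,
        c_star = c_abs,
        polarity = feat$polarity,
        cost = feat$cost,
        mean_position = c_abs)
      recurse(lo, c_abs - 1L - params$w)
      recurse(c_abs + 1L + params$w, hi)
      invisible(NULL)
    }
    recurse(1L, n)
  }

  ord <- order(vapply(events, function(e) e$mean_position, integer(1L)))
  structure(
    list(aligned = kymograph(mat, pixel_size = kymo$pixel_size,
                             frame_interval = kymo$frame_interval),
         features = events[ord],
         rejected_regions = rejected,
         events = events,
         n_regions = n_regions,
         params = params,
         raw = kymo),
    class = "kymo_alignment")
}

#' @export
print.kymo_alignment <- function(x, ...) {
  d <- dim(x$aligned$intensity)
  cat(sprintf("kymograph alignment: %d x %d, %d feature(s), %d region(s) rejected\n",
              d[1L], d[2L], length(x$features), length(x$rejected_regions)))
  for (f in x$features) {
    cat(sprintf("  %s feature at column %d (region %d..%d, cost/row %.3f)\n",
                f$polarity, f$mean_position, f$region[1L], f$region[2L],
                f$cost / d[1L]))
  }
  invisible(x)
}

# Replay the alignment's per-row warps on arbitrary source positions, frame by
# frame. `positions` is an m x p matrix of per-frame positions (columns are
# tracked points); returns the same shape after all alignment events.
replay_warps <- function(alignment, positions) {
  m <- nrow(positions)
  out <- positions
  for (e in alignment$events) {
    lo <- e$region[1L]; hi <- e$region[2L]
    W <- hi - lo + 1L
    cs <- e$c_star - lo + 1L
    for (y in seq_len(m)) {
      inside <- which(out[y, ] >= lo & out[y, ] <= hi)
      if (length(inside)) {
        f <- e$path[y] - lo + 1L
        out[y, inside] <- warp_forward(out[y, inside] - lo + 1, f, cs, W) +
          lo - 1
      }
    }
  }
  out
}

# Serialise an alignment result (without pixel data) for reports.
alignment_summary <- function(alignment) {
  list(
    dims = dim(alignment$aligned$intensity),
    n_regions = alignment$n_regions,
    params = unclass(alignment$params),
    features = lapply(alignment$features, function(f) {
      list(region = f$region, mean_position = f$mean_position,
           polarity = f$polarity, cost = f$cost)
    }),
    rejected_regions = alignment$rejected_regions)
}
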
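#' Alignment parameters
#'
#' Bundles the tunable parameters of feature detection and alignment. Defaults
#' are the values used throughout: smoothing sigmas 10 (horizontal) and 3
#' (vertical) pixels, LoG sigma 10 pixels, continuity constraint `k = 2`
#' pixels/frame, feature half-width `w = 5` pixels (features are typically
#' ~10 px wide), and acceptance threshold `theta = 0.9` (normalised path cost
#' per row below which a feature is accepted).
#'
#' @param w Feature half-width in pixels; `2w` columns are excluded from
#'   further search around each aligned feature and regions narrower than `2w`
#'   are left untouched.
#' @param k Maximum horizontal displacement of a feature between adjacent
#'   frames, in pixels.
#' @param sigma_h,sigma_v,sigma_log Preprocessing scales in pixels.
#' @param theta Feature acceptance threshold on cost per row, in (0, 1].
#' @param source_edge_scheme Weighting of the edges leaving the source node:
#'   `"destination_intensity"` (default; every edge costs the pixel it points
#'   to) or `"unit"` (source edges cost 1 regardless of the first-row pixel).
#' @return An object of class `align_params`.
#' @export
align_params <- function(w = 5L, k = 2L, sigma_h = 10, sigma_v = 3,
                         sigma_log = 10, theta = 0.9,
                         source_edge_scheme = c("destination_intensity",
                                                "unit")) {
  source_edge_scheme <- match.arg(source_edge_scheme)
  w <- as.integer(w); k <- as.integer(k)
  if (w < 1L) stop("`w` must be >= 1")
  if (k < 0L) stop("`k` must be >= 0")
  if (sigma_h <= 0 || sigma_v <= 0 || sigma_log <= 0) {
    stop("filter sigmas must be positive")
  }
  if (theta <= 0 || theta > 1) stop("`theta` must be in (0, 1]")
  structure(list(w = w, k = k, sigma_h = sigma_h, sigma_v = sigma_v,
                 sigma_log = sigma_log, theta = theta,
                 source_edge_scheme = source_edge_scheme),
            class = "align_params")
}

#' Continuity constraint from molecule length
#'
#' The per-frame horizontal step bound `k` scales with the length of the DNA
#' molecule: longer molecules diffuse less per frame. With reference values
#' `k_ref = 2` at `L_ref = 24` micrometres, the linear rule returns
#' `max(1, round(k_ref * L_ref / L))`. The diffusion argument behind it
#' (diffusion length per frame shrinking with molecule length) also admits a
#' square-root reading, `k_ref * sqrt(L_ref / L)`, offered as `mode =
#' "sqrt"`; the linear rule is the default. Rounding is half-away-from-zero.
#'
#' @param L Molecule length in micrometres.
#' @param k_ref Reference continuity constraint (pixels/frame).
#' @param L_ref Reference molecule length in micrometres.
#' @param mode `"linear"` or `"sqrt"`.
#' @return Integer `k >= 1`.
#' @examples
#' choose_k(24)   # 2
#' choose_k(96)   # 1
#' @export
choose_k <- function(L, k_ref = 2L, L_ref = 24, mode = c("linear", "sqrt")) {
  mode <- match.arg(mode)
  if (!is.numeric(L) || L <= 0) stop("`L` must be a positive length in um")
  if (k_ref < 1L || L_ref <= 0) stop("invalid reference values")
  raw <- switch(mode,
                linear = k_ref * L_ref / L,
                sqrt = k_ref * sqrt(L_ref / L))
  max(1L, as.integer(round_half_away(raw)))
}

#' Minimum-cost continuity-constrained path through a cost image
#'
#' Finds the feature trajectory `F(y)` (one column per row) that minimises the
#' summed cost-image entries subject to the continuity constraint
#' `|F(y+1) - F(y)| <= k`. Conceptually this is the shortest source-to-sink
#' path in a DAG with one node per pixel plus two peripheral nodes: the source
#' connects to every first-row node, every last-row node connects to the sink
#' with weight 1, and each pixel connects to the `2k + 1` admissible pixels in
#' the next row, every edge weighted by the pixel it points to. Because the
#' graph is layered by rows, the search is a row-by-row dynamic program over
#' the implicit graph — the graph is never materialised, which keeps the work
#' at `O(m * n * (2k+1))` and memory at `O(m * n)`.
#'
#' Ties are broken towards the straightest step at every cell (smallest
#' horizontal displacement, then the smaller column) and towards the smallest
#' final column at the sink, so results are deterministic and paths stay
#' vertical across exact-cost plateaus instead of drifting. The constant
#' sink-edge weight cannot change the argmin and is excluded from the
#' reported cost, which is always the sum of traversed cost-image entries.
#'
#' @param cost Non-negative numeric cost matrix (`m x n`).
#' @param k Maximum horizontal step between adjacent rows, `>= 0`.
#' @param source_edge_scheme `"destination_intensity"` (source edges cost the
#'   first-row pixel they enter, the blanket rule) or `"unit"` (source edges
#'   cost 1, so the first row does not influence path choice).
#' @param barrier Pixels with cost `>= barrier` are barriers that features
#'   cannot cross: they are excluded from the admissible graph. The default 1
#'   matches the barrier value of [cost_images()]; use `Inf` to make every
#'   pixel admissible.
#' @return An object of class `kymo_feature`: list with integer `path`
#'   (length `m`), `cost` (sum of traversed entries), `mean_position`
#'   (half-away-from-zero round of `mean(path)`) and `polarity` (`NA`;
#'   filled in by [detect_best_feature()]) — or `NULL` if barriers leave no
#'   admissible complete path.
#' @export
shortest_feature_path <- function(cost, k = 2L,
                                  source_edge_scheme =
                                    c("destination_intensity", "unit"),
                                  barrier = 1) {
  source_edge_scheme <- match.arg(source_edge_scheme)
  if (!is.matrix(cost) || !is.numeric(cost)) {
    stop("`cost` must be a numeric matrix")
  }
  m <- nrow(cost); n <- ncol(cost)
  if (m < 1L || n < 1L) stop("empty region: cost image must be at least 1x1")
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be >= 0")

  blocked <- cost >= barrier
  dp <- if (source_edge_scheme == "destination_intensity") cost[1L, ]
        else rep(1, n)
  dp[blocked[1L, ]] <- Inf
  pred <- matrix(0L, m, n)
  steps <- if (k == 0L) 0L else
    c(0L, as.vector(rbind(-seq_len(k), seq_len(k))))
  if (m >= 2L) {
    for (y in 2:m) {
      best <- rep(Inf, n)
      bpred <- integer(n)
      # iterate predecessors by |displacement| (0, -1, +1, -2, +2, ...) so
      # that strict improvement keeps the straightest step on ties
      for (s in steps) {
        lo <- max(1L, 1L - s); hi <- min(n, n - s)
        if (lo > hi) next
        j <- lo:hi
        cand <- dp[j + s]
        upd <- cand < best[j]
        if (any(upd)) {
          ju <- j[upd]
          best[ju] <- cand[upd]
          bpred[ju] <- ju + s
        }
      }
      dp <- best + cost[y, ]
      dp[blocked[y, ]] <- Inf
      pred[y, ] <- bpred
    }
  }
  if (all(is.infinite(dp))) return(NULL)
  jend <- which.min(dp)  # first minimum = smallest column
  path <- integer(m)
  path[m] <- jend
  if (m >= 2L) {
    for (y in m:2) path[y - 1L] <- pred[y, path[y]]
  }
  total <- sum(cost[cbind(seq_len(m), path)])
  new_feature(path, cost = total, polarity = NA_character_, k = k)
}

new_feature <- function(path, cost, polarity, k = NA_integer_) {
  stopifnot(is.numeric(path), length(path) >= 1L)
  path <- as.integer(path)
  if (!is.na(k) && length(path) > 1L && any(abs(diff(path)) > k)) {
    stop("internal error: path violates the continuity constraint")
  }
  structure(list(path = path,
                 polarity = polarity,
                 cost = cost,
                 mean_position = as.integer(round_half_away(mean(path)))),
            class = "kymo_feature")
}

#' @export
print.kymo_feature <- function(x, ...) {
  cat(sprintf("feature: %s, %d rows, mean position %d, cost %.4f (%.4f/row)\n",
              ifelse(is.na(x$polarity), "unassigned", x$polarity),
              length(x$path), x$mean_position, x$cost,
              x$cost / length(x$path)))
  invisible(x)
}

#' Detect the best feature in a kymograph region
#'
#' Runs preprocessing on the region, solves the constrained shortest-path
#' problem on both the bright and the dark cost image, and keeps the
#' lower-cost of the two paths (ties go to dark, a fixed documented choice).
#' The winning path is accepted as a feature only if it is distinct enough:
#' its cost per row must fall below `theta`. Otherwise `NULL` is returned,
#' signalling rejection — this happens, e.g., in flat regions where every
#' cost entry sits at the barrier value.
#'
#' When called standalone, preprocessing is computed on the region itself and
#' the response rescaled by its own extremes. During recursive alignment
#' ([align_kymograph()]) the caller instead supplies `norm`, the global LoG
#' normalisation constants of the full kymograph, so that `theta` acts as an
#' absolute contrast test and featureless sub-regions (where every cost entry
#' sits near the barrier) are rejected rather than having numerical noise
#' amplified into spurious features.
#'
#' @param region A [kymograph] or matrix (a column slice of a larger image).
#' @param params An [align_params] object.
#' @param norm Optional `list(pos =, neg =)` fixed rescaling for the
#'   Laplacian response (see [laplacian_response()]).
#' @return A `kymo_feature` with `polarity` set, or `NULL` if rejected.
#' @export
detect_best_feature <- function(region, params = align_params(),
                                norm = NULL) {
  region <- as_kymograph(region)
  m <- nrow(region$intensity)
  pp <- preprocess_kymograph(region, sigma_h = params$sigma_h,
                             sigma_v = params$sigma_v,
                             sigma_log = params$sigma_log, norm = norm)
  best_feature_from_costs(pp$bright, pp$dark, params)
}

# Shared core: solve both polarities, keep the cheaper (ties -> dark), apply
# the distinctness threshold. Either polarity may have no admissible path at
# all (regions fenced off by barriers); both blocked means rejection.
best_feature_from_costs <- function(bright, dark, params) {
  m <- nrow(bright)
  fb <- shortest_feature_path(bright, k = params$k,
                              source_edge_scheme = params$source_edge_scheme)
  fd <- shortest_feature_path(dark, k = params$k,
                              source_edge_scheme = params$source_edge_scheme)
  if (is.null(fb) && is.null(fd)) return(NULL)
  best <- if (is.null(fb) || (!is.null(fd) && fd$cost <= fb$cost)) {
    fd$polarity <- "dark"; fd
  } else {
    fb$polarity <- "bright"; fb
  }
  if (best$cost / m < params$theta) best else NULL
}
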
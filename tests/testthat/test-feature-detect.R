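test_that("a free zero-cost column is found for any k", {
  for (k in 0:3) {
    cost <- matrix(0.9, 7, 9)
    cost[, 4] <- 0
    f <- shortest_feature_path(cost, k = k)
    expect_identical(f$path, rep(4L, 7))
    expect_equal(f$cost, 0)
    expect_identical(f$mean_position, 4L)
  }
})

test_that("k = 0 returns the constant column with minimal column sum", {
  set.seed(30)
  cost <- matrix(runif(48, 0, 0.9), 6, 8)
  f <- shortest_feature_path(cost, k = 0)
  expect_identical(f$path, rep(which.min(colSums(cost)), 6L))
  expect_equal(f$cost, min(colSums(cost)))
})

test_that("the DP equals exhaustive enumeration on random instances", {
  set.seed(31)
  for (i in 1:120) {
    m <- sample(1:6, 1); n <- sample(1:7, 1); k <- sample(0:2, 1)
    cost <- matrix(runif(m * n, 0, 0.95), m, n)
    oracle <- enum_paths(cost, k)
    f <- shortest_feature_path(cost, k = k)
    expect_equal(f$cost, oracle$cost, tolerance = 1e-12)
    # continuous costs: the minimiser is a.s. unique, so paths must agree
    if (nrow(oracle$paths) == 1L) {
      expect_identical(f$path, as.integer(oracle$paths[1L, ]))
    }
  }
})

test_that("the DP agrees with an explicit igraph shortest path", {
  # independent route: materialise the DAG (source, sink, one node per
  # pixel, destination-weighted edges) and ask igraph for the distance
  set.seed(36)
  for (i in 1:15) {
    m <- sample(2:6, 1); n <- sample(2:7, 1); k <- sample(0:2, 1)
    cost <- matrix(runif(m * n, 0, 0.95), m, n)
    id <- function(y, j) (y - 1L) * n + j
    src <- m * n + 1L; snk <- m * n + 2L
    from <- integer(0); to <- integer(0); wt <- numeric(0)
    for (j in 1:n) {
      from <- c(from, src); to <- c(to, id(1L, j)); wt <- c(wt, cost[1L, j])
      from <- c(from, id(m, j)); to <- c(to, snk); wt <- c(wt, 1)
    }
    if (m > 1) {
      for (y in 1:(m - 1L)) {
        for (j in 1:n) {
          for (j2 in max(1L, j - k):min(n, j + k)) {
            from <- c(from, id(y, j)); to <- c(to, id(y + 1L, j2))
            wt <- c(wt, cost[y + 1L, j2])
          }
        }
      }
    }
    g <- igraph::make_graph(rbind(from, to), n = snk, directed = TRUE)
    d <- igraph::distances(g, v = src, to = snk, mode = "out", weights = wt)
    f <- shortest_feature_path(cost, k = k)
    expect_equal(f$cost + 1, as.numeric(d), tolerance = 1e-12)
  }
})

test_that("every returned path satisfies continuity and completeness", {
  set.seed(32)
  for (i in 1:40) {
    m <- sample(2:12, 1); n <- sample(2:15, 1); k <- sample(0:3, 1)
    f <- shortest_feature_path(matrix(runif(m * n, 0, 0.95), m, n), k = k)
    expect_length(f$path, m)
    expect_true(all(f$path >= 1 & f$path <= n))
    if (m > 1) expect_true(all(abs(diff(f$path)) <= k))
  }
})

test_that("adding a constant shifts the optimal cost by c*m, path unchanged", {
  set.seed(33)
  cost <- matrix(runif(60, 0, 0.4), 10, 6)
  f0 <- shortest_feature_path(cost, k = 1, barrier = Inf)
  for (cc in c(0.05, 0.3)) {
    f1 <- shortest_feature_path(cost + cc, k = 1, barrier = Inf)
    expect_equal(f1$cost, f0$cost + cc * 10, tolerance = 1e-12)
    expect_identical(f1$path, f0$path)
  }
})

test_that("barrier pixels cannot be crossed and can fence off all paths", {
  # a full-width barrier wall blocks every path
  cost <- matrix(0.1, 6, 5)
  cost[3, ] <- 1
  expect_null(shortest_feature_path(cost, k = 2))

  # a gap in the wall forces the path through it
  cost[3, 5] <- 0.2
  f <- shortest_feature_path(cost, k = 2)
  expect_identical(f$path[3], 5L)

  # with barrier = Inf the wall is merely expensive
  f2 <- shortest_feature_path(cost, k = 0, barrier = Inf)
  expect_length(f2$path, 6L)
})

test_that("paths stay straight across exact-cost plateaus", {
  cost <- matrix(0.5, 20, 15)
  f <- shortest_feature_path(cost, k = 2)
  expect_identical(diff(range(f$path)), 0L)
})

test_that("the source-edge scheme changes first-row handling only", {
  set.seed(34)
  cost <- matrix(runif(40, 0, 0.9), 5, 8)
  fd <- shortest_feature_path(cost, k = 1, "destination_intensity")
  fu <- shortest_feature_path(cost, k = 1, "unit")
  # reported cost is always the sum of traversed entries
  expect_equal(fd$cost, sum(cost[cbind(1:5, fd$path)]))
  expect_equal(fu$cost, sum(cost[cbind(1:5, fu$path)]))
})

test_that("work per call scales bilinearly in m and n", {
  set.seed(35)
  t_of <- function(m, n) {
    cost <- matrix(runif(m * n, 0, 0.9), m, n)
    reps <- 3L
    t0 <- proc.time()[3]
    for (r in seq_len(reps)) shortest_feature_path(cost, k = 2)
    (proc.time()[3] - t0) / reps
  }
  base <- t_of(100, 400)
  grown <- t_of(100, 3200)
  # 8x the columns should cost roughly 8x, certainly not quadratically
  expect_lt(grown / max(base, 1e-4), 30)
})

test_that("k is chosen from molecule length by the printed rule", {
  expect_identical(choose_k(24), 2L)
  expect_identical(choose_k(24, mode = "sqrt"), 2L)
  expect_identical(choose_k(96), 1L)
  expect_identical(choose_k(12), 4L)
  expect_identical(choose_k(96, mode = "sqrt"), 1L)
  expect_identical(choose_k(1e6), 1L)  # floor at 1
  expect_error(choose_k(-3), "positive")
})

test_that("detect_best_feature accepts a clean band and reports polarity", {
  bc <- generate_barcode(n = 100, n_features = 1, seed = 41)
  sim <- generate_kymograph(bc, m = 40, com_step_sd = 0.2, stretch_sd = 0.3,
                            noise_sd = 2, seed = 41)
  f <- detect_best_feature(sim$kymograph)
  expect_s3_class(f, "kymo_feature")
  expect_identical(f$polarity, "bright")
  expect_true(all(abs(f$path - sim$truth$centers[, 1]) <= 1.5))
})

test_that("a vanishing threshold rejects every region", {
  sim <- small_sim(42)
  p <- align_params(theta = 1e-9)
  expect_null(detect_best_feature(sim$kymograph, p))
})

test_that("the stronger dark band wins the polarity contest", {
  # bright bump of amplitude 30 and dark trough of amplitude 80: the dark
  # valley has the larger Laplacian magnitude and must be selected
  x <- seq_len(120)
  prof <- 200 + 30 * exp(-(x - 35)^2 / 18) - 80 * exp(-(x - 85)^2 / 18)
  img <- matrix(rep(prof, each = 30), nrow = 30)
  img <- img + matrix(rnorm(length(img), 0, 0.5), nrow = 30)
  f <- detect_best_feature(img, align_params(sigma_h = 3, sigma_log = 3))
  expect_identical(f$polarity, "dark")
  expect_lt(abs(f$mean_position - 85), 3)
})
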
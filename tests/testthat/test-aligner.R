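test_that("a feature already at its mean position is an exact no-op", {
  set.seed(50)
  img <- matrix(runif(200, 50, 150), 10, 20)
  out <- align_single_feature(img, rep(7L, 10))
  expect_equal(out, img, tolerance = 1e-12)
})

test_that("single-feature warp matches a direct spline evaluation oracle", {
  set.seed(51)
  img <- matrix(runif(10, 50, 150), 2, 5)
  out <- align_single_feature(img, c(1L, 3L))
  # c* = round(mean(c(1, 3))) = 2
  # row 1: feature at column 1 (edge): left side degenerate, passes through;
  # output cols 2..5 sample source nodes (2,5) -> (1,5)
  spl1 <- stats::splinefun(1:5, img[1, ], method = "natural")
  src1 <- c(1, 1 + (2:5 - 2) * 4 / 3)
  expect_equal(out[1, ], spl1(src1), tolerance = 1e-12)
  # row 2: nodes (1,3,5) -> (1,2,5): col 2 takes the value at source col 3
  spl2 <- stats::splinefun(1:5, img[2, ], method = "natural")
  src2 <- stats::approx(c(1, 2, 5), c(1, 3, 5), xout = 1:5)$y
  expect_equal(out[2, ], spl2(src2), tolerance = 1e-12)
  expect_equal(out[2, 2], img[2, 3], tolerance = 1e-12)
})

test_that("the aligned feature column is the rounded mean of the path", {
  set.seed(52)
  for (i in 1:10) {
    m <- sample(3:12, 1); n <- sample(8:25, 1)
    path <- cumsum(c(sample(2:(n - 2), 1), sample(-1:1, m - 1, TRUE)))
    path <- pmin(pmax(path, 1L), n)
    c_star <- as.integer(floor(mean(path) + 0.5))
    x <- seq_len(n)
    img <- t(vapply(path, function(f) exp(-(x - f)^2 / 4), numeric(n)))
    out <- align_single_feature(img, path)
    peaks <- apply(out, 1, which.max)
    expect_true(all(abs(peaks - c_star) <= 1))
  }
})

test_that("feature paths outside the region are contract errors", {
  img <- matrix(1, 4, 6)
  expect_error(align_single_feature(img, c(1L, 2L, 3L)), "every row")
  expect_error(align_single_feature(img, c(1L, 2L, 3L, 9L)), "bounds")
})

test_that("alignment preserves dimensions and leaves straight input alone", {
  sim <- small_sim(53)
  res <- align_kymograph(sim$kymograph)
  expect_identical(dim(res$aligned$intensity), dim(sim$kymograph$intensity))

  # all rows identical: every detected path is constant, output unchanged
  prof <- generate_barcode(n = 90, n_features = 2, seed = 54)$profile
  flat <- matrix(rep(prof, each = 25), nrow = 25)
  resf <- align_kymograph(flat)
  expect_equal(resf$aligned$intensity, flat, tolerance = 1e-9)
  expect_equal(time_trace(resf$aligned)$mean_variance, 0, tolerance = 1e-18)
})

test_that("inputs narrower than 2w pass through with no features", {
  img <- matrix(runif(45), 5, 9)  # 9 < 2w = 10
  res <- align_kymograph(img)
  expect_identical(res$aligned$intensity, img)
  expect_length(res$features, 0L)

  one_frame <- matrix(runif(50), 1, 50)
  res1 <- align_kymograph(one_frame)
  expect_identical(res1$aligned$intensity, one_frame)
  expect_length(res1$features, 0L)
})

test_that("slow rigid shifts are corrected almost completely", {
  bc <- generate_barcode(n = 170, n_features = 3, seed = 11)
  rs <- rigid_shift_kymo(bc$profile, m = 160, amplitude = 3)
  res <- align_kymograph(rs$img)
  v0 <- time_trace(rs$img)$mean_variance
  v1 <- time_trace(res$aligned)$mean_variance
  expect_lte(v1, 0.1 * v0)

  # replaying the recorded warps on the true band trajectories: each band
  # ends up occupying a fixed column to within ~1 px
  centers <- matrix(rep(bc$centers, each = 160), nrow = 160) - rs$shifts
  tracked <- kymoalign:::replay_warps(res, centers)
  dev <- apply(tracked, 2, function(p) max(abs(p - mean(p))))
  expect_true(all(dev <= 1.3))
})

test_that("alignment reduces mean variance on default-style simulations", {
  sim <- small_sim(55, m = 60L, n = 120L, n_features = 3L)
  res <- align_kymograph(sim$kymograph)
  err <- alignment_error(res, sim$truth)
  expect_gt(err$variance_reduction, 1.5)
  expect_equal(err$match_fraction, 1)
})

test_that("realigning an aligned kymograph barely changes the variance", {
  sim <- small_sim(56, m = 60L, n = 120L, n_features = 3L)
  once <- align_kymograph(sim$kymograph)
  twice <- align_kymograph(once$aligned)
  v1 <- time_trace(once$aligned)$mean_variance
  v2 <- time_trace(twice$aligned)$mean_variance
  expect_lt(abs(v2 - v1) / v1, 0.05)
})

test_that("recursion terminates within the region budget", {
  sim <- small_sim(57, m = 25L, n = 150L, n_features = 3L)
  res <- align_kymograph(sim$kymograph)
  w <- res$params$w
  # each accepted split consumes >= 2w+1 columns of search width, and every
  # examined region is an accepted split, a rejection, or a leaf, so the
  # number of examined regions is at most twice the split budget plus one
  expect_lte(res$n_regions, 2L * ceiling(150 / (2 * w + 1)) + 1L)
  # feature mean positions are strictly increasing across the sorted list
  pos <- vapply(res$features, function(f) f$mean_position, integer(1))
  if (length(pos) > 1) expect_true(all(diff(pos) > 0))
})
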
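test_that("MSD of identical and uniformly offset curves is exact", {
  A <- cbind(seq(0, 100, length.out = 100), 0)
  expect_equal(msd_modified(A, A)$msd_mm, 0)
  expect_gte(msd_modified(A, A)$n_distances, 2)
  B <- cbind(seq(0, 100, length.out = 100), 2)
  expect_equal(msd_modified(A, B)$msd_mm, 2)
  # no endpoint collapse occurs for aligned equal-length curves
  expect_equal(msd_standard(A, B)$msd_mm, msd_modified(A, B)$msd_mm)
  expect_error(msd_modified(A[1, , drop = FALSE], B), "2 samples")
})

test_that("a sub-curve of a curve scores zero modified MSD", {
  set.seed(71)
  for (rep in 1:5) {
    ctrl <- random_smooth_curve(9)
    cv <- interpolate_spline(ctrl, 100)
    i0 <- sample(1:30, 1)
    sub <- cv[i0:(i0 + sample(40:60, 1)), ]
    expect_lt(msd_modified(cv, sub)$msd_mm, 1e-9)
    expect_lt(msd_modified(sub, cv)$msd_mm, 1e-9) # and symmetric
    # the overhang inflates only the standard form
    expect_gt(msd_standard(cv, sub)$msd_mm, 0.1)
  }
})

test_that("standard MSD dominates modified MSD on estimate-vs-hand ensembles", {
  # the endpoint rule removes, per target endpoint, all but the shortest of
  # the distances matched to that endpoint; in estimator-vs-label geometry
  # (a perturbed/offset/truncated version of the same contour) those are
  # the overhang distances, the largest in the pool, so collapsing them
  # can only lower the mean
  set.seed(81)
  for (rep in 1:20) {
    ctrl <- random_smooth_curve(9)
    a <- interpolate_spline(ctrl, 100)
    b <- offset_curve_normal(a, rnorm(1, 0, 1.5))
    if (rep %% 2 == 0) b <- b[1:sample(50:90, 1), ]
    ms <- msd_standard(a, b)$msd_mm
    mm <- msd_modified(a, b)$msd_mm
    expect_gte(ms, mm - 1e-12)
    expect_gte(mm, 0)
  }
})

test_that("MSD is symmetric and invariant under common rigid motion", {
  set.seed(91)
  a <- interpolate_spline(random_smooth_curve(9), 100)
  b <- interpolate_spline(random_smooth_curve(9), 100)
  expect_equal(msd_modified(a, b)$msd_mm, msd_modified(b, a)$msd_mm)
  expect_equal(msd_standard(a, b)$msd_mm, msd_standard(b, a)$msd_mm)
  ar <- rotate_points(a, 0.7, c(10, -5)) + 3
  br <- rotate_points(b, 0.7, c(10, -5)) + 3
  expect_equal(msd_modified(ar, br)$msd_mm, msd_modified(a, b)$msd_mm,
    tolerance = 1e-9
  )
})

test_that("modified MSD matches an independent brute-force oracle", {
  set.seed(101)
  for (rep in 1:100) {
    a <- interpolate_spline(random_smooth_curve(7), 100)
    b <- interpolate_spline(random_smooth_curve(7), 100)
    if (rep %% 3 == 0) b <- b[1:sample(40:95, 1), ]
    expect_equal(msd_modified(a, b)$msd_mm, brute_msd_modified(a, b),
      tolerance = 1e-12
    )
  }
})

test_that("MSD at working density tracks a 10x dense-sampling evaluation", {
  # the same curve pair evaluated at 100 and at 1000 samples should agree
  # within the discretization error of the coarser sampling (about half
  # the inter-sample spacing)
  set.seed(111)
  for (rep in 1:10) {
    c1 <- random_smooth_curve(9)
    c2 <- random_smooth_curve(9)
    coarse <- msd_modified(
      interpolate_spline(c1, 100), interpolate_spline(c2, 100)
    )$msd_mm
    dense <- msd_modified(
      interpolate_spline(c1, 1000), interpolate_spline(c2, 1000)
    )$msd_mm
    spacing <- arc_length(interpolate_spline(c1, 100)) / 99
    expect_lt(abs(coarse - dense), spacing)
  }
})

test_that("constant perpendicular displacement is recovered exactly", {
  set.seed(121)
  for (d in c(0.5, 1.25, 2)) {
    cv <- interpolate_spline(random_smooth_curve(9), 100)
    off <- offset_curve_normal(cv, d)
    expect_equal(msd_modified(cv, off)$msd_mm, d, tolerance = 0.02 * d)
  }
})

test_that("Gaussian perpendicular jitter recovers the half-normal mean", {
  set.seed(131)
  sigma <- 1
  n_frames <- 400
  cv <- interpolate_spline(random_smooth_curve(9), 100)
  msds <- replicate(n_frames, {
    msd_modified(cv, offset_curve_normal(cv, rnorm(1, 0, sigma)))$msd_mm
  })
  expect_equal(mean(msds), sigma * sqrt(2 / pi), tolerance = 0.05)
})

test_that("length difference follows the est-minus-hand sign convention", {
  hand <- cbind(seq(0, 100, length.out = 50), 0)
  est <- cbind(seq(0, 102, length.out = 50), 0)
  ld <- length_difference(hand, est)
  expect_equal(ld$diff_mm, 2, tolerance = 1e-9)
  expect_equal(ld$pct, 2, tolerance = 1e-9)
  shrunk <- cbind(seq(0, 96, length.out = 50), 0)
  expect_equal(length_difference(hand, shrunk)$pct, -4, tolerance = 1e-9)
  same <- length_difference(hand, hand)
  expect_equal(same$diff_mm, 0)
  expect_equal(same$pct, 0)
  expect_error(length_difference(cbind(0, 0), est), "zero length")
})

test_that("keypoint RMSE gates on estimate confidence", {
  hand <- frame_keypoints(c("a", "b"), c(0, 10), c(0, 0), 1)
  est_eq <- frame_keypoints(c("a", "b"), c(0, 10), c(0, 0), 1)
  expect_equal(rmse_keypoints(hand, est_eq), 0)
  est_off <- frame_keypoints(c("a", "b"), c(3, 13), c(4, 4), 1)
  expect_equal(rmse_keypoints(hand, est_off), 5)
  # offsets 5 and 13; the second is excluded at cutoff 0.6
  est_mix <- frame_keypoints(c("a", "b"), c(3, 15), c(4, 12), c(0.9, 0.5))
  expect_equal(rmse_keypoints(hand, est_mix, 0.6), 5)
  expect_true(is.na(rmse_keypoints(hand,
    frame_keypoints(c("a", "b"), c(0, 1), c(0, 0), 0.1))))
  expect_error(
    rmse_keypoints(hand, frame_keypoints("z", 0, 0, 1)),
    "no shared"
  )
})

test_that("per-group summaries use n-1 sd and equal frame weights", {
  df <- data.frame(msd_mm = c(1, 2, 3), pct = c(-1, 0, 4))
  s <- summarize_frames(df, "g")
  expect_equal(s$msd_mean, 2)
  expect_equal(s$msd_sd, 1)
  expect_equal(s$msd_median, 2)
  expect_equal(s$pct_mean, 1)
  expect_equal(s$n_frames, 3)
  w <- capture_warnings(
    s1 <- summarize_frames(data.frame(msd_mm = 1, pct = 0), "one")
  )
  expect_match(w, "sd = 0", all = TRUE) # once per summarized column
  expect_equal(s1$msd_sd, 0)
  expect_equal(s1$msd_mean, 1)
  # agreement with an independent recomputation on a larger batch
  set.seed(141)
  big <- data.frame(msd_mm = rexp(500), pct = rnorm(500))
  s2 <- summarize_frames(big, "big")
  expect_equal(s2$msd_mean, sum(big$msd_mm) / 500)
  expect_equal(
    s2$msd_sd,
    sqrt(sum((big$msd_mm - mean(big$msd_mm))^2) / 499)
  )
  expect_equal(s2$pct_median, sort(big$pct)[250:251] |> mean())
})

test_that("distribution comparison reproduces the two t-test variants", {
  a <- c(1, 2, 3, 4)
  expect_equal(compare_distributions(a, a, "equal")$t, 0)
  expect_equal(compare_distributions(a, a, "equal")$p, 1)
  set.seed(151)
  x <- rnorm(100)
  y <- x + 10
  expect_lt(compare_distributions(x, y)$p, 1e-10)
  expect_error(compare_distributions(1, a), "at least 2")
  # Welch df lies between min(n)-1 and n1+n2-2; Student df is exact
  r <- compare_distributions(rnorm(10), rnorm(20, sd = 3), "unequal")
  expect_gte(r$df, 9)
  expect_lte(r$df, 28)
  expect_equal(compare_distributions(rnorm(10), rnorm(20), "equal")$df, 28)
})

test_that("t-test p-values agree with a permutation oracle", {
  set.seed(161)
  x <- rnorm(50)
  y <- rnorm(50, mean = 0.3)
  p_t <- compare_distributions(x, y, "equal")$p
  # permutation distribution of the mean difference
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  nperm <- 20000
  exceed <- 0
  for (i in seq_len(nperm)) {
    idx <- sample.int(100, 50)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs) {
      exceed <- exceed + 1
    }
  }
  p_perm <- exceed / nperm
  expect_equal(p_t, p_perm, tolerance = 0.03)
})
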
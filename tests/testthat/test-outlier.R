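test_that("distances match the hand-computed 2-D Mahalanobis oracle", {
  set.seed(21)
  X <- cbind(rnorm(40, 3, 2), rnorm(40, -1, 0.5))
  X[, 2] <- X[, 2] + 0.6 * X[, 1]
  d <- mahalanobis_distances(X, n_scores = 2)
  # explicit 2x2 inverse
  mu <- colMeans(X)
  S <- stats::cov(X)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / det_s
  oracle <- apply(X, 1, function(x) sqrt((x - mu) %*% Sinv %*% (x - mu)))
  expect_equal(as.vector(d), unname(oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a sample at the score-space mean has distance zero", {
  set.seed(22)
  base <- matrix(rnorm(60), 20, 3)
  X <- rbind(base, -base, 0)       # symmetric: row 41 sits at the mean
  d <- mahalanobis_distances(X, n_scores = 3)
  expect_lt(d[41], 1e-8)
})

test_that("distances are invariant under invertible affine maps", {
  set.seed(23)
  X <- matrix(rnorm(120), 40, 3)
  A <- matrix(c(2, 0.5, 0, -1, 3, 1, 0.2, 0, 1), 3)
  Y <- X %*% A + matrix(c(5, -2, 7), 40, 3, byrow = TRUE)
  d1 <- mahalanobis_distances(X, n_scores = 3)
  d2 <- mahalanobis_distances(Y, n_scores = 3)
  expect_equal(unname(d1), unname(d2), tolerance = 1e-8)
})

test_that("screening preconditions and degenerate paths", {
  set.seed(24)
  X <- matrix(rnorm(50), 10, 5)
  expect_error(mahalanobis_distances(X, n_scores = 9), "more samples")
  expect_error(flag_outliers(X[1:2, ]), "at least 3")
  # an absurdly low chi2 threshold flags everything -> degenerate error
  expect_error(flag_outliers(X, rule = "chi2", alpha = 1e-12, n_scores = 3),
               "every sample flagged")
  # k -> large: nothing flagged
  scr <- flag_outliers(X, k = 100, n_scores = 3)
  expect_length(scr$flagged_ids, 0L)
  expect_equal(nrow(scr$retained), 10L)
})

test_that("false positives on a clean i.i.d. Gaussian set are <= 1", {
  # Monte-Carlo under the null: 335 iid Gaussian spectra, mean+3sd rule
  set.seed(25)
  X <- matrix(rnorm(335 * 50), 335, 50)
  scr <- flag_outliers(X, n_scores = 10)
  expect_lte(length(scr$flagged_ids), 1L)
})

test_that("planted gross outliers are recovered on process data", {
  for (s in 1:5) {
    ds <- small_dataset(seed = s, n_batches = 7, by = 22.64)
    sm <- savgol_smooth(average_replicates(ds$spectra))
    scr <- flag_outliers(sm)
    expect_setequal(scr$flagged_ids, ds$outlier_ids)
    expect_equal(nrow(scr$retained$intensities), 330L)
    # flagged/retained partition the input, distances respect the threshold
    expect_setequal(c(scr$flagged_ids, scr$retained$sample_ids),
                    names(scr$distances))
    expect_true(all(scr$distances[scr$flagged_ids] > scr$threshold))
    expect_true(all(scr$distances[scr$retained$sample_ids] <= scr$threshold))
  }
})

test_that("re-screening the retained set is stable", {
  ds <- small_dataset(seed = 9, n_batches = 7, by = 22.64)
  sm <- savgol_smooth(average_replicates(ds$spectra))
  scr <- flag_outliers(sm)
  scr2 <- flag_outliers(scr$retained)
  expect_lte(length(scr2$flagged_ids), 2L)
})
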
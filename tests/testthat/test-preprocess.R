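test_that("S-G smoothing preserves constants and low-order polynomials", {
  X <- matrix(5, 3, 50)
  expect_equal(savgol_smooth(X, 11, 3), X, tolerance = 1e-10,
               ignore_attr = TRUE)
  # a cubic is reproduced exactly by a cubic local fit (oracle: direct
  # polynomial evaluation)
  t <- seq_len(80)
  cubic <- 2 + 0.5 * t - 0.03 * t^2 + 1e-4 * t^3
  sm <- savgol_smooth(matrix(cubic, 1), 11, 3)
  expect_equal(as.vector(sm), cubic, tolerance = 1e-8)
})

test_that("S-G matches the explicit local least-squares oracle", {
  set.seed(31)
  window <- 11L; polyorder <- 3L; half <- 5L
  for (rep in 1:10) {
    y <- rnorm(60)
    sm <- as.vector(savgol_smooth(matrix(y, 1), window, polyorder))
    for (i in c(6, 17, 33, 55)) {              # interior channels
      expect_equal(sm[i], savgol_oracle_point(y, i, window, polyorder),
                   tolerance = 1e-10)
    }
  }
})

test_that("major bands survive smoothing as local maxima", {
  axis <- default_axis()
  y <- band_spectrum(axis) + 0.2            # offset keeps minmax sane
  m <- raman_spectra(axis, matrix(y, 1), "s")
  sm <- savgol_smooth(m)
  for (center in c(1000, 1250, 1500)) {
    i <- which.min(abs(axis - center))
    win <- sm$intensities[1, (i - 5):(i + 5)]
    expect_equal(which.max(win), 6L)         # still peaked at the band
  }
})

test_that("S-G parameter validation", {
  X <- matrix(rnorm(40), 2, 20)
  expect_error(savgol_smooth(X, 10, 3), "odd")
  expect_error(savgol_smooth(X, 3, 3), "exceed")
  expect_error(savgol_smooth(X, 31, 3), "channel count")
})

test_that("min-max maps each spectrum exactly onto [0, 1]", {
  expect_equal(as.vector(minmax_scale(matrix(c(2, 4, 6), 1))),
               c(0, 0.5, 1))
  # idempotent on the canonical range
  x <- matrix(c(0, 0.25, 1, 0.5), 1)
  expect_equal(minmax_scale(x), x, ignore_attr = TRUE)
  # invariant to positive affine transforms
  set.seed(8)
  y <- matrix(rnorm(30), 2, 15)
  expect_equal(minmax_scale(3.7 * y + 11), minmax_scale(y),
               tolerance = 1e-12)
  # exact bounds on random spectra
  sc <- minmax_scale(matrix(rnorm(200), 10, 20))
  expect_equal(apply(sc, 1, min), rep(0, 10))
  expect_equal(apply(sc, 1, max), rep(1, 10))
})

test_that("constant spectra are rejected by name", {
  m <- raman_spectra(1:4, rbind(c(1, 2, 3, 4), c(7, 7, 7, 7)),
                     c("ok", "flat-one"))
  expect_error(minmax_scale(m), "flat-one")
})

test_that("the pretreatment pipeline applies its stages in order", {
  ds <- small_dataset(seed = 2, n_batches = 1)
  pp <- preprocess_spectra(ds$spectra)
  expect_equal(nrow(pp$intensities), nrow(ds$truth))   # averaged
  expect_equal(apply(pp$intensities, 1, min), rep(0, nrow(pp$intensities)),
               ignore_attr = TRUE)
  expect_equal(apply(pp$intensities, 1, max), rep(1, nrow(pp$intensities)),
               ignore_attr = TRUE)
  expect_equal(pp$meta$preprocess$order, c("average", "savgol", "minmax"))
  # manual composition gives the same result (stages are pure)
  manual <- minmax_scale(savgol_smooth(average_replicates(ds$spectra)))
  expect_equal(pp$intensities, manual$intensities, tolerance = 1e-12)
})
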
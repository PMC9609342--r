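test_that("soluble-solid formula and its error paths", {
  expect_equal(compute_soluble_solid(W = 3, W1 = 10, W2 = 10), 0)
  expect_equal(compute_soluble_solid(W = 2, W1 = 10, W2 = 10.05), 2.5)
  expect_equal(compute_soluble_solid(W = 3, W1 = 12, W2 = 12.06), 2)
  expect_equal(compute_soluble_solid(W = c(2, 3), W1 = c(10, 12),
                                     W2 = c(10.05, 12.06)), c(2.5, 2))
  expect_error(compute_soluble_solid(0, 10, 10.1), "positive")
  expect_error(compute_soluble_solid(-1, 10, 10.1), "positive")
  expect_error(compute_soluble_solid(2, 10, 9.9), "W2")
})

test_that("schedule time points follow the dense/sparse rule", {
  s <- sampling_schedule()          # 120 / 90 / 90 min stages
  tp <- schedule_timepoints(s)
  counts <- table(tp$stage)
  expect_equal(as.vector(counts), c(18L, 15L, 15L))
  expect_equal(tp$minute[tp$stage == 1],
               c(seq(5, 60, 5), seq(70, 120, 10)))
  # closed-form count property over random schedules
  set.seed(42)
  for (rep in 1:20) {
    dur <- sample(70:200, 1)
    dense <- sample(c(2, 5, 10), 1)
    sparse <- sample(c(10, 15, 20), 1)
    win <- sample(c(30, 60), 1)
    tp <- schedule_timepoints(sampling_schedule(dur, dense, sparse, win))
    expect_equal(nrow(tp), floor(win / dense) + floor((dur - win) / sparse))
    expect_true(all(diff(tp$minute) > 0))
  }
  # degenerate: equal intervals give a uniform grid
  tp <- schedule_timepoints(sampling_schedule(60, 10, 10, 30))
  expect_equal(tp$minute, seq(10, 60, 10))
  expect_error(sampling_schedule(dense_interval = 0), "positive")
})

test_that("rendered spectra are linear mixtures with peaks in place", {
  comps <- default_components()
  axis <- default_axis()
  zero <- render_spectrum(rep(0, 5), comps, axis)
  expect_equal(zero, numeric(length(axis)))
  # superposition over random concentration pairs
  set.seed(7)
  for (rep in 1:5) {
    c1 <- runif(5, 0, 100); c2 <- runif(5, 0, 100)
    y1 <- render_spectrum(c1, comps, axis)
    y2 <- render_spectrum(c2, comps, axis)
    y12 <- render_spectrum(c1 + c2, comps, axis)
    expect_equal(y12, y1 + y2, tolerance = 1e-12)
    expect_equal(render_spectrum(2 * c1, comps, axis), 2 * y1,
                 tolerance = 1e-12)
  }
  # single Gaussian at 1000 peaks at the nearest axis point
  single <- list(pure_component("x", 1000, 15, 1))
  y <- render_spectrum(1, single, axis)
  expect_equal(which.max(y), which.min(abs(axis - 1000)))
  expect_error(render_spectrum(-1, single, axis), "non-negative")
  expect_error(render_spectrum(c(1, 2), single, axis), "one concentration")
})

test_that("generate_dataset honours the sampling frame and drop_last", {
  ds336 <- small_dataset(seed = 3, n_batches = 7, drop_last = FALSE,
                         replicates = 1)
  expect_equal(nrow(ds336$truth), 336L)
  ds335 <- small_dataset(seed = 3, n_batches = 7, drop_last = TRUE,
                         replicates = 1)
  expect_equal(nrow(ds335$truth), 335L)
  expect_equal(nrow(ds335$spectra$intensities), 335L)
  # triplicates multiply acquisitions, not samples
  ds <- small_dataset(seed = 3, n_batches = 1, replicates = 3)
  expect_equal(nrow(ds$spectra$intensities), 3L * nrow(ds$truth))
})

test_that("planted outliers are recorded and configurable", {
  ds <- small_dataset(seed = 4)
  expect_length(ds$outlier_ids, 5L)
  expect_true(all(ds$outlier_ids %in% ds$truth$sample_id))
  ds0 <- small_dataset(seed = 4, outliers = list(n = 0))
  expect_length(ds0$outlier_ids, 0L)
  expect_error(small_dataset(n_batches = 1, outliers = list(n = 500)),
               "smaller than the sample count")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- small_dataset(seed = 11)
  b <- small_dataset(seed = 11)
  expect_identical(a$spectra$intensities, b$spectra$intensities)
  expect_identical(a$references, b$references)
  expect_identical(a$outlier_ids, b$outlier_ids)
  c <- small_dataset(seed = 12)
  expect_false(identical(a$spectra$intensities, c$spectra$intensities))
  # written artifacts are byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(a, d1); write_dataset(b, d2)
  for (f in c("spectra.csv", "references.csv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ground-truth soluble solid spans the configured range", {
  ds <- small_dataset(seed = 5)
  ss <- ds$truth$soluble_solid
  expect_equal(min(ss), 418.7, tolerance = 1e-9)
  expect_equal(max(ss), 4882.7, tolerance = 1e-9)
  ds2 <- small_dataset(seed = 5, soluble_solid_range = c(100, 200))
  expect_equal(range(ds2$truth$soluble_solid), c(100, 200), tolerance = 1e-9)
})

test_that("kinetics trajectories are non-decreasing within each stage", {
  ds <- small_dataset(seed = 6, outliers = list(n = 0))
  for (b in unique(ds$truth$batch)) {
    for (s in unique(ds$truth$stage)) {
      tr <- ds$truth[ds$truth$batch == b & ds$truth$stage == s, ]
      tr <- tr[order(tr$minute), ]
      for (comp in c("danshensu", "soluble_solid")) {
        expect_true(all(diff(tr[[comp]]) >= -1e-9))
      }
    }
  }
})
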
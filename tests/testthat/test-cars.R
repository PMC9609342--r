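test_that("the EDF retention schedule is pinned at both endpoints", {
  for (p in c(50, 200, 1175)) {
    n_runs <- 50
    r <- edf_ratio(1:n_runs, p, n_runs)
    expect_equal(r[1], 1, tolerance = 1e-12)          # all p survive run 1
    expect_equal(r[n_runs], 2 / p, tolerance = 1e-12) # 2 survive run N
    expect_true(all(diff(r) < 0))                     # strictly decreasing
    # closed form a * exp(-k * i)
    a <- (p / 2)^(1 / (n_runs - 1))
    k <- log(p / 2) / (n_runs - 1)
    expect_equal(r, a * exp(-k * (1:n_runs)), tolerance = 1e-12)
  }
})

test_that("CARS recovers planted informative channels", {
  hits <- 0L
  for (s in 1:5) {
    fx <- linear_fixture(n = 264, seed = 100 + s)   # study-sized calibration
    sel <- suppressWarnings(cars_select(fx$X, fx$y, seed = s))
    if (all(fx$informative %in% sel$selected_indices)) hits <- hits + 1L
    expect_true(all(diff(sel$trace$n_variables) <= 0))
    expect_true(all(sel$selected_indices %in% seq_len(ncol(fx$X))))
    expect_false(is.unsorted(sel$selected_indices))
    expect_false(anyDuplicated(sel$selected_indices) > 0)
  }
  expect_gte(hits, 5L)
})

test_that("selection is bit-identical under a fixed seed", {
  fx <- linear_fixture(seed = 7)
  s1 <- cars_select(fx$X, fx$y, seed = 3)
  s2 <- cars_select(fx$X, fx$y, seed = 3)
  expect_identical(s1$selected_indices, s2$selected_indices)
  expect_identical(s1$trace, s2$trace)
})

test_that("a response independent of X behaves as a null", {
  set.seed(71)
  X <- matrix(runif(60 * 80), 60, 80)
  y <- rnorm(60)
  s1 <- suppressWarnings(cars_select(X, y, seed = 1))
  s2 <- suppressWarnings(cars_select(X, y, seed = 2))
  # best RMSECV is on the order of sd(y): nothing to model
  expect_gt(min(s1$trace$rmsecv), 0.6 * sd(y))
  expect_lt(min(s1$trace$rmsecv), 1.6 * sd(y))
  # and the selection is unstable across seeds
  jaccard <- length(intersect(s1$selected_indices, s2$selected_indices)) /
    length(union(s1$selected_indices, s2$selected_indices))
  expect_lt(jaccard, 0.5)
})

test_that("min_vars restricts the winning run, not the trace", {
  fx <- linear_fixture(seed = 8)
  sel <- suppressWarnings(cars_select(fx$X, fx$y, seed = 4, min_vars = 20L))
  expect_gte(length(sel$selected_indices), 20L)
  expect_gte(max(sel$trace$n_variables), 20L)
})

test_that("noiseless linear data: selected subset beats the full spectrum", {
  fx <- linear_fixture(n = 60, p = 120, noise = 0, seed = 9)
  sel <- suppressWarnings(cars_select(fx$X, fx$y, seed = 5))
  full_cv <- min(ramanqc:::pls_cv_safe(fx$X, fx$y, 10, folds = 5, seed = 1))
  sub_cv <- min(ramanqc:::pls_cv_safe(fx$X[, sel$selected_indices,
                                           drop = FALSE],
                                      fx$y, 10, folds = 5, seed = 1))
  expect_lte(sub_cv, full_cv + 1e-10)
})

test_that("configuration invariants are enforced", {
  expect_error(cars_config(mc_rate = 1.2), "mc_rate")
  expect_error(cars_config(n_runs = 1), "n_runs")
  fx <- linear_fixture(n = 20, p = 30, seed = 10)
  expect_error(cars_select(fx$X, fx$y[1:5]), "match")
})
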
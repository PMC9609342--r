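test_that("rmse agrees with hand-computed fixtures", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(91)
  a <- rnorm(10); b <- rnorm(10); perm <- sample(10)
  expect_equal(rmse(a[perm], b[perm]), rmse(a, b))
  expect_error(rmse(1:3, 1:4), "equal")
})

test_that("r_squared is a coefficient of determination", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_lt(r_squared(y, c(4, 3, 2, 1)), 0)   # can go negative
  expect_error(r_squared(rep(2, 4), y), "degenerate")
  expect_error(r_squared(1:3, 1:4), "equal")
})

test_that("cross-validation pools out-of-fold predictions reproducibly", {
  set.seed(92)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- as.vector(X %*% rnorm(6))
  cv1 <- cross_validate("plsr", X, y, folds = 5, seed = 3,
                        params = list(components = 6))
  cv2 <- cross_validate("plsr", X, y, folds = 5, seed = 3,
                        params = list(components = 6))
  expect_identical(cv1, cv2)
  # noiseless linear data: near-exact out-of-fold recovery
  expect_lt(cv1$rmsecv, 1e-6 * sd(y))
  expect_gt(cv1$rcv2, 1 - 1e-10)
  # leave-one-out runs and pools n predictions
  cv_loo <- cross_validate("plsr", X, y, folds = 40, seed = 3,
                           params = list(components = 6))
  expect_length(cv_loo$predictions, 40L)
  expect_length(cv_loo$fold_assignment, 40L)
  expect_error(cross_validate("plsr", X, y, folds = 41), "empty")
})

test_that("evaluate_model is definitional on the training split", {
  set.seed(93)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- as.vector(X %*% rnorm(8)) + rnorm(50, 0, 0.2)
  m <- fit_plsr(X, y, components = 8)
  row <- evaluate_model(m, X, y, X, y, seed = 2,
                        params = list(components = 8))
  # "validation" = training split reproduces Rc2/RMSEC exactly
  expect_equal(row$rp2, row$rc2, tolerance = 1e-12)
  expect_equal(row$rmsep, row$rmsec, tolerance = 1e-12)
  # every cell recomputes bit-for-bit from its stored prediction vector
  pv <- attr(row, "predictions")
  expect_identical(r_squared(y, pv$calibration), row$rc2)
  expect_identical(rmse(y, pv$calibration), row$rmsec)
  expect_identical(r_squared(y, pv$cross_validation), row$rcv2)
  expect_identical(rmse(y, pv$cross_validation), row$rmsecv)
  expect_identical(r_squared(y, pv$validation), row$rp2)
  expect_identical(rmse(y, pv$validation), row$rmsep)
})

test_that("evaluate_models fills the whole engines-by-attributes grid", {
  set.seed(94)
  n <- 60; p <- 30
  X <- matrix(runif(n * p), n, p)
  ytab <- data.frame(a1 = as.vector(X %*% rnorm(p)) + rnorm(n, 0, 0.1),
                     a2 = rowSums(X[, 1:5]) + rnorm(n, 0, 0.1))
  tr <- 1:45; te <- 46:60
  engines <- list(plsr = list(engine = "plsr"),
                  cars_plsr = list(engine = "plsr", selector = "cars"))
  rep_tab <- suppressWarnings(
    evaluate_models(engines, X[tr, ], ytab[tr, ], X[te, ], ytab[te, ],
                    seed = 5))
  expect_s3_class(rep_tab, "evaluation_report")
  expect_equal(nrow(rep_tab), 4L)           # 2 engines x 2 attributes
  expect_true(all(c("rc2", "rmsec", "rcv2", "rmsecv", "rp2", "rmsep") %in%
                    names(rep_tab)))
  expect_true(all(is.finite(as.matrix(
    rep_tab[, c("rc2", "rmsec", "rcv2", "rmsecv", "rp2", "rmsep")]))))
  expect_true(all(rep_tab$n_selected[rep_tab$model == "plsr"] == p))
  expect_true(all(rep_tab$n_selected[rep_tab$model == "cars_plsr"] < p))
  expect_error(
    evaluate_models(engines, X[tr, ], ytab[tr, ], X[te, ], ytab[te, ],
                    attributes = "missing_one"), "missing")
})
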
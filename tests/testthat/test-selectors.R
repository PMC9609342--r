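test_that("UVE keeps informative channels and kills dead ones", {
  fx <- linear_fixture(n = 60, p = 40, informative = c(5, 15, 25, 35, 40),
                       coefs = c(3, -2, 4, 1.5, -3), noise = 0.05, seed = 81)
  sel <- uve_select(fx$X, fx$y, n_noise = 40, seed = 2)
  expect_true(all(fx$informative %in% sel$selected_indices))
  dead <- setdiff(seq_len(40), fx$informative)
  expect_gte(mean(!dead %in% sel$selected_indices), 0.9)
  # the cutoff is definitional: every kept channel beats it
  expect_true(all(abs(sel$stability[sel$selected_indices]) > sel$cutoff))
  expect_gt(sel$cutoff, 0)
})

test_that("UVE error paths: too few noise channels, pure-noise input", {
  fx <- linear_fixture(n = 30, p = 20, seed = 82)
  expect_error(uve_select(fx$X, fx$y, n_noise = 5), "at least 10")
  # pure noise: (near-)empty selection -- either the empty-selection
  # error, or at most a couple of lucky channels beating the cutoff
  set.seed(83)
  X <- matrix(runif(40 * 20), 40, 20)
  y <- rnorm(40)
  res <- tryCatch(uve_select(X, y, n_noise = 200, seed = 3),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "removed every channel")
  } else {
    expect_lte(length(res$selected_indices), 2L)
  }
})

test_that("SPA never selects perfectly collinear channel pairs", {
  set.seed(84)
  X <- matrix(runif(50 * 12), 50, 12)
  X[, 7] <- 2.5 * X[, 3]                 # exact collinearity (centered too)
  y <- rowSums(X[, c(1, 3, 5)]) + rnorm(50, 0, 0.01)
  sel <- spa_select(X, y, max_vars = 6)
  expect_false(all(c(3, 7) %in% sel$selected_indices))
})

test_that("SPA chains on an orthogonal design follow descending norms", {
  # with orthogonal centered columns, projecting out a selected column
  # leaves the others untouched, so the chain is the norm ordering
  n <- 16
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:6]
  scales <- c(5, 9, 2, 7, 1, 4)
  X <- sweep(Q, 2, scales, `*`)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  chain <- ramanqc:::spa_chain(Xc, start = which.max(colSums(Xc^2)), 4,
                               seq_len(6))
  norms <- colSums(Xc^2)
  expect_equal(chain, order(norms, decreasing = TRUE)[1:4])
})

test_that("SPA's parsimonious subset beats an overfit full spectrum", {
  # low-rank smooth spectra: SPA's home turf (collinear channels), with
  # the full-spectrum MLR in its overfitting regime (p close to n)
  set.seed(85)
  n <- 100; p <- 60; k <- 5
  profiles <- t(sapply(1:k, function(j)
    exp(-0.5 * ((1:p - j * 10) / 4)^2)))
  conc <- matrix(runif(n * k, 0, 10), n, k)
  X <- conc %*% profiles + matrix(rnorm(n * p, 0, 0.01), n, p)
  y <- conc[, 3] + rnorm(n, 0, 0.05)
  tr <- 1:70; te <- 71:100
  sel <- spa_select(X[tr, ], y[tr], max_vars = 10)
  fit_sel <- stats::lm.fit(cbind(1, X[tr, sel$selected_indices,
                                      drop = FALSE]), y[tr])
  pred_sel <- cbind(1, X[te, sel$selected_indices, drop = FALSE]) %*%
    fit_sel$coefficients
  fit_full <- stats::lm.fit(cbind(1, X[tr, ]), y[tr])
  bf <- fit_full$coefficients; bf[is.na(bf)] <- 0
  pred_full <- cbind(1, X[te, ]) %*% bf
  expect_lte(rmse(y[te], pred_sel), rmse(y[te], pred_full))
  expect_gt(r_squared(y[te], pred_sel), 0.95)
  # zero-variance channels are excluded with a warning
  Xz <- X; Xz[, 5] <- 1
  expect_warning(spa_select(Xz[tr, ], y[tr], max_vars = 5),
                 "zero-variance")
})

test_that("siPLS finds the informative interval and degenerates sanely", {
  set.seed(86)
  hits <- 0L
  for (s in 1:5) {
    fx <- linear_fixture(n = 50, p = 60, informative = 25:27,
                         coefs = c(4, -3, 5), noise = 0.05, seed = 860 + s)
    sel <- sipls_select(fx$X, fx$y, n_intervals = 10, combo_sizes = 2,
                        seed = s)
    # informative channels 25:27 live in interval 5 (channels 25:30)
    if (5 %in% sel$best_combo) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
  # n_intervals = 1: the whole axis
  fx <- linear_fixture(n = 30, p = 20, seed = 87)
  sel1 <- sipls_select(fx$X, fx$y, n_intervals = 1, combo_sizes = 1, seed = 1)
  expect_equal(sel1$selected_indices, 1:20)
  # constant y: every combo ties; the first (lexicographic) wins
  selc <- sipls_select(fx$X, rep(1, 30), n_intervals = 4, combo_sizes = 2,
                       seed = 1)
  expect_equal(selc$best_run, 1L)
  expect_equal(selc$best_combo, c(1L, 2L))
  # combinatorial budget guard
  X_wide <- matrix(rnorm(20 * 60), 20, 60)
  expect_error(sipls_select(X_wide, rnorm(20), n_intervals = 50,
                            combo_sizes = 4, seed = 1), "budget")
})

test_that("compare_selectors ranks methods and repeats deterministically", {
  fx <- linear_fixture(n = 70, p = 50, informative = c(10, 25, 40),
                       coefs = c(4, -3, 5), noise = 0.05, seed = 88)
  tr <- 1:55; te <- 56:70
  tab <- suppressWarnings(compare_selectors(
    fx$X[tr, ], fx$y[tr], fx$X[te, ], fx$y[te],
    methods = c("cars", "cars", "sipls"), seed = 2,
    sipls = list(n_intervals = 10, combo_sizes = 2)))
  expect_equal(nrow(tab), 3L)
  expect_named(tab, c("method", "n_selected", "rp2", "rmsep"))
  # identical method listed twice -> identical rows
  cars_rows <- tab[tab$method == "cars", ]
  expect_equal(cars_rows[1, -1], cars_rows[2, -1], ignore_attr = TRUE)
  expect_true(all(diff(tab$rp2) <= 0))   # ranked by rp2
  # every selector beats a random equal-size baseline
  sel_best <- attr(tab, "selections")[[1]]
  set.seed(3)
  rnd <- sort(sample(50, length(sel_best$selected_indices)))
  m_rnd <- fit_plsr(fx$X[tr, rnd, drop = FALSE], fx$y[tr])
  rmsep_rnd <- rmse(fx$y[te], predict(m_rnd, fx$X[te, rnd, drop = FALSE]))
  expect_lte(min(tab$rmsep), rmsep_rnd)
  expect_error(compare_selectors(fx$X[tr, ], fx$y[tr], fx$X[te, ],
                                 fx$y[te], methods = "cars"), "at least 2")
})
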
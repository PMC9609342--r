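# Shared fixture builders; everything is generated in code, seeded.

# Sparse linear ground truth: y depends on `informative` of p channels.
linear_fixture <- function(n = 80, p = 200, informative = NULL,
                           coefs = c(3, -2, 4, 1.5, -3), noise = 0.05,
                           seed = 1) {
  if (is.null(informative)) {
    informative <- unique(pmax(1L, round(p * c(0.1, 0.3, 0.5, 0.7, 0.9))))
    coefs <- coefs[seq_along(informative)]
  }
  set.seed(seed)
  X <- matrix(stats::runif(n * p), n, p)
  w <- numeric(p)
  w[informative] <- coefs
  y <- as.vector(X %*% w) + stats::rnorm(n, 0, noise)
  list(X = X, y = y, informative = informative, w = w)
}

# Small smooth band spectrum on an axis (for preprocessing tests).
band_spectrum <- function(axis, centers = c(1000, 1250, 1500),
                          heights = c(1, 0.8, 0.6), width = 20) {
  y <- numeric(length(axis))
  for (j in seq_along(centers)) {
    y <- y + heights[j] * exp(-0.5 * ((axis - centers[j]) / width)^2)
  }
  y
}

# A small, fast synthetic dataset (coarse axis, few batches).
small_dataset <- function(seed = 1, n_batches = 2, by = 45.28, ...) {
  generate_dataset(n_batches = n_batches, axis = seq(176, 3500, by = by),
                   seed = seed, ...)
}

# Independent brute-force Savitzky-Golay oracle: explicit local
# least-squares polynomial fit at one interior channel.
savgol_oracle_point <- function(y, i, window, polyorder) {
  half <- (window - 1) %/% 2
  idx <- (i - half):(i + half)
  fit <- stats::lm(y[idx] ~ poly(seq_along(idx), polyorder, raw = TRUE))
  unname(stats::predict(fit)[half + 1])
}

# Independent brute-force Kennard-Stone: literal re-statement of the
# max-min rule with explicit loops.
ks_oracle <- function(X, n_cal) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  best <- c(1, 2); bd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand_best <- NA; cand_d <- -Inf
    for (i in setdiff(1:n, sel)) {
      di <- min(D[i, sel])
      if (di > cand_d) { cand_d <- di; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}
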
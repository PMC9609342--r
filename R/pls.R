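# Partial least squares regression by the SIMPLS algorithm (single
# response). SIMPLS extracts successive weight vectors maximizing the
# covariance of score and response under orthogonality of the score
# vectors; with as many components as the rank of X it reproduces the
# least-squares fit, which the tests use as an exactness oracle.

simpls_fit <- function(X, y, ncomp, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  X0 <- sweep(X, 2, x_mean)
  y0 <- y - y_mean
  S <- crossprod(X0, y0)
  scale0 <- sqrt(sum(S^2))
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  B <- matrix(0, p, ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t_sc <- X0 %*% r
    normt <- sqrt(sum(t_sc^2))
    if (!is.finite(normt) || normt <= tol * max(scale0, 1)) break
    t_sc <- t_sc / normt
    r <- r / normt
    p_l <- crossprod(X0, t_sc)
    Q[a] <- crossprod(y0, t_sc)[1]
    v <- p_l
    if (a > 1L) {
      Va <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Va %*% crossprod(Va, p_l)
    }
    nv <- sqrt(sum(v^2))
    if (nv <= tol) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    V[, a] <- v
    B[, a] <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
    a_used <- a
  }
  if (a_used == 0L) {
    stop("PLS failed: X carries no covariance with y", call. = FALSE)
  }
  list(coefs = B[, seq_len(a_used), drop = FALSE], x_mean = x_mean,
       y_mean = y_mean, ncomp = a_used)
}

# Predictions for every component count 1..fit$ncomp (n x ncomp matrix).
simpls_predict_all <- function(fit, X) {
  X0 <- sweep(as.matrix(X), 2, fit$x_mean)
  sweep(X0 %*% fit$coefs, 2, -fit$y_mean)
}

simpls_predict <- function(fit, X, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  simpls_predict_all(fit, X)[, ncomp]
}

# Seeded k-fold assignment, balanced fold sizes.
cv_folds <- function(n, folds, seed = NULL) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  # folds == n is leave-one-out; folds > n would leave empty folds
  if (n < folds) stop("more folds than samples (a fold would be empty)",
                      call. = FALSE)
  perm <- if (is.null(seed)) sample.int(n) else with_seed(seed, sample.int(n))
  split(perm, rep_len(seq_len(folds), n))
}

# Pooled out-of-fold RMSE of PLS for each component count 1..ncomp_max.
# Returns list(rmsecv = vector, press-style pooled predictions matrix).
pls_cv_rmse <- function(X, y, ncomp_max, folds = 5L, seed = NULL,
                        fold_idx = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(fold_idx)) fold_idx <- cv_folds(n, folds, seed)
  ncomp_max <- min(ncomp_max, ncol(X),
                   n - max(lengths(fold_idx)) - 1L)
  ncomp_max <- max(ncomp_max, 1L)
  pred <- matrix(NA_real_, n, ncomp_max)
  for (f in fold_idx) {
    fit <- simpls_fit(X[-f, , drop = FALSE], y[-f], ncomp_max)
    ph <- simpls_predict_all(fit, X[f, , drop = FALSE])
    pred[f, seq_len(fit$ncomp)] <- ph
    if (fit$ncomp < ncomp_max) {       # pad with the deepest available model
      pred[f, (fit$ncomp + 1L):ncomp_max] <- ph[, fit$ncomp]
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  list(rmsecv = rmsecv, predictions = pred, best = which.min(rmsecv))
}
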
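# Epsilon-insensitive support vector regression, solved exactly as the
# dual quadratic program with quadprog. Calibration sets here are a few
# hundred samples, so the dense 2n-variable QP is well within reach and
# avoids approximate SMO iterations.

svr_kernel <- function(X1, X2, kernel, gamma) {
  if (kernel == "linear") return(tcrossprod(X1, X2))
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

svr_solve <- function(K, y, cost, epsilon) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K))
  diag(H) <- diag(H) + 1e-8 * max(mean(diag(K)), 1)
  dvec <- c(y - epsilon, -y - epsilon)
  Amat <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), rep(-cost, 2 * n))
  sol <- quadprog::solve.QP(H, dvec, Amat, bvec, meq = 1)
  z <- sol$solution
  beta <- z[seq_len(n)] - z[n + seq_len(n)]
  f0 <- as.vector(K %*% beta)
  tol <- 1e-6 * cost
  free_lo <- z[seq_len(n)] > tol & z[seq_len(n)] < cost - tol
  free_hi <- z[n + seq_len(n)] > tol & z[n + seq_len(n)] < cost - tol
  b_vals <- c(y[free_lo] - f0[free_lo] - epsilon,
              y[free_hi] - f0[free_hi] + epsilon)
  b <- if (length(b_vals)) mean(b_vals) else mean(y - f0)
  list(beta = beta, b = b)
}

default_svr_grid <- function() {
  expand.grid(cost = c(1, 10, 100), gamma_scale = c(0.1, 1, 10),
              epsilon = c(0.01, 0.1))
}

#' Fit an epsilon-SVR calibration model
#'
#' Kernelized epsilon-insensitive regression; the hyperparameter grid is
#' searched by k-fold cross-validation (skipped when the grid has a
#' single row). Targets are z-scored internally and predictions
#' back-transformed. The RBF width is `gamma_scale / (p * mean channel
#' variance)`, the usual "scale" heuristic.
#'
#' @param X Calibration spectra (samples x channels), expected on the
#'   preprocessed [0, 1] scale.
#' @param y Reference values.
#' @param grid Data frame with columns `cost`, `gamma_scale`, `epsilon`.
#' @param kernel `"rbf"` (default) or `"linear"` (ignores `gamma_scale`).
#' @param cv_folds Folds for the grid search.
#' @param seed Integer seed for the fold assignment.
#' @return A `raman_model` (engine `"svr"`).
#' @export
fit_svr <- function(X, y, grid = default_svr_grid(),
                    kernel = c("rbf", "linear"), cv_folds = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in training data", call. = FALSE)
  }
  if (nrow(grid) < 1L) stop("hyperparameter grid is empty", call. = FALSE)
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (y_sd == 0) {                       # degenerate constant target
    model <- list(engine = "svr", constant = y_mean, n_channels = ncol(X),
                  training = list(predictions = rep(y_mean, length(y)),
                                  y = y))
    return(structure(model, class = "raman_model"))
  }
  ys <- (y - y_mean) / y_sd
  gamma0 <- 1 / (ncol(X) * max(mean(apply(X, 2, stats::var)), 1e-12))

  chosen <- grid[1, ]
  if (nrow(grid) > 1L) {
    fold_idx <- cv_folds(nrow(X), cv_folds, seed)
    cv_err <- vapply(seq_len(nrow(grid)), function(g) {
      gam <- gamma0 * grid$gamma_scale[g]
      pred <- numeric(nrow(X))
      for (f in fold_idx) {
        Ktr <- svr_kernel(X[-f, , drop = FALSE], X[-f, , drop = FALSE],
                          kernel, gam)
        fit <- svr_solve(Ktr, ys[-f], grid$cost[g], grid$epsilon[g])
        Kte <- svr_kernel(X[f, , drop = FALSE], X[-f, , drop = FALSE],
                          kernel, gam)
        pred[f] <- Kte %*% fit$beta + fit$b
      }
      sqrt(mean((pred - ys)^2))
    }, numeric(1))
    chosen <- grid[which.min(cv_err), ]
  }
  gam <- gamma0 * chosen$gamma_scale
  K <- svr_kernel(X, X, kernel, gam)
  fit <- svr_solve(K, ys, chosen$cost, chosen$epsilon)
  train_pred <- as.vector(K %*% fit$beta + fit$b) * y_sd + y_mean
  structure(list(engine = "svr", kernel = kernel, gamma = gam,
                 cost = chosen$cost, epsilon = chosen$epsilon,
                 beta = fit$beta, b = fit$b, X_train = X,
                 y_center = y_mean, y_scale = y_sd,
                 n_channels = ncol(X),
                 chosen = as.list(chosen),
                 training = list(predictions = train_pred, y = y)),
            class = "raman_model")
}

predict_svr <- function(model, X_new) {
  if (!is.null(model$constant)) {
    return(rep(model$constant, nrow(X_new)))
  }
  K <- svr_kernel(X_new, model$X_train, model$kernel, model$gamma)
  as.vector(K %*% model$beta + model$b) * model$y_scale + model$y_center
}
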
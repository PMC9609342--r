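# Competitive adaptive reweighted sampling (CARS): Monte-Carlo wavelength
# selection for PLS calibration. Each sampling run fits a PLS model on a
# random subset of calibration samples, keeps the top fraction of
# variables by absolute regression coefficient following an exponentially
# decreasing schedule (fast screening early, fine screening late), then
# resamples survivors with probability proportional to |coefficient|
# (adaptive reweighted sampling). The subset whose cross-validated RMSE is
# smallest over all runs wins.

#' CARS configuration
#'
#' @param n_runs Number of Monte-Carlo sampling runs (default 50).
#' @param mc_rate Fraction of calibration samples drawn per run
#'   (default 0.8).
#' @param cv_folds Cross-validation folds for RMSECV scoring (default 5).
#' @param max_components Cap on PLS latent variables (default 10); the
#'   count actually used in each fit is chosen by inner cross-validation.
#' @return A `cars_config` list.
#' @export
cars_config <- function(n_runs = 50L, mc_rate = 0.8, cv_folds = 5L,
                        max_components = 10L) {
  if (mc_rate <= 0 || mc_rate >= 1) stop("mc_rate must be in (0, 1)",
                                         call. = FALSE)
  if (n_runs < 2L) stop("n_runs must be at least 2", call. = FALSE)
  structure(list(n_runs = as.integer(n_runs), mc_rate = mc_rate,
                 cv_folds = as.integer(cv_folds),
                 max_components = as.integer(max_components)),
            class = "cars_config")
}

#' Exponentially decreasing retention ratio
#'
#' Fraction of the `p` variables retained at run `i` of `n_runs`:
#' `r_i = a * exp(-k * i)` with the endpoints pinned so that all `p`
#' variables survive run 1 and exactly 2 survive run `n_runs`
#' (`a = (p/2)^(1/(n_runs-1))`, `k = log(p/2)/(n_runs-1)`).
#'
#' @param i Run index (vectorized).
#' @param p Total number of variables.
#' @param n_runs Total number of runs.
#' @return Retention ratio(s) in (0, 1].
#' @export
edf_ratio <- function(i, p, n_runs) {
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * i)
}

#' CARS wavelength selection
#'
#' @param X Calibration spectra (samples x channels).
#' @param y Reference values for one attribute.
#' @param config A [cars_config()].
#' @param seed Integer seed; the whole selection is reproducible from it.
#' @param min_vars Only runs that kept at least this many variables are
#'   eligible as the winning subset (default 2). Downstream models with a
#'   minimum input size -- the CNN needs its receptive field -- set this
#'   higher; the trace still records every run.
#' @return A `selection_result`: `selected_indices` (sorted channel
#'   indices of the best run), `method`, `trace` (per-run variable count
#'   and RMSECV), `best_run`, `subsets` (per-run index lists), `seed`.
#' @export
cars_select <- function(X, y, config = cars_config(), seed = 1L,
                        min_vars = 2L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("X rows must match length(y)", call. = FALSE)
  if (n < config$cv_folds) stop("need at least `cv_folds` samples",
                                call. = FALSE)
  m <- ceiling(config$mc_rate * n)
  N <- config$n_runs

  with_seed(seed, {
    fold_idx <- cv_folds(n, config$cv_folds)   # shared across runs
    live <- seq_len(p)
    subsets <- vector("list", N)
    counts <- integer(N)
    rmsecv <- rep(NA_real_, N)
    truncated <- FALSE
    runs_done <- 0L
    for (i in seq_len(N)) {
      rows <- sample.int(n, m)
      ncomp <- min(config$max_components, length(live), m - 2L)
      b <- mc_pls_coefs(X[rows, live, drop = FALSE], y[rows], ncomp,
                        config$cv_folds)
      w <- abs(b)
      keep <- min(length(live), max(2L, round(edf_ratio(i, p, N) * p)))
      ord <- order(w, decreasing = TRUE)
      forced <- ord[seq_len(keep)]
      # Adaptive reweighted sampling: weighted draw with replacement among
      # the forced survivors; unique picks form the new live set.
      if (sum(w[forced]) <= 0) {
        draws <- forced
      } else {
        draws <- sample(forced, keep, replace = TRUE, prob = w[forced])
      }
      new_live <- live[sort(unique(draws))]
      if (length(new_live) < 2L) {
        warning(sprintf("CARS subset collapsed below 2 variables at run %d; %s",
                        i, "returning best subset so far"), call. = FALSE)
        truncated <- TRUE
        break
      }
      live <- new_live
      cvr <- pls_cv_safe(X[, live, drop = FALSE], y,
                         min(config$max_components, length(live)),
                         fold_idx = fold_idx)
      subsets[[i]] <- live
      counts[i] <- length(live)
      rmsecv[i] <- min(cvr)
      runs_done <- i
    }
    if (runs_done == 0L) stop("CARS made no complete run", call. = FALSE)
    trace <- data.frame(run = seq_len(runs_done),
                        n_variables = counts[seq_len(runs_done)],
                        rmsecv = rmsecv[seq_len(runs_done)])
    eligible <- trace$n_variables >= min_vars
    if (!any(eligible)) {
      warning(sprintf("no CARS run kept >= %d variables; using all runs",
                      min_vars), call. = FALSE)
      eligible <- rep(TRUE, nrow(trace))
    }
    best <- which(eligible)[which.min(trace$rmsecv[eligible])]
    structure(list(selected_indices = subsets[[best]],
                   method = "cars",
                   trace = trace,
                   best_run = best,
                   subsets = subsets[seq_len(runs_done)],
                   truncated = truncated,
                   config = config,
                   seed = seed),
              class = "selection_result")
  })
}

# PLS regression coefficients on a Monte-Carlo subset, latent-variable
# count chosen by inner CV (falls back to the deepest fit that converged).
mc_pls_coefs <- function(X, y, ncomp_max, folds) {
  ncomp_max <- max(1L, ncomp_max)
  best <- tryCatch({
    cvr <- pls_cv_rmse(X, y, ncomp_max, folds = folds)
    cvr$best
  }, error = function(e) ncomp_max)
  fit <- simpls_fit(X, y, ncomp_max)
  fit$coefs[, min(best, fit$ncomp)]
}

# RMSECV per component count; mean-predictor fallback when PLS cannot fit
# (e.g. constant y), so callers always get a comparable score.
pls_cv_safe <- function(X, y, ncomp_max, folds = 5L, seed = NULL,
                        fold_idx = NULL) {
  tryCatch(pls_cv_rmse(X, y, ncomp_max, folds = folds, seed = seed,
                       fold_idx = fold_idx)$rmsecv,
           error = function(e) {
             if (is.null(fold_idx)) fold_idx <- cv_folds(length(y), folds, seed)
             pred <- numeric(length(y))
             for (f in fold_idx) pred[f] <- mean(y[-f])
             sqrt(mean((pred - y)^2))
           })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d channels selected", x$method,
              length(x$selected_indices)))
  if (!is.null(x$best_run)) cat(sprintf(" (best run %d)", x$best_run))
  if (!is.null(x$trace$rmsecv)) {
    cat(sprintf(", RMSECV %.4g", min(x$trace$rmsecv, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}
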
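# Comparison wavelength selectors: uninformative variable elimination
# (UVE), the successive projections algorithm (SPA), and synergy-interval
# PLS (siPLS). All return the same `selection_result` shape as CARS so
# they can be benchmarked by a common downstream model.

#' Uninformative variable elimination
#'
#' Augments the spectra with `n_noise` artificial random channels, fits a
#' PLS model under leave-one-out resampling, and computes per-variable
#' stability `mean(b) / sd(b)` of the regression coefficients. Real
#' channels whose |stability| does not exceed the largest |stability|
#' among the noise channels are deemed uninformative and removed.
#'
#' @param X Calibration spectra (samples x channels).
#' @param y Reference values.
#' @param n_noise Number of artificial noise channels (default
#'   `ncol(X)`, at least 10).
#' @param noise_amplitude Scale of the noise channels; kept tiny so they
#'   do not perturb the fit (default 1e-10).
#' @param max_components Cap on PLS latent variables.
#' @param cv_folds Folds for the RMSECV reported in the trace.
#' @param seed Integer seed.
#' @return A `selection_result` with `stability` and `cutoff` fields.
#' @export
uve_select <- function(X, y, n_noise = ncol(X), noise_amplitude = 1e-10,
                       max_components = 10L, cv_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n_noise < 10L) stop("n_noise must be at least 10", call. = FALSE)
  with_seed(seed, {
    noise <- matrix(stats::runif(n * n_noise), n, n_noise) * noise_amplitude
    A <- cbind(X, noise)
    ncomp <- min(max_components, p, n - 2L)
    coefs <- matrix(0, n, p + n_noise)
    for (i in seq_len(n)) {                      # leave-one-out
      fit <- simpls_fit(A[-i, , drop = FALSE], y[-i], ncomp)
      coefs[i, ] <- fit$coefs[, fit$ncomp]
    }
    mu <- colMeans(coefs)
    sdev <- apply(coefs, 2, stats::sd)
    stability <- ifelse(sdev > 0, mu / sdev, 0)
    cutoff <- max(abs(stability[(p + 1L):(p + n_noise)]))
    selected <- which(abs(stability[seq_len(p)]) > cutoff)
    if (!length(selected)) {
      stop("UVE removed every channel: no variable beats the noise cutoff",
           call. = FALSE)
    }
    rmsecv <- min(pls_cv_safe(X[, selected, drop = FALSE], y,
                              min(max_components, length(selected)),
                              folds = cv_folds, seed = seed))
    structure(list(selected_indices = selected, method = "uve",
                   trace = data.frame(run = 1L,
                                      n_variables = length(selected),
                                      rmsecv = rmsecv),
                   best_run = 1L,
                   stability = stability[seq_len(p)], cutoff = cutoff,
                   seed = seed),
              class = "selection_result")
  })
}

#' Successive projections algorithm
#'
#' Builds minimally collinear variable chains: starting from each
#' candidate channel, repeatedly appends the channel whose component
#' orthogonal to the span of the chain is largest. Chains of every length
#' up to `max_vars` are scored by multiple linear regression RMSE on an
#' internal Kennard-Stone validation split; the minimal-RMSE chain wins.
#'
#' @param X Calibration spectra.
#' @param y Reference values.
#' @param max_vars Maximum chain length (default 25; must be below
#'   `min(n_samples, n_channels)`).
#' @param n_starts Number of starting channels tried (all channels when
#'   `p <= n_starts`, otherwise evenly spaced; default 100).
#' @param val_fraction Fraction of samples held out (by Kennard-Stone on
#'   the remainder) for chain scoring (default 0.25).
#' @return A `selection_result`; the trace rows are the scored chains.
#' @export
spa_select <- function(X, y, max_vars = 25L, n_starts = 100L,
                       val_fraction = 0.25) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (max_vars >= min(n, p)) {
    stop("max_vars must be below min(n_samples, n_channels)", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  dead <- which(sds == 0)
  if (length(dead)) {
    warning(sprintf("excluding %d zero-variance channel(s)", length(dead)),
            call. = FALSE)
  }
  candidates <- setdiff(seq_len(p), dead)
  if (length(candidates) <= max_vars) {
    stop("too few non-degenerate channels for the requested chain length",
         call. = FALSE)
  }
  starts <- if (length(candidates) <= n_starts) candidates else
    candidates[unique(round(seq(1, length(candidates),
                                length.out = n_starts)))]

  ks <- kennard_stone_split(X, ratio = (1 - val_fraction) / val_fraction)
  tr <- match(ks$calibration_ids, rownames(X) %||% as.character(seq_len(n)))
  va <- match(ks$validation_ids, rownames(X) %||% as.character(seq_len(n)))

  Xc <- scale(X, center = TRUE, scale = FALSE)    # projections on centered data
  best <- list(rmse = Inf, chain = NULL)
  trace_rows <- vector("list", length(starts))
  for (s_i in seq_along(starts)) {
    chain <- spa_chain(Xc, starts[s_i], max_vars, candidates)
    rmses <- rep(NA_real_, length(chain))
    for (l in seq_along(chain)) {
      vars <- chain[seq_len(l)]
      fit <- stats::lm.fit(cbind(1, X[tr, vars, drop = FALSE]), y[tr])
      pred <- cbind(1, X[va, vars, drop = FALSE]) %*% fit$coefficients
      rmses[l] <- sqrt(mean((pred - y[va])^2))
    }
    l_best <- which.min(rmses)
    trace_rows[[s_i]] <- data.frame(run = s_i, n_variables = l_best,
                                    rmsecv = rmses[l_best])
    if (rmses[l_best] < best$rmse) {
      best <- list(rmse = rmses[l_best], chain = chain[seq_len(l_best)])
    }
  }
  trace <- do.call(rbind, trace_rows)
  structure(list(selected_indices = sort(best$chain), method = "spa",
                 trace = trace, best_run = which.min(trace$rmsecv)),
            class = "selection_result")
}

# One SPA chain: successive orthogonal projections from `start`.
spa_chain <- function(Xc, start, max_vars, candidates) {
  P <- Xc[, candidates, drop = FALSE]
  local <- match(start, candidates)
  chain_local <- local
  for (step in seq_len(max_vars - 1L)) {
    xj <- P[, chain_local[length(chain_local)]]
    nj <- sum(xj^2)
    if (nj <= 1e-300) break
    P <- P - xj %*% (crossprod(xj, P) / nj)
    norms <- colSums(P^2)
    norms[chain_local] <- -Inf
    nxt <- which.max(norms)
    if (norms[nxt] <= 1e-12 * max(colSums(Xc[, candidates, drop = FALSE]^2))) {
      break                                    # remaining channels collinear
    }
    chain_local <- c(chain_local, nxt)
  }
  candidates[chain_local]
}

#' Synergy-interval PLS
#'
#' Splits the axis into `n_intervals` contiguous intervals (nearly equal
#' length; the last absorbs the remainder) and exhaustively scores every
#' combination of `combo_sizes` intervals by PLS RMSECV, returning the
#' channels of the best combination. With `n_intervals = 1` the selection
#' is the full axis. Ties are broken by the first combination in
#' lexicographic order.
#'
#' @param X Calibration spectra.
#' @param y Reference values.
#' @param n_intervals Number of intervals (default 20).
#' @param combo_sizes Combination sizes to score (default `2:3`; sizes
#'   must lie in 1..4).
#' @param max_components Cap on PLS latent variables.
#' @param cv_folds Cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return A `selection_result`; `trace` holds one row per combination.
#' @export
sipls_select <- function(X, y, n_intervals = 20L, combo_sizes = 2:3,
                         max_components = 10L, cv_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L || n_intervals > p) {
    stop("n_intervals must be between 1 and the channel count", call. = FALSE)
  }
  if (any(combo_sizes < 1L) || any(combo_sizes > 4L)) {
    stop("combo_sizes must lie in 1..4", call. = FALSE)
  }
  bounds <- floor(seq(0, p, length.out = n_intervals + 1L))
  intervals <- lapply(seq_len(n_intervals),
                      function(k) (bounds[k] + 1L):bounds[k + 1L])
  combo_sizes <- combo_sizes[combo_sizes <= n_intervals]
  if (!length(combo_sizes)) combo_sizes <- n_intervals
  combos <- unlist(lapply(sort(combo_sizes), function(s)
    utils::combn(n_intervals, s, simplify = FALSE)), recursive = FALSE)
  if (length(combos) > 1e5) {
    stop("combinatorial budget exceeded (> 1e5 interval combinations)",
         call. = FALSE)
  }
  fold_idx <- cv_folds(nrow(X), cv_folds, seed)
  scores <- vapply(combos, function(cmb) {
    vars <- unlist(intervals[cmb])
    min(pls_cv_safe(X[, vars, drop = FALSE], y,
                    min(max_components, length(vars)), fold_idx = fold_idx))
  }, numeric(1))
  best <- which.min(scores)          # first minimum = lexicographic tie-break
  trace <- data.frame(run = seq_along(combos),
                      n_variables = vapply(combos, function(cmb)
                        length(unlist(intervals[cmb])), integer(1)),
                      rmsecv = scores)
  structure(list(selected_indices = sort(unlist(intervals[combos[[best]]])),
                 method = "sipls", trace = trace, best_run = best,
                 intervals = intervals, best_combo = combos[[best]],
                 seed = seed),
            class = "selection_result")
}

#' Benchmark variable selectors with a common downstream model
#'
#' Runs each requested selector on the calibration data, fits a common
#' PLSR model on the selected channels, and reports held-out performance,
#' ranked by validation R-squared.
#'
#' @param X,y Calibration spectra and reference values.
#' @param X_val,y_val Validation spectra and reference values.
#' @param methods Selectors to compare (subset of
#'   `c("cars", "uve", "spa", "sipls")`; duplicates allowed).
#' @param seed Integer seed shared by all selectors.
#' @param cars,uve,spa,sipls Optional argument lists overriding each
#'   selector's defaults.
#' @return Data frame: `method`, `n_selected`, `rp2`, `rmsep`, ordered by
#'   decreasing `rp2`, with the `selection_result`s attached as the
#'   `selections` attribute.
#' @export
compare_selectors <- function(X, y, X_val, y_val,
                              methods = c("cars", "uve", "spa", "sipls"),
                              seed = 1L, cars = list(), uve = list(),
                              spa = list(), sipls = list()) {
  if (length(methods) < 2L) stop("need at least 2 methods", call. = FALSE)
  X <- as.matrix(X)
  X_val <- as.matrix(X_val)
  selections <- vector("list", length(methods))
  rows <- vector("list", length(methods))
  for (i in seq_along(methods)) {
    sel <- switch(methods[i],
      cars = do.call(cars_select,
                     c(list(X = X, y = y, seed = seed), cars)),
      uve = do.call(uve_select, c(list(X = X, y = y, seed = seed), uve)),
      spa = do.call(spa_select, c(list(X = X, y = y), spa)),
      sipls = do.call(sipls_select,
                      c(list(X = X, y = y, seed = seed), sipls)),
      stop(sprintf("unknown selector '%s'", methods[i]), call. = FALSE))
    idx <- sel$selected_indices
    model <- fit_plsr(X[, idx, drop = FALSE], y, seed = seed)
    pred <- predict(model, X_val[, idx, drop = FALSE])
    rows[[i]] <- data.frame(method = methods[i], n_selected = length(idx),
                            rp2 = r_squared(y_val, pred),
                            rmsep = rmse(y_val, pred))
    selections[[i]] <- sel
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$rp2)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "selections") <- selections[ord]
  out
}
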
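# Common calibration-model contract: every engine (PLSR, SVR, CNN)
# returns a `raman_model` whose predict() accepts spectra on the training
# channel grid, so one evaluation harness serves all engines.

#' Fit a PLSR calibration model
#'
#' SIMPLS partial least squares; the latent-variable count is chosen by
#' minimal cross-validated RMSE.
#'
#' @param X Calibration spectra (samples x channels).
#' @param y Reference values.
#' @param max_components Cap on latent variables (default 10).
#' @param cv_folds Folds for component selection.
#' @param seed Integer seed for the fold assignment.
#' @param components Force this latent-variable count, skipping the CV
#'   choice (optional).
#' @return A `raman_model` (engine `"plsr"`).
#' @export
fit_plsr <- function(X, y, max_components = 10L, cv_folds = 5L, seed = 1L,
                     components = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (stats::sd(y) == 0) {
    stop("degenerate target: y is constant", call. = FALSE)
  }
  max_components <- min(max_components, ncol(X), nrow(X) - 1L)
  ncomp <- if (!is.null(components)) {
    min(as.integer(components), max_components)
  } else if (max_components > 1L && nrow(X) >= 2L * cv_folds) {
    cvr <- pls_cv_rmse(X, y, max_components, folds = cv_folds, seed = seed)
    cvr$best
  } else {
    max_components
  }
  fit <- simpls_fit(X, y, max_components)
  ncomp <- min(ncomp, fit$ncomp)
  train_pred <- simpls_predict(fit, X, ncomp)
  structure(list(engine = "plsr", fit = fit, ncomp = ncomp,
                 n_channels = ncol(X),
                 training = list(predictions = train_pred, y = y)),
            class = "raman_model")
}

#' Predict from a calibration model
#'
#' @param object A `raman_model` from [fit_plsr()], [fit_svr()] or
#'   [fit_cnn()].
#' @param newdata Spectra on the training channel grid (matrix or
#'   [raman_spectra]); if the model carries `selected_indices`, full-grid
#'   spectra are subset automatically.
#' @param ... Unused.
#' @return Numeric vector of predictions, named by sample id when
#'   available.
#' @export
predict.raman_model <- function(object, newdata, ...) {
  ids <- NULL
  if (inherits(newdata, "raman_spectra")) {
    ids <- newdata$sample_ids
    newdata <- newdata$intensities
  }
  newdata <- as.matrix(newdata)
  if (!is.null(object$selected_indices) &&
      ncol(newdata) != object$n_channels) {
    newdata <- newdata[, object$selected_indices, drop = FALSE]
  }
  if (ncol(newdata) != object$n_channels) {
    stop(sprintf("axis mismatch: model expects %d channels, got %d",
                 object$n_channels, ncol(newdata)), call. = FALSE)
  }
  pred <- switch(object$engine,
    plsr = simpls_predict(object$fit, newdata, object$ncomp),
    svr = predict_svr(object, newdata),
    cnn = predict_cnn(object, newdata),
    stop(sprintf("unknown engine '%s'", object$engine), call. = FALSE))
  if (!is.null(ids)) names(pred) <- ids
  pred
}

#' @export
print.raman_model <- function(x, ...) {
  extra <- switch(x$engine,
    plsr = sprintf(", %d latent variables", x$ncomp),
    svr = if (is.null(x$constant))
      sprintf(", cost %g, epsilon %g", x$cost, x$epsilon) else " (constant)",
    cnn = sprintf(", %d parameters, %d epochs", x$graph$n_parameters,
                  length(x$history)),
    "")
  cat(sprintf("<raman_model> %s on %d channels%s\n", x$engine, x$n_channels,
              extra))
  invisible(x)
}

# Engine dispatcher used by the evaluation harness and the pipeline.
# `engine` is one of "plsr", "svr", "cnn"; `params` are engine arguments.
fit_engine <- function(engine, X, y, params = list(), seed = 1L) {
  switch(engine,
    plsr = do.call(fit_plsr, c(list(X = X, y = y, seed = seed), params)),
    svr = do.call(fit_svr, c(list(X = X, y = y, seed = seed), params)),
    cnn = do.call(fit_cnn, c(list(X = X, y = y, seed = seed), params)),
    stop(sprintf("unknown engine '%s'", engine), call. = FALSE))
}
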
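# Performance figures: RMSE and the coefficient of determination on the
# calibration set (RMSEC, Rc2), under k-fold cross-validation (RMSECV,
# Rcv2) and on the external validation set (RMSEP, Rp2) -- the six
# numbers a calibration-transfer table reports per model per attribute.

#' Root mean square error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    stop("y_true and y_pred must have equal, positive length", call. = FALSE)
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. Unlike a squared correlation this can be
#' negative, when the model predicts worse than the mean of the
#' observations.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_true` must not
#'   be constant.
#' @return A value `<= 1`.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    stop("y_true and y_pred must have equal, positive length", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("degenerate target: y_true is constant", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Cross-validated performance of an engine
#'
#' Refits the engine on each training fold, pools the out-of-fold
#' predictions, and computes RMSECV and Rcv2 on the pool. The fold
#' assignment is seeded and returned, so the split is reproducible.
#'
#' @param engine `"plsr"`, `"svr"` or `"cnn"`.
#' @param X,y Calibration data.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (folds and per-fold engine seeds derive from
#'   it).
#' @param params Engine arguments passed to each fold's fit.
#' @return List: `rcv2`, `rmsecv`, `predictions` (pooled out-of-fold),
#'   `fold_assignment`.
#' @export
cross_validate <- function(engine, X, y, folds = 5L, seed = 1L,
                           params = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  fold_idx <- cv_folds(n, folds, seed)
  pred <- numeric(n)
  for (k in seq_along(fold_idx)) {
    f <- fold_idx[[k]]
    model <- fit_engine(engine, X[-f, , drop = FALSE], y[-f], params,
                        seed = seed + k)
    pred[f] <- predict(model, X[f, , drop = FALSE])
  }
  list(rcv2 = r_squared(y, pred), rmsecv = rmse(y, pred),
       predictions = pred, fold_assignment = fold_idx)
}

#' Evaluate a fitted model on a calibration/validation split
#'
#' Produces one row of the comparison table: Rc2/RMSEC from the stored
#' training predictions, Rcv2/RMSECV by refitting under cross-validation,
#' and Rp2/RMSEP on the validation set. The prediction vectors behind
#' every cell are attached so each figure is traceable.
#'
#' @param model A fitted `raman_model`.
#' @param engine Engine label used for the CV refits (defaults to
#'   `model$engine`).
#' @param X_cal,y_cal Calibration spectra and reference values (those the
#'   model was fitted on).
#' @param X_val,y_val Validation spectra and reference values.
#' @param cv_folds Folds for RMSECV (default 5).
#' @param seed Integer seed for the CV fold assignment.
#' @param params Engine arguments for the CV refits.
#' @return One-row data frame `rc2, rmsec, rcv2, rmsecv, rp2, rmsep` with
#'   attribute `predictions` (list of the three prediction vectors).
#' @export
evaluate_model <- function(model, X_cal, y_cal, X_val, y_val,
                           engine = model$engine, cv_folds = 5L, seed = 1L,
                           params = list()) {
  cal_pred <- model$training$predictions
  cv <- cross_validate(engine, X_cal, y_cal, folds = cv_folds, seed = seed,
                       params = params)
  val_pred <- predict(model, X_val)
  row <- data.frame(
    rc2 = r_squared(y_cal, cal_pred), rmsec = rmse(y_cal, cal_pred),
    rcv2 = cv$rcv2, rmsecv = cv$rmsecv,
    rp2 = r_squared(y_val, val_pred), rmsep = rmse(y_val, val_pred))
  attr(row, "predictions") <- list(calibration = cal_pred,
                                   cross_validation = cv$predictions,
                                   validation = val_pred)
  row
}

#' Build a full engines-by-attributes comparison report
#'
#' For every engine/attribute pair: optional variable selection on the
#' calibration set, engine fit, and the six performance figures via
#' [evaluate_model()]. The result is the familiar comparison-table shape,
#' one row per (engine, attribute).
#'
#' @param engines Named list of engine definitions, each a list with
#'   `engine` (`"plsr" | "svr" | "cnn"`), optional `selector`
#'   (`"cars" | "uve" | "spa" | "sipls"`), optional `selector_params` and
#'   `params`.
#' @param X_cal,X_val Calibration/validation spectra (matrices on a
#'   common grid).
#' @param y_cal,y_val Data frames of reference values (one column per
#'   attribute) aligned with the spectra rows.
#' @param attributes Attribute names (default: columns of `y_cal`).
#' @param cv_folds Folds for RMSECV.
#' @param seed Integer seed.
#' @return An `evaluation_report` data frame: `model`, `attribute`,
#'   `n_selected`, and the six figures; fitted models and selections are
#'   attached as attributes.
#' @export
evaluate_models <- function(engines, X_cal, y_cal, X_val, y_val,
                            attributes = colnames(y_cal), cv_folds = 5L,
                            seed = 1L) {
  X_cal <- as.matrix(X_cal)
  X_val <- as.matrix(X_val)
  rows <- list()
  models <- list()
  selections <- list()
  for (eng_name in names(engines)) {
    eng <- engines[[eng_name]]
    for (attr_name in attributes) {
      if (!attr_name %in% colnames(y_cal)) {
        stop(sprintf("attribute '%s' missing from reference table",
                     attr_name), call. = FALSE)
      }
      y_c <- y_cal[[attr_name]]
      y_v <- y_val[[attr_name]]
      idx <- seq_len(ncol(X_cal))
      sel <- NULL
      if (!is.null(eng$selector)) {
        sel_params <- eng$selector_params %||% list()
        if (identical(eng$engine, "cnn") &&
            identical(eng$selector, "cars") && is.null(sel_params$min_vars)) {
          sel_params$min_vars <- 20L        # CNN receptive field + margin
        }
        sel <- run_selector(eng$selector, X_cal, y_c, sel_params, seed)
        idx <- sel$selected_indices
      }
      params <- eng$params %||% list()
      if (identical(eng$engine, "cnn")) {
        spec_args <- c(list(attribute = attr_name),
                       params$spec_args %||% list())
        params$spec <- do.call(cnn_spec, spec_args)
        params$spec_args <- NULL
      }
      model <- fit_engine(eng$engine, X_cal[, idx, drop = FALSE], y_c,
                          params, seed = seed)
      model$attribute <- attr_name
      model$selected_indices <- idx
      row <- evaluate_model(model, X_cal[, idx, drop = FALSE], y_c,
                            X_val[, idx, drop = FALSE], y_v,
                            cv_folds = cv_folds, seed = seed,
                            params = params)
      key <- paste(eng_name, attr_name, sep = ".")
      rows[[key]] <- cbind(data.frame(model = eng_name,
                                      attribute = attr_name,
                                      n_selected = length(idx)), row)
      models[[key]] <- model
      selections[[key]] <- sel
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(report, models = models, selections = selections,
            cv_folds = cv_folds, seed = seed,
            class = c("evaluation_report", "data.frame"))
}

run_selector <- function(selector, X, y, params, seed) {
  switch(selector,
    cars = do.call(cars_select, c(list(X = X, y = y, seed = seed), params)),
    uve = do.call(uve_select, c(list(X = X, y = y, seed = seed), params)),
    spa = do.call(spa_select, c(list(X = X, y = y), params)),
    sipls = do.call(sipls_select, c(list(X = X, y = y, seed = seed), params)),
    stop(sprintf("unknown selector '%s'", selector), call. = FALSE))
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("<evaluation_report> %d rows (%d models x attributes)\n",
              nrow(x), length(unique(x$model))))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
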
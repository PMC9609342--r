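# End-to-end orchestration: simulate (or load) -> preprocess -> screen ->
# split -> select -> train -> evaluate, from a single config, with every
# artifact written to a run directory and tied to the config and seed by
# a hashed manifest.

#' Default pipeline configuration
#'
#' The stated world of the synthetic study: 7 batches on the three-stage
#' reflux schedule (335 samples after the dropped final slot), triplicate
#' acquisitions, 5 planted gross outliers, the 1175-channel instrument
#' axis, S-G window 11 / order 3, mean + 3 sd Mahalanobis screening on
#' auto-chosen PCA scores, a 4:1 Kennard-Stone split, 5-fold CV, and four
#' engines: SPA-SVR, CARS-PLSR, full-spectrum CNN, CARS-CNN.
#'
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_batches = 7L, replicates = 3L, drop_last = TRUE),
    preprocess = list(window = 11L, polyorder = 3L),
    screen = list(rule = "mean3sd", k = 3, n_scores = "auto"),
    split = list(ratio = 4),
    cv_folds = 5L,
    attributes = c("danshensu", "ferulic_acid", "rosmarinic_acid",
                   "salvianolic_acid_B", "soluble_solid"),
    engines = list(
      spa_svr = list(engine = "svr", selector = "spa"),
      cars_plsr = list(engine = "plsr", selector = "cars"),
      cnn = list(engine = "cnn"),
      cars_cnn = list(engine = "cnn", selector = "cars")
    )
  )
}

#' Read a pipeline configuration file
#'
#' JSON always; YAML when the `yaml` package is installed. Unknown
#' top-level keys are rejected.
#'
#' @param path Config file (`.json`, `.yaml` or `.yml`).
#' @return Validated configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

#' Validate and complete a pipeline configuration
#'
#' @param config Partial configuration list; missing blocks are filled
#'   from [default_config()].
#' @return The completed configuration.
#' @export
validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), c(names(base), "input"))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(base, config)
  if ("engines" %in% names(config)) cfg$engines <- config$engines
  if (!length(cfg$engines)) {
    stop("config error: `engines` must name at least one engine",
         call. = FALSE)
  }
  for (nm in names(cfg$engines)) {
    eng <- cfg$engines[[nm]]
    if (is.null(eng$engine) || !eng$engine %in% c("plsr", "svr", "cnn")) {
      stop(sprintf("config error: engine '%s' must set engine to %s", nm,
                   "plsr, svr or cnn"), call. = FALSE)
    }
  }
  if (!length(cfg$attributes)) {
    stop("config error: `attributes` must not be empty", call. = FALSE)
  }
  cfg
}

#' Run the full calibration study
#'
#' Executes simulate (or load) -> preprocess -> screen -> split ->
#' select/train/evaluate from one configuration. Every stage's effective
#' parameters go to the run log; all artifacts are written under
#' `out_dir` and listed, with content hashes, in `manifest.json`. Reruns
#' with the same config and seed are bit-identical.
#'
#' @param config Configuration list (see [default_config()]) or a path
#'   accepted by [read_config()].
#' @param out_dir Run directory (created; must be empty or absent).
#' @return Invisibly, a list: `report` (the [evaluate_models()] table),
#'   `screening`, `split`, `dataset`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.json")
  log_entries <- list()
  log_stage <- function(stage, params) {
    log_entries[[stage]] <<- params
  }

  # -- simulate or load ------------------------------------------------
  if (!is.null(cfg$input)) {
    spectra <- read_spectra(cfg$input$spectra, format = "csv")
    refs <- utils::read.csv(cfg$input$references)
    ds <- list(spectra = spectra, references = refs, outlier_ids = character(0))
    log_stage("input", cfg$input)
  } else {
    ds <- do.call(generate_dataset,
                  c(cfg$simulate, list(seed = cfg$seed)))
    log_stage("simulate", c(cfg$simulate, list(seed = cfg$seed)))
  }
  write_spectra(ds$spectra, file.path(out_dir, "spectra_raw.csv"))

  # -- preprocess (averaging + S-G; min-max follows screening) ---------
  smoothed <- savgol_smooth(average_replicates(ds$spectra),
                            window = cfg$preprocess$window,
                            polyorder = cfg$preprocess$polyorder)
  log_stage("preprocess", list(window = cfg$preprocess$window,
                               polyorder = cfg$preprocess$polyorder,
                               order = c("average", "savgol", "screen",
                                         "minmax")))
  write_spectra(minmax_scale(smoothed),
                file.path(out_dir, "spectra_preprocessed.csv"))

  # -- screen (on smoothed, un-normalized spectra: min-max would erase
  # the amplitude signature of gross acquisition failures) -------------
  scr <- flag_outliers(smoothed, rule = cfg$screen$rule, k = cfg$screen$k,
                       n_scores = cfg$screen$n_scores)
  log_stage("screen", list(rule = cfg$screen$rule, k = cfg$screen$k,
                           n_scores = attr(scr$distances, "n_scores"),
                           threshold = scr$threshold,
                           flagged_ids = scr$flagged_ids))
  jsonlite::write_json(
    list(rule = scr$rule, threshold = scr$threshold,
         flagged_ids = scr$flagged_ids,
         distances = as.list(stats::setNames(unname(scr$distances),
                                             names(scr$distances)))),
    file.path(out_dir, "screening.json"), auto_unbox = TRUE, digits = NA)
  retained <- minmax_scale(scr$retained)
  write_spectra(retained, file.path(out_dir, "spectra_retained.csv"))

  # -- references ------------------------------------------------------
  wide <- reference_table(ds$references)
  wide <- wide[match(retained$sample_ids, wide$sample_id), , drop = FALSE]
  if (anyNA(wide$sample_id)) {
    stop("reference table does not cover every retained sample",
         call. = FALSE)
  }

  # -- split -----------------------------------------------------------
  sp <- kennard_stone_split(retained, ratio = cfg$split$ratio)
  log_stage("split", list(ratio = cfg$split$ratio,
                          n_calibration = sp$n_calibration,
                          n_validation = sp$n_validation))
  jsonlite::write_json(list(calibration_ids = sp$calibration_ids,
                            validation_ids = sp$validation_ids,
                            ratio = sp$ratio),
                       file.path(out_dir, "split.json"), auto_unbox = TRUE,
                       digits = NA)

  cal_idx <- match(sp$calibration_ids, retained$sample_ids)
  val_idx <- match(sp$validation_ids, retained$sample_ids)
  X_cal <- retained$intensities[cal_idx, , drop = FALSE]
  X_val <- retained$intensities[val_idx, , drop = FALSE]
  y_cal <- wide[cal_idx, cfg$attributes, drop = FALSE]
  y_val <- wide[val_idx, cfg$attributes, drop = FALSE]

  # -- select / train / evaluate --------------------------------------
  report <- evaluate_models(cfg$engines, X_cal, y_cal, X_val, y_val,
                            attributes = cfg$attributes,
                            cv_folds = cfg$cv_folds, seed = cfg$seed)
  log_stage("evaluate", list(engines = names(cfg$engines),
                             attributes = cfg$attributes,
                             cv_folds = cfg$cv_folds))
  utils::write.csv(as.data.frame(report),
                   file.path(out_dir, "evaluation_report.csv"),
                   row.names = FALSE)
  sel_json <- lapply(attr(report, "selections"), function(s) {
    if (is.null(s)) return(NULL)
    list(method = s$method, selected_indices = s$selected_indices,
         trace = s$trace)
  })
  jsonlite::write_json(sel_json, file.path(out_dir, "selections.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(log_entries, log_path, auto_unbox = TRUE, digits = NA)

  # -- manifest --------------------------------------------------------
  artifacts <- setdiff(list.files(out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, artifacts))
  manifest <- list(
    package = "ramanqc",
    version = as.character(utils::packageVersion("ramanqc")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "engines")],
    engines = names(cfg$engines),
    artifacts = as.list(stats::setNames(unname(hashes), artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(report = report, screening = scr, split = sp, dataset = ds,
                 manifest = manifest, out_dir = out_dir, config = cfg))
}

#' Bundle the per-attribute models of one engine
#'
#' @param report An `evaluation_report` from [evaluate_models()] /
#'   [run_pipeline()].
#' @param engine Engine name (a `model` value of the report, e.g.
#'   `"cars_cnn"`).
#' @param preprocess Preprocessing fingerprint to apply to incoming raw
#'   spectra (window/polyorder list, as in the config).
#' @return A `model_bundle`: named list of `raman_model`s (one per
#'   attribute) plus the fingerprint.
#' @export
model_bundle <- function(report, engine = "cars_cnn",
                         preprocess = list(window = 11L, polyorder = 3L)) {
  models <- attr(report, "models")
  keys <- grep(paste0("^", engine, "\\."), names(models), value = TRUE)
  if (!length(keys)) {
    stop(sprintf("no fitted models for engine '%s'", engine), call. = FALSE)
  }
  out <- stats::setNames(models[keys], sub(paste0("^", engine, "\\."), "",
                                           keys))
  structure(list(engine = engine, models = out, preprocess = preprocess),
            class = "model_bundle")
}

#' Predict attributes of unknown process samples
#'
#' Applies a [model_bundle()] to raw unknown-batch spectra: replicate
#' averaging and the bundle's preprocessing fingerprint, then one
#' prediction per sample per attribute. Sample ids of the form
#' `batch-stage-point` yield a `batch` column, so per-batch extraction
#' trajectories can be plotted directly.
#'
#' @param bundle A `model_bundle`.
#' @param spectra A [raman_spectra] (raw, replicate-level) or the path of
#'   a wide CSV.
#' @param attributes Attributes to predict (default: all in the bundle).
#' @return Tidy data frame: `batch`, `sample_id`, `attribute`,
#'   `predicted`.
#' @export
predict_unknown <- function(bundle, spectra,
                            attributes = names(bundle$models)) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (is.character(spectra)) spectra <- read_spectra(spectra, "csv")
  if (nrow(spectra$intensities) == 0) {
    stop("empty spectra input", call. = FALSE)
  }
  unknown <- setdiff(attributes, names(bundle$models))
  if (length(unknown)) {
    stop(sprintf("no model for attribute(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  pp <- preprocess_spectra(spectra, window = bundle$preprocess$window,
                           polyorder = bundle$preprocess$polyorder)
  rows <- lapply(attributes, function(a) {
    pred <- predict(bundle$models[[a]], pp)
    data.frame(batch = sub("^([^-]+)-.*$", "\\1", pp$sample_ids),
               sample_id = pp$sample_ids, attribute = a,
               predicted = unname(pred))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
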
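# Synthetic extraction-process generator: known-truth Raman datasets that
# mimic the statistical structure of batch reflux-extraction monitoring
# (saturating analyte kinetics, fluorescence baseline, replicate
# acquisitions, a few gross outliers), so every downstream stage of the
# calibration pipeline can be tested against ground truth.

#' Soluble solid content by the oven-drying formula
#'
#' Gravimetric soluble-solid content of an extract aliquot:
#' `Sc = (W2 - W1) / W * 100` (percent).
#'
#' @param W Mass of the extract aliquot (g). Must be positive.
#' @param W1 Mass of the empty weighing bottle (g).
#' @param W2 Mass of the bottle plus dried residue (g). Must be `>= W1`.
#' @return Soluble solid content in percent. Vectorized over all arguments.
#' @export
#' @examples
#' compute_soluble_solid(W = 2, W1 = 10, W2 = 10.05)  # 2.5
compute_soluble_solid <- function(W, W1, W2) {
  if (any(!is.finite(W)) || any(W <= 0)) {
    stop("invalid measurement: aliquot mass W must be positive", call. = FALSE)
  }
  if (any(!is.finite(W1)) || any(!is.finite(W2)) || any(W2 < W1)) {
    stop("invalid measurement: dried mass W2 must be >= bottle mass W1",
         call. = FALSE)
  }
  (W2 - W1) / W * 100
}

#' Sampling schedule for a multi-stage reflux extraction
#'
#' The default follows the monitored process: three reflux stages of 120,
#' 90 and 90 minutes; within each stage, a sample every 5 min for the
#' first hour, then every 10 min until the stage ends.
#'
#' @param stage_durations Minutes per reflux stage.
#' @param dense_interval Sampling interval (min) inside the dense window.
#' @param sparse_interval Sampling interval (min) after the dense window.
#' @param dense_window Length (min) of the dense window at stage start.
#' @return A `sampling_schedule` list.
#' @export
sampling_schedule <- function(stage_durations = c(120, 90, 90),
                              dense_interval = 5, sparse_interval = 10,
                              dense_window = 60) {
  if (dense_interval <= 0 || sparse_interval <= 0) {
    stop("sampling intervals must be positive", call. = FALSE)
  }
  if (any(stage_durations <= 0) || dense_window <= 0) {
    stop("stage durations and dense window must be positive", call. = FALSE)
  }
  structure(list(stage_durations = stage_durations,
                 dense_interval = dense_interval,
                 sparse_interval = sparse_interval,
                 dense_window = dense_window),
            class = "sampling_schedule")
}

#' Enumerate sampling time points of a schedule
#'
#' @param s A [sampling_schedule].
#' @return A data frame with columns `stage` and `minute`; per stage,
#'   `floor(dense_window / dense_interval)` dense points then
#'   `floor((duration - dense_window) / sparse_interval)` sparse points.
#' @export
schedule_timepoints <- function(s) {
  stopifnot(inherits(s, "sampling_schedule"))
  out <- lapply(seq_along(s$stage_durations), function(k) {
    dur <- s$stage_durations[k]
    win <- min(s$dense_window, dur)
    dense <- seq(s$dense_interval, win, by = s$dense_interval)
    sparse <- numeric(0)
    if (dur >= win + s$sparse_interval) {
      sparse <- seq(win + s$sparse_interval, dur, by = s$sparse_interval)
    }
    data.frame(stage = k, minute = c(dense, sparse))
  })
  do.call(rbind, out)
}

#' Instrument wavenumber axis
#'
#' @param from,to Axis limits (cm^-1).
#' @param by Channel spacing (cm^-1). The defaults give the 1175-channel
#'   grid of the portable dispersive instrument (176-3500 cm^-1 at
#'   2.83 cm^-1).
#' @return Numeric vector of wavenumbers.
#' @export
default_axis <- function(from = 176, to = 3500, by = 2.83) {
  seq(from, to, by = by)
}

#' Pure-component spectrum description
#'
#' @param component_name Label.
#' @param peak_centers Band positions (cm^-1).
#' @param peak_widths Gaussian/Lorentzian width parameter per band (cm^-1).
#' @param peak_heights Unitless intensity per unit concentration, per band.
#' @param shape `"gaussian"` or `"pseudovoigt"`.
#' @param eta Lorentzian fraction for the pseudo-Voigt shape (0 = pure
#'   Gaussian).
#' @return A `pure_component` list.
#' @export
pure_component <- function(component_name, peak_centers, peak_widths,
                           peak_heights, shape = c("gaussian", "pseudovoigt"),
                           eta = 0.3) {
  shape <- match.arg(shape)
  if (length(peak_centers) != length(peak_widths) ||
      length(peak_centers) != length(peak_heights)) {
    stop("peak_centers, peak_widths, peak_heights must have equal length",
         call. = FALSE)
  }
  if (any(peak_widths <= 0)) stop("peak widths must be positive", call. = FALSE)
  if (any(peak_heights < 0)) stop("peak heights must be >= 0", call. = FALSE)
  structure(list(component_name = component_name, peak_centers = peak_centers,
                 peak_widths = peak_widths, peak_heights = peak_heights,
                 shape = shape, eta = eta),
            class = "pure_component")
}

pure_profile <- function(comp, axis) {
  y <- numeric(length(axis))
  for (j in seq_along(comp$peak_centers)) {
    z <- (axis - comp$peak_centers[j]) / comp$peak_widths[j]
    g <- exp(-0.5 * z^2)
    if (comp$shape == "pseudovoigt") {
      l <- 1 / (1 + z^2)
      g <- (1 - comp$eta) * g + comp$eta * l
    }
    y <- y + comp$peak_heights[j] * g
  }
  y
}

#' Default pure-component library
#'
#' Five components: the four phenolic-acid analytes plus a dissolved-solids
#' matrix component whose dominant bands sit at 1000, 1250 and 1500 cm^-1
#' (aromatic ring stretch, C-O-C asymmetric stretch, C=C stretch), the
#' major bands of the real extract. Analyte bands partially overlap the
#' matrix bands and each other so that wavelength selection is non-trivial.
#' Heights are per unit concentration (ug/mL), scaled so each component
#' contributes a comparable share of total intensity at its typical
#' process concentration.
#'
#' @return Named list of [pure_component] objects.
#' @export
default_components <- function() {
  list(
    danshensu = pure_component(
      "danshensu", c(780, 985, 1290, 1605), c(14, 18, 16, 15),
      c(6, 4, 7, 5) * 1e-3),
    ferulic_acid = pure_component(
      "ferulic_acid", c(865, 1180, 1268, 1515), c(12, 15, 14, 13),
      c(16, 22, 14, 20) * 1e-3),
    rosmarinic_acid = pure_component(
      "rosmarinic_acid", c(920, 1255, 1440, 1610), c(15, 14, 16, 14),
      c(7, 9, 8, 6) * 1e-3),
    salvianolic_acid_B = pure_component(
      "salvianolic_acid_B", c(1030, 1350, 1470, 1598), c(16, 15, 17, 14),
      c(1.6, 2.2, 1.8, 1.5) * 1e-3),
    soluble_solid = pure_component(
      "soluble_solid", c(1000, 1250, 1500, 2910), c(20, 22, 24, 60),
      c(2.6, 2.0, 2.2, 0.9) * 1e-4)
  )
}

#' First-order extraction kinetics
#'
#' Concentration within reflux stage `s` at stage time `t` (min):
#' `c(t) = c_max * stage_yields[s] * (1 - exp(-rate * t))` -- a saturating
#' rise, with most of the yield in stage 1 and diminishing returns in
#' later stages.
#'
#' @param c_max Asymptotic stage-1 concentration (ug/mL).
#' @param rate First-order rate constant (1/min).
#' @param stage_yields Fraction of `c_max` recoverable per stage.
#' @return An `extraction_kinetics` list.
#' @export
extraction_kinetics <- function(c_max, rate, stage_yields = c(1, 0.35, 0.15)) {
  if (c_max <= 0 || rate <= 0) {
    stop("c_max and rate must be positive", call. = FALSE)
  }
  structure(list(c_max = c_max, rate = rate, stage_yields = stage_yields),
            class = "extraction_kinetics")
}

#' Default kinetics per component
#' @return Named list of [extraction_kinetics], one per default component.
#' @export
default_kinetics <- function() {
  list(
    danshensu = extraction_kinetics(120, 0.050),
    ferulic_acid = extraction_kinetics(40, 0.040),
    rosmarinic_acid = extraction_kinetics(90, 0.060),
    salvianolic_acid_B = extraction_kinetics(400, 0.045),
    soluble_solid = extraction_kinetics(5000, 0.050)
  )
}

kinetics_concentration <- function(k, stage, minute) {
  y <- k$stage_yields[pmin(stage, length(k$stage_yields))]
  k$c_max * y * (1 - exp(-k$rate * minute))
}

#' Render one spectrum from a linear mixture model
#'
#' `intensity(v) = sum_k c_k * pure_k(v) + baseline(v) + noise`, where the
#' baseline is a smooth fluorescence-like curve
#' `b1 * exp(-(v - v0)/1200) + b2 + b3 * u + b4 * u^2` with `u` the axis
#' rescaled to `[0, 1]`, and the noise is i.i.d. Gaussian.
#'
#' @param concentrations Named or positional numeric vector (ug/mL), one
#'   per component; must be non-negative.
#' @param components List of [pure_component] objects.
#' @param axis Wavenumber grid; default [default_axis()].
#' @param baseline_coeffs Numeric vector `(b1, b2, b3, b4)` (recycled with
#'   zeros); default no baseline.
#' @param noise_sd Standard deviation of additive noise; default 0.
#' @param seed Optional integer seed for the noise draw.
#' @return Numeric intensity vector on `axis`.
#' @export
render_spectrum <- function(concentrations, components, axis = default_axis(),
                            baseline_coeffs = c(0, 0, 0, 0), noise_sd = 0,
                            seed = NULL) {
  if (length(concentrations) != length(components)) {
    stop("need one concentration per component", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  y <- numeric(length(axis))
  for (k in seq_along(components)) {
    y <- y + concentrations[k] * pure_profile(components[[k]], axis)
  }
  y <- y + eval_baseline(baseline_coeffs, axis)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(axis), 0, noise_sd) else
      with_seed(seed, stats::rnorm(length(axis), 0, noise_sd))
    y <- y + noise
  }
  y
}

eval_baseline <- function(coeffs, axis) {
  b <- rep_len(c(coeffs, rep(0, 4)), 4)
  u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  b[1] * exp(-(axis - axis[1]) / 1200) + b[2] + b[3] * u + b[4] * u^2
}

#' Generate a synthetic extraction-process dataset
#'
#' Emulates multi-batch reflux-extraction monitoring: per batch, spectra at
#' every schedule time point (triplicate acquisitions by default), analyte
#' concentrations following saturating first-order kinetics with small
#' batch-to-batch variation, a smooth fluorescence baseline with
#' per-acquisition drift, additive noise, reference values carrying ~1%
#' multiplicative measurement error (typical HPLC repeatability), and a
#' configurable number of gross outlier samples (intensity scaled 10x plus
#' random single-channel spikes -- unambiguous acquisition failures).
#'
#' @param n_batches Number of batches (default 7).
#' @param schedule A [sampling_schedule].
#' @param components Pure-component library.
#' @param kinetics Named list of [extraction_kinetics] matching `components`.
#' @param outliers List: `n` planted gross outliers (default 5), `amplitude`
#'   intensity scale factor (default 10), `n_spikes` random spikes
#'   (default 3), `spike_height` spike intensity (default 30).
#' @param replicates Acquisitions per sample (default 3).
#' @param axis Wavenumber grid.
#' @param noise_sd Additive noise standard deviation (default 0.02,
#'   roughly 1-2% of a typical band height at process concentrations).
#' @param baseline_coeffs Mean baseline coefficients, see
#'   [render_spectrum()]; per-acquisition coefficients jitter around these
#'   by `baseline_drift` (relative sd).
#' @param baseline_drift Relative baseline drift between acquisitions.
#' @param reference_cv Coefficient of variation of reference-method error.
#' @param batch_cv Batch-to-batch coefficient of variation of `c_max`.
#' @param soluble_solid_range Target range (ug/mL) that the ground-truth
#'   soluble solid spans across the dataset (affine rescaling of the raw
#'   kinetic trajectory); default `c(418.7, 4882.7)`.
#' @param drop_last Drop the final time point of the last batch, matching
#'   a process dataset in which one schedule slot went uncollected
#'   (default TRUE: 7 batches x 48 points - 1 = 335 samples).
#' @param seed Integer seed; regeneration with the same configuration and
#'   seed is bit-identical.
#' @return A `raman_dataset`: `spectra` (replicate-level [raman_spectra],
#'   ids `batch-stage-point#r<k>`), `references` (tidy data frame
#'   `sample_id, attribute, value, units`), `truth` (noise-free wide data
#'   frame), `outlier_ids`, `seed`, and the generating configuration.
#' @export
generate_dataset <- function(n_batches = 7,
                             schedule = sampling_schedule(),
                             components = default_components(),
                             kinetics = default_kinetics(),
                             outliers = list(n = 5, amplitude = 10,
                                             n_spikes = 3, spike_height = 30),
                             replicates = 3,
                             axis = default_axis(),
                             noise_sd = 0.02,
                             baseline_coeffs = c(1.2, 0.15, 0.3, -0.2),
                             baseline_drift = 0.05,
                             reference_cv = 0.01,
                             batch_cv = 0.05,
                             soluble_solid_range = c(418.7, 4882.7),
                             drop_last = TRUE,
                             seed = 1L) {
  stopifnot(n_batches >= 1, replicates >= 1)
  if (!identical(names(components), names(kinetics))) {
    stop("components and kinetics must be named lists with matching names",
         call. = FALSE)
  }
  outliers <- utils::modifyList(
    list(n = 5, amplitude = 10, n_spikes = 3, spike_height = 30), outliers)
  tp <- schedule_timepoints(schedule)
  n_comp <- length(components)
  comp_names <- names(components)

  # Sample frame: batch x schedule point, minus the optional dropped slot.
  frame <- do.call(rbind, lapply(seq_len(n_batches), function(b) {
    cbind(batch = b, tp, point = stats::ave(tp$stage, tp$stage,
                                            FUN = seq_along))
  }))
  if (drop_last) frame <- frame[-nrow(frame), , drop = FALSE]
  n_samp <- nrow(frame)
  if (outliers$n >= n_samp) {
    stop("outlier count must be smaller than the sample count", call. = FALSE)
  }
  ids <- sprintf("%d-%d-%d", frame$batch, frame$stage, frame$point)

  with_seed(seed, {
    # Ground-truth concentrations (samples x components), with lognormal
    # batch effects on c_max.
    batch_eff <- matrix(exp(stats::rnorm(n_batches * n_comp, 0, batch_cv)),
                        n_batches, n_comp)
    conc <- matrix(0, n_samp, n_comp, dimnames = list(ids, comp_names))
    for (k in seq_len(n_comp)) {
      conc[, k] <- kinetics_concentration(kinetics[[k]], frame$stage,
                                          frame$minute) *
        batch_eff[frame$batch, k]
    }
    # Pin the soluble-solid trajectory to the configured span.
    if (!is.null(soluble_solid_range) && "soluble_solid" %in% comp_names) {
      s <- conc[, "soluble_solid"]
      conc[, "soluble_solid"] <-
        soluble_solid_range[1] + (s - min(s)) / (max(s) - min(s)) *
        diff(soluble_solid_range)
    }

    profiles <- vapply(components, pure_profile, numeric(length(axis)),
                       axis = axis)           # channels x components
    clean <- conc %*% t(profiles)             # samples x channels

    outlier_ids <- character(0)
    if (outliers$n > 0) {
      outlier_ids <- sort(sample(ids, outliers$n))
    }

    inten <- matrix(0, n_samp * replicates, length(axis))
    rep_ids <- character(n_samp * replicates)
    r <- 0
    for (i in seq_len(n_samp)) {
      for (j in seq_len(replicates)) {
        r <- r + 1
        bc <- baseline_coeffs *
          (1 + stats::rnorm(length(baseline_coeffs), 0, baseline_drift))
        y <- clean[i, ] + eval_baseline(bc, axis) +
          stats::rnorm(length(axis), 0, noise_sd)
        if (ids[i] %in% outlier_ids) {
          y <- y * outliers$amplitude
          if (outliers$n_spikes > 0) {
            ch <- sample.int(length(axis), outliers$n_spikes)
            y[ch] <- y[ch] + outliers$spike_height
          }
        }
        inten[r, ] <- y
        rep_ids[r] <- if (replicates > 1) sprintf("%s#r%d", ids[i], j) else
          ids[i]
      }
    }

    ref_noise <- matrix(1 + stats::rnorm(n_samp * n_comp, 0, reference_cv),
                        n_samp, n_comp)
    measured <- conc * ref_noise
    references <- data.frame(
      sample_id = rep(ids, times = n_comp),
      attribute = rep(comp_names, each = n_samp),
      value = as.vector(measured),
      units = "ug/mL",
      stringsAsFactors = FALSE
    )

    spectra <- raman_spectra(
      axis, inten, rep_ids,
      meta = list(generator = "ramanqc synthetic extraction process",
                  seed = seed, replicates = replicates,
                  n_batches = n_batches))

    structure(list(
      spectra = spectra,
      references = references,
      truth = data.frame(sample_id = ids, batch = frame$batch,
                         stage = frame$stage, minute = frame$minute,
                         as.data.frame(conc), row.names = NULL,
                         check.names = FALSE),
      outlier_ids = outlier_ids,
      seed = seed,
      config = list(n_batches = n_batches, replicates = replicates,
                    outliers = outliers, noise_sd = noise_sd,
                    reference_cv = reference_cv, batch_cv = batch_cv,
                    soluble_solid_range = soluble_solid_range,
                    drop_last = drop_last)
    ), class = "raman_dataset")
  })
}

#' @export
print.raman_dataset <- function(x, ...) {
  n_rep <- nrow(x$spectra$intensities)
  cat(sprintf(paste0("<raman_dataset> %d samples (%d acquisitions), ",
                     "%d channels, %d planted outliers, seed %d\n"),
              nrow(x$truth), n_rep, length(x$spectra$axis),
              length(x$outlier_ids), x$seed))
  invisible(x)
}

#' Reference values as a wide table
#'
#' @param ds A `raman_dataset` (or its tidy `references` data frame).
#' @return Data frame: one row per sample, one column per attribute.
#' @export
reference_table <- function(ds) {
  refs <- if (inherits(ds, "raman_dataset")) ds$references else ds
  wide <- stats::reshape(refs[, c("sample_id", "attribute", "value")],
                         idvar = "sample_id", timevar = "attribute",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Write a synthetic dataset to disk
#'
#' Spectra as wide CSV, references as tidy CSV, and a ground-truth sidecar
#' JSON (outlier ids, seed, configuration).
#'
#' @param ds A `raman_dataset`.
#' @param dir Output directory (created if absent).
#' @param jcamp Also write one JCAMP-DX file per acquisition.
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir, jcamp = FALSE) {
  stopifnot(inherits(ds, "raman_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    spectra = file.path(dir, "spectra.csv"),
    references = file.path(dir, "references.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_spectra(ds$spectra, paths$spectra)
  utils::write.csv(ds$references, paths$references, row.names = FALSE)
  jsonlite::write_json(
    list(seed = ds$seed, outlier_ids = ds$outlier_ids, config = ds$config,
         truth = ds$truth),
    paths$truth, auto_unbox = TRUE, digits = NA)
  if (jcamp) {
    paths$jcamp <- write_spectra_jcamp(ds$spectra, file.path(dir, "jcamp"))
  }
  invisible(paths)
}

# Evaluate `code` under a temporary, fully specified RNG state so results
# are bit-identical regardless of the caller's RNG, then restore.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind[1:2]))
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  RNGkind("Mersenne-Twister", "Inversion")
  set.seed(seed)
  code
}
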
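# Spectral pretreatment: Savitzky-Golay least-squares smoothing followed by
# per-spectrum min-max scaling to [0, 1]. The fixed pipeline order is
# replicate averaging -> S-G -> min-max; each step is a pure function.

savgol_matrix <- function(n, window, polyorder) {
  half <- (window - 1L) %/% 2L
  hat <- function(positions, eval_at) {
    A <- outer(positions, 0:polyorder, `^`)
    E <- outer(eval_at, 0:polyorder, `^`)
    E %*% solve(crossprod(A), t(A))
  }
  S <- matrix(0, n, n)
  w_int <- hat(-half:half, 0)          # central S-G weights
  for (i in (half + 1L):(n - half)) {
    S[i, (i - half):(i + half)] <- w_int
  }
  # Edge rows: same local polynomial fit, asymmetric window (the fit to the
  # first/last `window` channels, evaluated at the edge positions).
  S[1:half, 1:window] <- hat(0:(window - 1L), 0:(half - 1L))
  S[(n - half + 1L):n, (n - window + 1L):n] <-
    hat(0:(window - 1L), (window - half):(window - 1L))
  S
}

#' Savitzky-Golay smoothing
#'
#' Per-spectrum local least-squares polynomial smoothing with a symmetric
#' window at interior channels and polynomial-interpolated edges (the same
#' asymmetric-window fit, so the channel count is preserved). The defaults
#' (window 11 channels, cubic) preserve bands of ~30 cm^-1 width on a
#' 2.83 cm^-1 grid.
#'
#' @param m A [raman_spectra] object or a numeric matrix (rows = spectra).
#' @param window Odd window length in channels; must exceed `polyorder`
#'   and not exceed the channel count.
#' @param polyorder Polynomial degree of the local fit.
#' @return Same type as `m`, smoothed; the axis is unchanged.
#' @export
savgol_smooth <- function(m, window = 11L, polyorder = 3L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (window <= polyorder) {
    stop("`window` must exceed `polyorder`", call. = FALSE)
  }
  X <- if (inherits(m, "raman_spectra")) m$intensities else as.matrix(m)
  if (window > ncol(X)) {
    stop("`window` exceeds the channel count", call. = FALSE)
  }
  S <- savgol_matrix(ncol(X), window, polyorder)
  sm <- X %*% t(S)
  if (inherits(m, "raman_spectra")) {
    meta <- m$meta
    meta$savgol <- list(window = window, polyorder = polyorder)
    raman_spectra(m$axis, sm, m$sample_ids, meta)
  } else {
    dimnames(sm) <- dimnames(X)
    sm
  }
}

#' Min-max scaling to [0, 1]
#'
#' Maps each spectrum affinely so its minimum becomes 0 and its maximum 1.
#' The result is invariant to any prior positive affine transform of the
#' spectrum, which removes laser-power and collection-efficiency scale
#' differences between acquisitions.
#'
#' @param m A [raman_spectra] object or a numeric matrix (rows = spectra).
#' @return Same type as `m`, each row spanning exactly [0, 1].
#' @export
minmax_scale <- function(m) {
  X <- if (inherits(m, "raman_spectra")) m$intensities else as.matrix(m)
  lo <- apply(X, 1, min)
  hi <- apply(X, 1, max)
  flat <- which(hi - lo <= 0)
  if (length(flat)) {
    ids <- if (inherits(m, "raman_spectra")) m$sample_ids[flat] else
      as.character(flat)
    stop(sprintf("degenerate (constant) spectrum: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  sc <- (X - lo) / (hi - lo)
  if (inherits(m, "raman_spectra")) {
    meta <- m$meta
    meta$minmax <- TRUE
    raman_spectra(m$axis, sc, m$sample_ids, meta)
  } else {
    dimnames(sc) <- dimnames(X)
    sc
  }
}

#' Full pretreatment pipeline
#'
#' Replicate averaging (optional), Savitzky-Golay smoothing, then min-max
#' scaling, in that fixed order.
#'
#' @param m A [raman_spectra] object.
#' @param window,polyorder S-G parameters, see [savgol_smooth()].
#' @param average Average replicate acquisitions first.
#' @param replicate_key Passed to [average_replicates()].
#' @return A preprocessed [raman_spectra]; `meta$preprocess` records the
#'   parameters actually applied (the preprocessing fingerprint).
#' @export
preprocess_spectra <- function(m, window = 11L, polyorder = 3L,
                               average = TRUE, replicate_key = "#r[0-9]+$") {
  stopifnot(inherits(m, "raman_spectra"))
  if (average) m <- average_replicates(m, replicate_key)
  m <- savgol_smooth(m, window, polyorder)
  m <- minmax_scale(m)
  m$meta$preprocess <- list(window = as.integer(window),
                            polyorder = as.integer(polyorder),
                            average = average, order = c("average", "savgol",
                                                         "minmax"))
  m
}
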
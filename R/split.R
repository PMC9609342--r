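# Kennard-Stone calibration/validation splitting: a deterministic max-min
# design that seeds the calibration set with the two mutually most distant
# samples and grows it greedily, so the calibration set spans the spectral
# space and the validation samples sit inside it.

#' Kennard-Stone split
#'
#' Greedy max-min partition into calibration and validation sets. The two
#' most distant samples (Euclidean, on the supplied feature rows) seed the
#' calibration set; each further step adds the sample whose minimum
#' distance to the already-chosen set is largest, until the calibration
#' set holds `floor(ratio * n / (ratio + 1))` samples. Ties are broken by
#' lowest sample index, making the split deterministic across platforms.
#'
#' @param m A [raman_spectra] object or numeric matrix (rows = samples).
#' @param ratio Calibration:validation ratio, as a number (4 means 4:1) or
#'   a string `"4:1"`.
#' @return A `calibration_split`: `calibration_ids` (in selection order),
#'   `validation_ids`, `ratio`, `n_calibration`, `n_validation`.
#' @export
kennard_stone_split <- function(m, ratio = 4) {
  X <- if (inherits(m, "raman_spectra")) m$intensities else as.matrix(m)
  ids <- if (inherits(m, "raman_spectra")) m$sample_ids else
    (rownames(X) %||% as.character(seq_len(nrow(X))))
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":")[[1]])
    ratio <- parts[1] / ifelse(length(parts) > 1, parts[2], 1)
  }
  if (!is.finite(ratio) || ratio <= 0) {
    stop("ratio implies an empty validation set", call. = FALSE)
  }
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  n_cal <- floor(ratio * n / (ratio + 1))
  if (n_cal < 2) stop("ratio leaves fewer than 2 calibration samples",
                      call. = FALSE)
  if (n_cal >= n) {
    stop("ratio implies an empty validation set", call. = FALSE)
  }

  D <- as.matrix(stats::dist(X))
  # Seed: the most distant pair; on ties, the pair with the lowest indices
  # (row-major order of which()).
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE][1, ]
  sel <- sort(unname(far))
  min_d <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_cal) {
    min_d[sel] <- -Inf
    nxt <- which.max(min_d)          # which.max takes the first (lowest) index
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, D[, nxt])
  }
  structure(list(calibration_ids = ids[sel],
                 validation_ids = ids[setdiff(seq_len(n), sel)],
                 ratio = ratio,
                 n_calibration = n_cal,
                 n_validation = n - n_cal),
            class = "calibration_split")
}

#' @export
print.calibration_split <- function(x, ...) {
  cat(sprintf("<calibration_split> %d calibration / %d validation (ratio %g:1)\n",
              x$n_calibration, x$n_validation, x$ratio))
  invisible(x)
}
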
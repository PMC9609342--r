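#' Construct a spectra matrix
#'
#' The package's central data structure: a set of spectra on a common,
#' strictly increasing wavenumber grid. Rows are samples, columns are
#' spectral channels.
#'
#' @param axis Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, one row per sample, `length(axis)`
#'   columns. Row names, if present, must agree with `sample_ids`.
#' @param sample_ids Character vector of unique sample labels. Defaults to
#'   the row names of `intensities`.
#' @param meta Optional named list of acquisition provenance (instrument
#'   settings, replicate counts, processing history).
#'
#' @return An object of class `raman_spectra` with fields `axis`,
#'   `intensities`, `sample_ids` and `meta`.
#' @export
raman_spectra <- function(axis, intensities, sample_ids = rownames(intensities),
                          meta = list()) {
  axis <- as.numeric(axis)
  if (is.null(dim(intensities))) {
    intensities <- matrix(intensities, nrow = 1)
  }
  intensities <- as.matrix(intensities)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(intensities)))
  }
  sample_ids <- as.character(sample_ids)
  if (any(diff(axis) <= 0)) {
    stop("`axis` must be strictly increasing", call. = FALSE)
  }
  if (ncol(intensities) != length(axis)) {
    stop(sprintf("intensities have %d channels but axis has %d points",
                 ncol(intensities), length(axis)), call. = FALSE)
  }
  if (nrow(intensities) != length(sample_ids)) {
    stop("row count of intensities must equal number of sample ids",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop(sprintf("duplicate sample id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("intensities contain non-finite values", call. = FALSE)
  }
  rownames(intensities) <- sample_ids
  structure(list(axis = axis, intensities = intensities,
                 sample_ids = sample_ids, meta = meta),
            class = "raman_spectra")
}

#' @export
print.raman_spectra <- function(x, ...) {
  cat(sprintf("<raman_spectra> %d spectra x %d channels, %.2f-%.2f cm^-1\n",
              nrow(x$intensities), length(x$axis), min(x$axis), max(x$axis)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.raman_spectra <- function(x) dim(x$intensities)

#' Subset a spectra matrix by sample
#'
#' @param m A `raman_spectra` object.
#' @param ids Character vector of sample ids (or integer indices) to keep,
#'   in the order given.
#' @return A `raman_spectra` with the requested rows.
#' @export
subset_samples <- function(m, ids) {
  stopifnot(inherits(m, "raman_spectra"))
  if (is.character(ids)) {
    missing <- setdiff(ids, m$sample_ids)
    if (length(missing)) {
      stop(sprintf("unknown sample id(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    idx <- match(ids, m$sample_ids)
  } else {
    idx <- as.integer(ids)
  }
  raman_spectra(m$axis, m$intensities[idx, , drop = FALSE],
                m$sample_ids[idx], m$meta)
}

#' Read spectra from disk
#'
#' Supports the package's wide CSV layout (first column the wavenumber
#' axis, one further column per sample) and a minimal JCAMP-DX subset
#' (one spectrum per file, `##XYDATA=(X++(Y..Y))` blocks in plain AFFN
#' form; for JCAMP, `path` may be a vector of files, one per sample).
#' A JCAMP file stored with a descending axis is re-sorted ascending,
#' with intensities re-ordered consistently.
#'
#' @param path File path (CSV) or vector of file paths (JCAMP).
#' @param format `"csv"` or `"jcamp"`.
#' @return A [raman_spectra] object.
#' @export
read_spectra <- function(path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  if (format == "csv") {
    read_spectra_csv(path)
  } else {
    read_spectra_jcamp(path)
  }
}

read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2) {
    stop(sprintf("%s: need a wavenumber column plus at least one sample column",
                 path), call. = FALSE)
  }
  ids <- colnames(tab)[-1]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("%s: duplicate sample column(s): %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  axis <- tab[[1]]
  if (any(!is.finite(axis)) || any(diff(axis) <= 0)) {
    stop(sprintf("%s: wavenumber column must be finite and strictly increasing",
                 path), call. = FALSE)
  }
  inten <- t(as.matrix(tab[, -1, drop = FALSE]))
  if (any(!is.finite(inten))) {
    bad <- which(!is.finite(inten), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: non-finite intensity for sample '%s' at row %d",
                 path, ids[bad[1]], bad[2]), call. = FALSE)
  }
  raman_spectra(axis, inten, ids, meta = list(source = path, format = "csv"))
}

#' Write spectra to a wide CSV
#'
#' @param m A `raman_spectra` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(m, path) {
  stopifnot(inherits(m, "raman_spectra"))
  tab <- data.frame(wavenumber = m$axis, check.names = FALSE)
  tab[m$sample_ids] <- as.data.frame(t(m$intensities))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

# Minimal JCAMP-DX (one spectrum per file, AFFN-encoded X++(Y..Y) table).
read_spectra_jcamp <- function(paths) {
  specs <- lapply(paths, read_one_jcamp)
  axis <- specs[[1]]$axis
  for (s in specs[-1]) {
    if (length(s$axis) != length(axis) || max(abs(s$axis - axis)) > 1e-6) {
      stop("JCAMP files do not share a common wavenumber axis", call. = FALSE)
    }
  }
  inten <- do.call(rbind, lapply(specs, `[[`, "y"))
  ids <- vapply(specs, `[[`, character(1), "title")
  raman_spectra(axis, inten, ids,
                meta = list(source = paths, format = "jcamp"))
}

read_one_jcamp <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^##", key, "="), "", hit[1]))
  }
  title <- field("TITLE")
  if (is.null(title) || !nzchar(title)) title <- basename(path)
  npoints <- as.integer(field("NPOINTS"))
  xfactor <- as.numeric(field("XFACTOR") %||% "1")
  yfactor <- as.numeric(field("YFACTOR") %||% "1")
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) {
    stop(sprintf("%s: no ##XYDATA block", path), call. = FALSE)
  }
  end <- grep("^##END=", lines)
  end <- end[end > start[1]][1]
  if (is.na(end)) end <- length(lines) + 1
  body <- lines[(start[1] + 1):(end - 1)]
  xs <- numeric(0)
  ys <- numeric(0)
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                                 "[ \t,]+")[[1]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2) {
      stop(sprintf("%s: malformed XYDATA line %d", path, start[1] + i),
           call. = FALSE)
    }
    # X++(Y..Y): first value is the abscissa of the first ordinate; the
    # remaining ordinates continue on the implied grid.
    xs <- c(xs, vals[1])
    ys <- c(ys, vals[-1])
  }
  if (!is.na(npoints) && length(ys) != npoints) {
    stop(sprintf("%s: NPOINTS=%d but %d ordinates found", path, npoints,
                 length(ys)), call. = FALSE)
  }
  # Reconstruct the full abscissa from FIRSTX/LASTX (preferred) or line Xs.
  firstx <- as.numeric(field("FIRSTX") %||% xs[1])
  lastx <- as.numeric(field("LASTX") %||% NA)
  n <- length(ys)
  if (is.finite(lastx) && n > 1) {
    axis <- seq(firstx, lastx, length.out = n) * xfactor
  } else {
    dx <- as.numeric(field("DELTAX") %||% "1")
    axis <- (firstx + dx * (seq_len(n) - 1)) * xfactor
  }
  y <- ys * yfactor
  ord <- order(axis)
  list(title = title, axis = axis[ord], y = y[ord])
}

#' Write one spectrum per file in minimal JCAMP-DX
#'
#' @param m A `raman_spectra` object.
#' @param dir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_spectra_jcamp <- function(m, dir) {
  stopifnot(inherits(m, "raman_spectra"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(m$axis)
  paths <- character(nrow(m$intensities))
  for (i in seq_len(nrow(m$intensities))) {
    id <- m$sample_ids[i]
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", id), ".jdx"))
    y <- m$intensities[i, ]
    rows <- split(seq_len(n), ceiling(seq_len(n) / 6))
    body <- vapply(rows, function(idx) {
      paste(format(c(m$axis[idx[1]], y[idx]), trim = TRUE, digits = 10),
            collapse = " ")
    }, character(1))
    writeLines(c(
      paste0("##TITLE=", id),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=RAMAN SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ARBITRARY UNITS",
      "##XFACTOR=1", "##YFACTOR=1",
      paste0("##FIRSTX=", format(m$axis[1], digits = 10)),
      paste0("##LASTX=", format(m$axis[n], digits = 10)),
      paste0("##NPOINTS=", n),
      "##XYDATA=(X++(Y..Y))",
      body,
      "##END="
    ), path)
    paths[i] <- path
  }
  invisible(paths)
}

#' Average replicate acquisitions
#'
#' Collapses replicate spectra of the same physical sample to their
#' channel-wise arithmetic mean. Replicate membership is derived from the
#' sample ids with `replicate_key`, a regular expression whose removal
#' yields the group label (the default strips a `#r<k>` suffix, the
#' generator's replicate tag).
#'
#' @param m A `raman_spectra` object.
#' @param replicate_key Regular expression identifying the replicate suffix,
#'   or a character/factor vector of group labels of length `nrow(m)`.
#' @return A `raman_spectra` with one row per group, ordered by first
#'   appearance; group sizes are recorded in `meta$replicates`.
#' @export
average_replicates <- function(m, replicate_key = "#r[0-9]+$") {
  stopifnot(inherits(m, "raman_spectra"))
  n <- nrow(m$intensities)
  if (length(replicate_key) == 1 && is.character(replicate_key)) {
    groups <- sub(replicate_key, "", m$sample_ids)
  } else if (length(replicate_key) == n) {
    groups <- as.character(replicate_key)
  } else {
    stop("`replicate_key` must be a single regex or one label per sample",
         call. = FALSE)
  }
  ord <- unique(groups)
  idx <- split(seq_len(n), factor(groups, levels = ord))
  out <- matrix(0, length(ord), length(m$axis))
  for (g in seq_along(idx)) {
    out[g, ] <- colMeans(m$intensities[idx[[g]], , drop = FALSE])
  }
  sizes <- lengths(idx)
  names(sizes) <- ord
  meta <- m$meta
  meta$replicates <- sizes
  raman_spectra(m$axis, out, ord, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
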
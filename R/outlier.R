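# Abnormal-spectrum screening by Mahalanobis distance in a reduced
# principal-component score space. The raw channel-space covariance of a
# few hundred spectra over ~1000 channels is singular, so distances are
# computed on PCA scores retaining a target share of variance (standard
# chemometric practice); Mahalanobis distance is affine-invariant, so the
# projection choice only matters through its dimensionality. The variance
# target is deliberately high (99.9%): gross acquisition failures such as
# cosmic-ray spikes are near-orthogonal to the dominant (concentration-
# driven) variation and only become visible once the minor components are
# included -- a 95% cut can drop them entirely.

#' Mahalanobis distances of spectra
#'
#' Projects the (preprocessed) spectra onto their leading principal
#' components and returns each sample's Mahalanobis distance from the
#' score-space mean under the score covariance.
#'
#' @param m A [raman_spectra] object or numeric matrix (rows = samples).
#' @param n_scores Number of principal components, or `"auto"` (default):
#'   the smallest number explaining `variance` of total variance, capped
#'   at `max_scores` and at least 2.
#' @param variance Variance share targeted by `"auto"` (default 0.999; see
#'   the note on spike-type outliers in the source).
#' @param max_scores Cap on the score count (default 10).
#' @return Numeric vector of distances (>= 0), named by sample id, with
#'   attribute `n_scores`.
#' @export
mahalanobis_distances <- function(m, n_scores = "auto", variance = 0.999,
                                  max_scores = 10L) {
  X <- if (inherits(m, "raman_spectra")) m$intensities else as.matrix(m)
  n <- nrow(X)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  if (identical(n_scores, "auto")) {
    q <- which(cumsum(ev) / sum(ev) >= variance)[1]
    q <- max(2L, min(q, max_scores, length(ev)))
  } else {
    q <- as.integer(n_scores)
  }
  if (n <= q + 1L) {
    stop("need more samples than score dimensions + 1", call. = FALSE)
  }
  scores <- pca$x[, seq_len(q), drop = FALSE]
  S <- stats::cov(scores)
  if (rcond_sym(S) < 1e-12) {
    stop(paste("singular score covariance; retry with fewer `n_scores`"),
         call. = FALSE)
  }
  d2 <- stats::mahalanobis(scores, colMeans(scores), S)
  d <- sqrt(pmax(d2, 0))
  names(d) <- if (inherits(m, "raman_spectra")) m$sample_ids else rownames(X)
  attr(d, "n_scores") <- q
  d
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Flag and remove abnormal spectra
#'
#' Samples whose Mahalanobis distance exceeds a threshold are flagged and
#' excluded. Two threshold rules: `"mean3sd"` (default), mean + k * sd of
#' the distance distribution, applied iteratively -- after flagging, the
#' threshold is recomputed from the unflagged distances until no new
#' sample is flagged, so that gross outliers cannot mask milder ones by
#' inflating the distribution's spread; `"chi2"`, the square root of the
#' chi-square quantile at `alpha` with `n_scores` degrees of freedom
#' (a fixed reference threshold, no iteration).
#'
#' @param m A [raman_spectra] object (or matrix).
#' @param rule `"mean3sd"` or `"chi2"`.
#' @param k Multiplier for the `"mean3sd"` rule (default 3).
#' @param alpha Quantile for the `"chi2"` rule (default 0.999).
#' @param distances Optional precomputed result of
#'   [mahalanobis_distances()]; computed if missing.
#' @param ... Passed on to [mahalanobis_distances()].
#' @return A `screening_result`: `distances`, `threshold`, `rule`,
#'   `flagged_ids`, and `retained` (the input minus flagged rows).
#' @export
flag_outliers <- function(m, rule = c("mean3sd", "chi2"), k = 3,
                          alpha = 0.999, distances = NULL, ...) {
  rule <- match.arg(rule)
  X_is_spectra <- inherits(m, "raman_spectra")
  n <- if (X_is_spectra) nrow(m$intensities) else nrow(m)
  if (n < 3) stop("need at least 3 samples to screen", call. = FALSE)
  if (is.null(distances)) distances <- mahalanobis_distances(m, ...)
  if (rule == "chi2") {
    threshold <- sqrt(stats::qchisq(alpha, df = attr(distances, "n_scores")))
    flagged <- which(distances > threshold)
  } else {
    flagged <- integer(0)
    repeat {
      keep <- setdiff(seq_len(n), flagged)
      threshold <- mean(distances[keep]) + k * stats::sd(distances[keep])
      new_flagged <- which(distances > threshold)
      if (length(new_flagged) == length(flagged)) break
      if (length(new_flagged) >= n) break      # degenerate, caught below
      flagged <- new_flagged
    }
  }
  if (length(flagged) == n) {
    stop("screening degenerate: every sample flagged", call. = FALSE)
  }
  ids <- names(distances) %||% as.character(seq_len(n))
  retained <- if (X_is_spectra) {
    subset_samples(m, setdiff(seq_len(n), flagged))
  } else {
    m[setdiff(seq_len(n), flagged), , drop = FALSE]
  }
  structure(list(distances = distances, threshold = threshold, rule = rule,
                 flagged_ids = ids[flagged], retained = retained),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %s rule, threshold %.3f: %d flagged, %d retained\n",
              x$rule, x$threshold, length(x$flagged_ids),
              length(x$distances) - length(x$flagged_ids)))
  if (length(x$flagged_ids)) {
    cat("  flagged:", paste(x$flagged_ids, collapse = ", "), "\n")
  }
  invisible(x)
}
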
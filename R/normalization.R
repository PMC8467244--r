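# Preprocessing: LOWESS normalization of each sample against the cohort
# median reference, then log2 transform and per-gene median centering.
# Fold changes are later computed on the unlogged LOWESS-normalized scale;
# clustering and tests use the log2 median-centered scale.

#' Per-gene median reference profile
#'
#' The cohort reference each sample is normalized against: for every gene,
#' the median raw intensity over all samples.
#'
#' @param expr an [expression_matrix()] with at least two samples.
#' @return named numeric vector, one value per gene.
#' @export
median_reference <- function(expr) {
  if (ncol(expr) < 2) {
    stop("need >= 2 samples to define a median reference", call. = FALSE)
  }
  apply(unclass(expr), 1, median, na.rm = TRUE)
}

#' LOWESS-normalize samples against a reference profile
#'
#' For each sample, fits a LOWESS curve of M = log2(sample) - log2(ref)
#' against an intensity abscissa and subtracts the fitted trend, removing
#' intensity-dependent bias. Returned intensities are
#' 2^(log2(ref) + corrected M), positive by construction.
#'
#' The abscissa is, by default, the reference intensity log2(ref)
#' (`x_axis = "reference"`): with a cohort median reference this
#' coordinate is identical across samples, so a genuinely regulated gene
#' cannot drag the fitted curve toward its own M — up- and down-regulated
#' genes stay balanced within every intensity window and only the
#' technical trend is removed. The classic two-channel abscissa
#' A = (log2(sample) + log2(ref)) / 2 (`x_axis = "ma"`) is also
#' available; note that with strong regulation it lets differential genes
#' shift along A and be partially absorbed by the smoother.
#'
#' If the abscissa values of a sample are (numerically) all equal, the
#' fit is degenerate and the sample falls back to subtracting median(M),
#' with a message.
#'
#' @param expr an [expression_matrix()].
#' @param reference per-gene reference profile; defaults to
#'   [median_reference()] of `expr`.
#' @param span LOWESS smoother span in (0, 1].
#' @param x_axis "reference" (default) or "ma".
#' @return an [expression_matrix()] of normalized intensities.
#' @export
lowess_normalize <- function(expr, reference = NULL, span = 0.3,
                             x_axis = c("reference", "ma")) {
  stopifnot(span > 0, span <= 1)
  x_axis <- match.arg(x_axis)
  if (is.null(reference)) reference <- median_reference(expr)
  if (!identical(names(reference), rownames(expr))) {
    reference <- reference[rownames(expr)]
  }
  if (any(is.na(reference)) || any(reference <= 0)) {
    stop("reference must be positive for every gene", call. = FALSE)
  }
  lr <- log2(reference)
  out <- unclass(expr)
  for (s in seq_len(ncol(out))) {
    ls <- log2(out[, s])
    m <- ls - lr
    a <- if (x_axis == "ma") (ls + lr) / 2 else lr
    ok <- is.finite(m) & is.finite(a)
    if (diff(range(a[ok])) < 1e-12) {
      message("sample '", colnames(out)[s],
              "': degenerate A values; median-of-M fallback")
      mhat <- rep(median(m[ok]), length(m))
    } else {
      fit <- lowess(a[ok], m[ok], f = span)
      mhat <- rep(NA_real_, length(m))
      mhat[ok] <- approx(fit$x, fit$y, xout = a[ok], rule = 2,
                         ties = mean)$y
    }
    out[, s] <- 2^(lr + m - mhat)
  }
  expression_matrix(out)
}

#' Log2 transform and median-center genes
#'
#' value\[g, s\] = log2(expr\[g, s\]) - median over samples of
#' log2(expr\[g, .\]). Every gene row of the result has median zero; this
#' is the scale used by profile clustering, group tests and the predictor.
#'
#' @param expr an [expression_matrix()] (normally LOWESS-normalized first).
#' @return a `normalized_matrix` (gene x sample, log2 median-centered).
#' @export
log_median_center <- function(expr) {
  lx <- log2(unclass(expr))
  ctr <- apply(lx, 1, median, na.rm = TRUE)
  structure(lx - ctr, class = c("normalized_matrix", "matrix", "array"))
}

#' One-call preprocessing: LOWESS normalize then log-median-center
#'
#' @inheritParams lowess_normalize
#' @return list with `unlogged` (LOWESS-normalized [expression_matrix()],
#'   the fold-change scale) and `norm` (log2 median-centered
#'   `normalized_matrix`, the clustering/testing scale).
#' @export
normalize_expression <- function(expr, span = 0.3,
                                 x_axis = c("reference", "ma")) {
  unlogged <- lowess_normalize(expr, span = span, x_axis = x_axis)
  list(unlogged = unlogged, norm = log_median_center(unlogged))
}
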
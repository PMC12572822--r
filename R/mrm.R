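#' Build a morphometric relatedness matrix (MRM)
#'
#' Standardizes every feature column (mean 0, variance 1, n-1 denominator) and
#' forms `A = Z Z' / p`, the n x n similarity between individuals over the
#' selected features; A is then trace-normalized so the diagonal mean is
#' exactly 1, which puts kernels from different feature sets on a common
#' variance scale. A is the covariance kernel of the morphometricity mixed
#' model.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param feature_subset optional index vector restricting the features used.
#' @param label kernel label (e.g. `"cortical"`, `"processingA"`).
#' @return An n x n matrix of class `"mrm"` with attributes `"source_p"`,
#'   `"label"` and `"sample_ids"`.
#' @export
build_mrm <- function(X, feature_subset = NULL, label = "all") {
  vals <- if (is_feature_matrix(X)) X$values else as.matrix(X)
  if (!is.null(feature_subset)) vals <- vals[, feature_subset, drop = FALSE]
  n <- nrow(vals)
  if (n < 3L) stop2("build_mrm: need at least 3 samples")
  sds <- apply(vals, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (all(const)) stop2("build_mrm: all selected features are constant")
  if (any(const)) {
    warning(sprintf("build_mrm: excluding %d constant feature(s)", sum(const)))
    vals <- vals[, !const, drop = FALSE]
  }
  p <- ncol(vals)
  if (p < 1L) stop2("build_mrm: no usable features")
  Z <- scale(vals)
  A <- tcrossprod(Z) / p
  A <- A * (n / sum(diag(A)))          # mean diagonal exactly 1
  A <- (A + t(A)) / 2
  structure(A, class = c("mrm", "matrix"), source_p = p, label = label,
            sample_ids = rownames(vals) %||% paste0("S", seq_len(n)))
}

#' @export
print.mrm <- function(x, ...) {
  cat(sprintf("<mrm> %d x %d similarity matrix ('%s', %d features)\n",
              nrow(x), ncol(x), attr(x, "label"), attr(x, "source_p")))
  invisible(x)
}
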
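#' Regress covariates out of every feature column
#'
#' Replaces every column by its least-squares residual on the covariate
#' design; residual columns are orthogonal to the design. Covariate adjustment
#' before computing cross-feature correlations avoids covariates inflating the
#' apparent correlation between brain measurements.
#'
#' @param X a [feature_matrix()] or plain numeric matrix.
#' @param C covariate design from [covariate_matrix()].
#' @return Object of the same type with residualized values.
#' @export
residualize <- function(X, C) {
  vals <- if (is_feature_matrix(X)) X$values else as.matrix(X)
  C <- as.matrix(C)
  if (nrow(vals) != nrow(C)) stop2("residualize: sample mismatch")
  qc <- qr(C)
  if (qc$rank < ncol(C)) stop2("residualize: rank-deficient covariate design")
  if (nrow(C) < qc$rank + 2L) stop2("residualize: too few samples for design")
  R <- qr.resid(qc, vals)
  if (is_feature_matrix(X)) { X$values <- R; X } else R
}

#' Rank-based inverse normal transformation
#'
#' Maps the within-column ranks through the standard normal quantile function
#' with the Blom offset `(rank - 3/8) / (n + 1/4)`; ties receive average ranks
#' (hence equal output values). The transform is monotone in the input and
#' removes skewness and excess kurtosis. Constant columns cannot be ranked
#' and are passed through unchanged with a warning.
#'
#' @param X a [feature_matrix()] or numeric matrix/vector.
#' @return Object of the same type, transformed column-wise.
#' @export
rint <- function(X) {
  one <- function(x) {
    if (length(unique(x)) < 2L) {
      warning("rint: constant column left unchanged")
      return(x)
    }
    r <- rank(x, ties.method = "average")
    stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  }
  if (is_feature_matrix(X)) { X$values <- apply(X$values, 2L, one); return(X) }
  if (is.matrix(X)) return(apply(X, 2L, one))
  one(X)
}
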
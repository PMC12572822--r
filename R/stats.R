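#' Bias-adjusted squared correlation
#'
#' The squared sample correlation overestimates the population value by about
#' `1/N`; the adjusted estimator `R2 - (1 - R2) / (N - 2)` removes that upward
#' bias. Equals `R2` exactly when `R2 = 1` and is never larger than `R2`.
#'
#' @param r2 squared correlation(s) in `[0, 1]` (vectorized).
#' @param n sample size used to estimate the correlation; must exceed 2.
#' @return Adjusted squared correlation (may be slightly negative).
#' @export
adjusted_r2 <- function(r2, n) {
  if (any(n <= 2)) stop2("adjusted_r2: need n > 2")
  if (any(r2 < 0 | r2 > 1)) stop2("adjusted_r2: r2 must be in [0, 1]")
  r2 - (1 - r2) / (n - 2)
}

#' Per-feature sum of adjusted squared correlations (sumR2)
#'
#' For every feature i, sums the bias-adjusted squared correlation with every
#' other feature (self-pair excluded): a summary of how correlated each
#' measurement is with the rest of the structural connectome. Dividing by the
#' number of features gives a value comparable across processings with
#' different p. Caller is expected to pass covariate-residualized features.
#'
#' @param X a [feature_matrix()] or numeric matrix of residualized features.
#' @param subsample optional number of rows to use (seeded uniform row
#'   subsample, emulating computing on a representative participant subset).
#' @param seed seed for the row subsample.
#' @param include_self if `TRUE`, follow the summation-over-all-j reading and
#'   include the constant self term (off by default; the self-pair carries no
#'   information about correlation with *other* measurements).
#' @return A data frame (one row per feature): `feature_id`, `skewness`,
#'   `kurtosis`, `sumr2`, `sumr2_per_p`, `n_used`.
#' @export
sum_r2 <- function(X, subsample = NULL, seed = 1L, include_self = FALSE) {
  vals <- if (is_feature_matrix(X)) X$values else as.matrix(X)
  if (!is.null(subsample) && subsample < nrow(vals)) {
    set.seed(seed)
    vals <- vals[sort(sample.int(nrow(vals), subsample)), , drop = FALSE]
  }
  n_used <- nrow(vals)
  if (n_used <= 3L) stop2("sum_r2: need more than 3 samples")
  p <- ncol(vals)
  r2 <- stats::cor(vals)^2
  adj <- adjusted_r2(r2, n_used)
  if (!include_self) diag(adj) <- 0 else diag(adj) <- 1
  s <- rowSums(adj)
  mom <- feature_moments(vals)
  data.frame(feature_id = colnames(vals) %||% paste0("F", seq_len(p)),
             skewness = mom$skewness, kurtosis = mom$kurtosis,
             sumr2 = s, sumr2_per_p = s / p, n_used = n_used,
             stringsAsFactors = FALSE)
}

#' Column-wise skewness and kurtosis
#'
#' Classical moment estimators: `skewness = m3 / m2^1.5` and (non-excess)
#' `kurtosis = m4 / m2^2` with central sample moments `mk` and no bias
#' correction, so a normal sample gives kurtosis near 3. Constant columns are
#' reported as `NA`.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @return A data frame with `feature_id`, `skewness`, `kurtosis` plus the
#'   medians across features as attributes `"median_skewness"` /
#'   `"median_kurtosis"`.
#' @export
feature_moments <- function(X) {
  vals <- if (is_feature_matrix(X)) X$values else as.matrix(X)
  mu <- colMeans(vals)
  Z <- sweep(vals, 2L, mu, "-")
  m2 <- colMeans(Z^2); m3 <- colMeans(Z^3); m4 <- colMeans(Z^4)
  const <- m2 <= 0
  sk <- ifelse(const, NA_real_, m3 / m2^1.5)
  ku <- ifelse(const, NA_real_, m4 / m2^2)
  out <- data.frame(feature_id = colnames(vals) %||% paste0("F", seq_len(ncol(vals))),
                    skewness = sk, kurtosis = ku, stringsAsFactors = FALSE)
  attr(out, "median_skewness") <- stats::median(sk, na.rm = TRUE)
  attr(out, "median_kurtosis") <- stats::median(ku, na.rm = TRUE)
  out
}
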
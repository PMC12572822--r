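#' Mass-univariate brain-wide association study
#'
#' Regresses the trait on every feature plus covariates (one linear model per
#' feature). Features are standardized to unit SD first, so effects are in
#' trait units per feature SD. Computation residualizes the trait and all
#' features on the covariates once and uses the algebraically identical
#' partial-regression form, with two-sided p values from the t reference with
#' `df = n - rank(C) - 1`.
#'
#' @param y trait vector.
#' @param X a [feature_matrix()] or numeric matrix.
#' @param C covariate design (or `NULL` for intercept only).
#' @return A data frame of class `"assoc_table"` with `feature_id`, `beta`,
#'   `se`, `z` (= beta/se), `p`, `n_used` and a `flagged` column marking
#'   features constant after residualization (reported with beta 0, p 1).
#' @export
run_bwas <- function(y, X, C = NULL) {
  vals <- if (is_feature_matrix(X)) X$values else as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(vals)
  if (length(y) != n) stop2("run_bwas: sample mismatch")
  if (is.null(C)) C <- covariate_matrix(NULL, n = n)
  C <- as.matrix(C)
  qc <- qr(C)
  df <- n - qc$rank - 1L
  if (df < 2L) stop2("run_bwas: too few complete cases for the design")
  sds <- apply(vals, 2L, stats::sd)
  sds[sds == 0] <- 1
  Z <- sweep(vals, 2L, sds, "/")
  ry <- qr.resid(qc, y)
  RX <- qr.resid(qc, Z)
  sxx <- colSums(RX^2)
  flagged <- sxx < 1e-12 * n
  sxx[flagged] <- 1
  beta <- colSums(RX * ry) / sxx
  rss <- sum(ry^2) - beta^2 * sxx
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / sxx)
  # an exact fit (zero residual) gets the most extreme representable z/p
  z <- ifelse(se > 0, beta / se,
              ifelse(beta == 0, 0, sign(beta) * sqrt(.Machine$double.xmax)))
  p <- 2 * stats::pt(-abs(z), df = df)
  beta[flagged] <- 0; se[flagged] <- NA_real_; z[flagged] <- 0; p[flagged] <- 1
  p <- pmax(p, .Machine$double.xmin)
  ids <- colnames(vals) %||% paste0("F", seq_len(ncol(vals)))
  out <- data.frame(feature_id = ids, beta = beta, se = se, z = z, p = p,
                    n_used = n, flagged = flagged, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("assoc_table", "data.frame")
  attr(out, "df") <- df
  out
}

#' Summaries of BWAS effect sizes
#'
#' @param assoc an `"assoc_table"` from [run_bwas()].
#' @return List with `median_abs_z` and `mean_abs_z` across all features.
#' @export
summarize_bwas <- function(assoc) {
  if (nrow(assoc) == 0L) stop2("summarize_bwas: empty association table")
  list(median_abs_z = stats::median(abs(assoc$z)),
       mean_abs_z = mean(abs(assoc$z)))
}

# Vectorized min-p across many null traits: residualize traits and features on
# the covariates once, convert partial correlations to t and p.
.null_minp <- function(vals, C, n_traits, seed) {
  n <- nrow(vals)
  qc <- qr(C)
  df <- n - qc$rank - 1L
  RX <- qr.resid(qc, vals)
  sxx <- colSums(RX^2)
  keep <- sxx > 1e-12 * n
  RX <- RX[, keep, drop = FALSE]
  sxx <- sxx[keep]
  set.seed(seed)
  minp <- numeric(n_traits)
  block <- max(1L, floor(2e7 / max(1L, ncol(RX))))
  done <- 0L
  while (done < n_traits) {
    m <- min(block, n_traits - done)
    Y <- matrix(stats::rnorm(n * m), n, m)
    RY <- qr.resid(qc, Y)
    syy <- colSums(RY^2)
    r <- crossprod(RX, RY) / sqrt(outer(sxx, syy))
    r2 <- pmin(r^2, 1 - 1e-15)
    tmax <- sqrt(df * apply(r2 / (1 - r2), 2L, max))
    minp[done + seq_len(m)] <- 2 * stats::pt(-tmax, df = df)
    done <- done + m
  }
  pmax(minp, .Machine$double.xmin)
}

#' Empirical FWER calibration from simulated null traits
#'
#' Simulates standard-normal traits unrelated to the features, runs the BWAS
#' for each (with the covariates still in the model), and records every
#' trait's minimum p value. The min-p sample is the basis for the empirical
#' family-wise error rate at any threshold and for the optimal (FWER = 5%)
#' threshold.
#'
#' @param X a [feature_matrix()] or matrix (QC'd features).
#' @param C covariate design (or `NULL`).
#' @param n_traits number of simulated null traits (default 1000).
#' @param seed RNG seed.
#' @param alpha level used for the Bonferroni threshold record.
#' @return An object of class `"null_calibration"`: `minp`, `n_traits`,
#'   `p_features`, `threshold_bonferroni = alpha / p_features`, `seed`.
#' @export
simulate_null_calibration <- function(X, C = NULL, n_traits = 1000L, seed = 1L,
                                      alpha = 0.05) {
  vals <- if (is_feature_matrix(X)) X$values else as.matrix(X)
  if (is.null(C)) C <- covariate_matrix(NULL, n = nrow(vals))
  if (n_traits < 100L)
    warning("simulate_null_calibration: fewer than 100 traits gives a wide FWER confidence interval")
  minp <- .null_minp(vals, as.matrix(C), n_traits, seed)
  structure(list(minp = minp, n_traits = n_traits, p_features = ncol(vals),
                 threshold_bonferroni = alpha / ncol(vals), seed = seed,
                 alpha = alpha),
            class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf("<null_calibration> %d simulated traits over %d features\n",
              x$n_traits, x$p_features))
  cat(sprintf("  Bonferroni threshold: %.3g;  FWER there: %.3f\n",
              x$threshold_bonferroni,
              fwer_at(x, x$threshold_bonferroni)$fwer))
  invisible(x)
}

#' Empirical FWER at a significance threshold
#'
#' Proportion of simulated null traits whose minimum p value falls below the
#' threshold, with the 95% normal-approximation binomial confidence interval.
#'
#' @param cal a [simulate_null_calibration()] result.
#' @param threshold significance threshold in `(0, 1)`.
#' @param level confidence level for the binomial CI.
#' @return List with `fwer`, `ci_lower`, `ci_upper`, `ci_halfwidth`.
#' @export
fwer_at <- function(cal, threshold, level = 0.95) {
  if (threshold <= 0 || threshold > 1)
    stop2("fwer_at: threshold must be in (0, 1]")
  ph <- mean(cal$minp < threshold)
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(ph * (1 - ph) / cal$n_traits)
  list(fwer = ph, ci_lower = max(0, ph - hw), ci_upper = min(1, ph + hw),
       ci_halfwidth = hw)
}

#' Optimal significance threshold for FWER = alpha
#'
#' The empirical alpha-quantile of the per-trait minimum p values: the
#' `floor(alpha * n_traits)`-th smallest min-p (order statistic), which is the
#' largest threshold guaranteeing a calibration-set FWER at or below alpha,
#' and calibrates FWER to approximately alpha on fresh null traits.
#'
#' @param cal a [simulate_null_calibration()] result.
#' @param alpha target FWER.
#' @param method `"order"` (k-th order statistic, default) or `"quantile"`
#'   (interpolating [stats::quantile()] type 7); the two differ by less than
#'   one rank.
#' @return The threshold (a probability).
#' @export
optimal_threshold <- function(cal, alpha = 0.05, method = c("order", "quantile")) {
  method <- match.arg(method)
  if (cal$n_traits < 1 / alpha)
    warning("optimal_threshold: fewer than 1/alpha null traits; the threshold is poorly resolved")
  if (method == "quantile")
    return(unname(stats::quantile(cal$minp, alpha, type = 7)))
  k <- max(1L, floor(alpha * cal$n_traits))
  sort(cal$minp)[k]
}

#' Quantile-quantile plot data
#'
#' For an association table, observed sorted -log10 p against the uniform
#' expectation. For a null calibration, observed sorted minimum p values
#' against the Beta(1, p_features) quantiles of the minimum of p independent
#' uniforms (the independence reference; correlated features push the curve
#' below it). Emitted for plotting only.
#'
#' @param x an `"assoc_table"` or `"null_calibration"`.
#' @return Data frame with `expected_log10p` and `observed_log10p`.
#' @export
qq_data <- function(x) {
  if (inherits(x, "null_calibration")) {
    obs <- sort(x$minp)
    q <- (seq_along(obs) - 0.5) / length(obs)
    expd <- stats::qbeta(q, 1, x$p_features)
  } else {
    obs <- sort(x$p)
    expd <- (seq_along(obs) - 0.5) / length(obs)
  }
  data.frame(expected_log10p = -log10(expd), observed_log10p = -log10(obs))
}
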
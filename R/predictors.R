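#' Linear brain-based predictor
#'
#' A set of feature weights (trait units per feature SD) plus the training
#' standardization parameters (per-feature mean and SD from the TRAINING
#' sample only). Built either from BWAS weights over selected features
#' ([build_predictor()]) or from the whole feature set via BLUP
#' ([blup_predictor()]).
#'
#' @name linear_predictor
NULL

new_linear_predictor <- function(feature_id, weight, train_mean, train_sd,
                                 rule) {
  stopifnot(all(is.finite(weight)))
  structure(list(feature_id = feature_id, weight = weight,
                 train_mean = train_mean, train_sd = train_sd, rule = rule,
                 empty = length(feature_id) == 0L),
            class = "linear_predictor")
}

#' @export
print.linear_predictor <- function(x, ...) {
  cat(sprintf("<linear_predictor> rule '%s', %d feature(s)%s\n", x$rule,
              length(x$feature_id), if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Build a linear predictor from BWAS results
#'
#' Selection rules: `"top_per_cluster"` keeps the most significant feature of
#' each cluster (its BWAS beta as weight); `"all_significant"` keeps every
#' significant feature; `"size_one_only"` keeps the features of size-one
#' clusters only.
#'
#' @param assoc discovery `"assoc_table"`.
#' @param cs [find_clusters()] result from the same discovery run.
#' @param X_train training [feature_matrix()] (standardization source).
#' @param rule selection rule.
#' @return A `"linear_predictor"`; empty selections are flagged, not an error.
#' @export
build_predictor <- function(assoc, cs, X_train,
                            rule = c("top_per_cluster", "all_significant",
                                     "size_one_only")) {
  rule <- match.arg(rule)
  vals <- if (is_feature_matrix(X_train)) X_train$values else as.matrix(X_train)
  idx <- switch(rule,
    top_per_cluster = vapply(cs$clusters, `[[`, numeric(1), "top_feature"),
    all_significant = cs$signif,
    size_one_only = unlist(lapply(cs$clusters, function(cl)
      if (cl$size == 1L) cl$members else integer(0))))
  idx <- as.integer(idx)
  if (length(idx) == 0L)
    return(new_linear_predictor(character(0), numeric(0), numeric(0),
                                numeric(0), rule))
  ids <- assoc$feature_id[idx]
  new_linear_predictor(ids, assoc$beta[idx], colMeans(vals[, idx, drop = FALSE]),
                       apply(vals[, idx, drop = FALSE], 2L, stats::sd), rule)
}

#' Score individuals with a linear predictor
#'
#' `score = sum_i w_i * (x_i - train_mean_i) / train_sd_i`. Features are
#' standardized with the TRAINING parameters; a feature missing from the new
#' data is a hard error (no imputation).
#'
#' @param object a `"linear_predictor"`.
#' @param X_new a [feature_matrix()] or matrix with named columns.
#' @param standardize standardize with training parameters (default `TRUE`;
#'   `FALSE` uses raw feature values).
#' @param ... ignored.
#' @return Numeric score per sample.
#' @export
predict.linear_predictor <- function(object, X_new, standardize = TRUE, ...) {
  vals <- if (is_feature_matrix(X_new)) X_new$values else as.matrix(X_new)
  if (object$empty) return(rep(0, nrow(vals)))
  miss <- setdiff(object$feature_id, colnames(vals))
  if (length(miss) > 0L)
    stop2("predict: features absent from new data: ",
          paste(utils::head(miss, 5L), collapse = ", "),
          if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L) else "")
  Z <- vals[, object$feature_id, drop = FALSE]
  if (standardize) {
    sd_safe <- ifelse(object$train_sd > 0, object$train_sd, 1)
    Z <- sweep(sweep(Z, 2L, object$train_mean, "-"), 2L, sd_safe, "/")
  }
  drop(Z %*% object$weight)
}

#' Best linear unbiased predictor from a morphometricity fit
#'
#' Converts the fitted single-kernel mixed model into per-feature weights:
#' with `W` the training features standardized (training mean/SD) and scaled
#' by `1/sqrt(p)` so that `A = W W'`, the weights are
#' `u = sigma_g^2 W' V^{-1} (y - C beta)`. Scoring new data with these
#' weights is algebraically identical to the kernel form
#' `g* = A_{*,train} (A + lambda I)^{-1} (y - C beta)` with
#' `lambda = sigma_e^2 / sigma_g^2`.
#'
#' @param fit a converged single-kernel [morpho()] fit with stored kernels.
#' @param X_train the training [feature_matrix()] the kernel was built from.
#' @return A `"linear_predictor"` with rule `"blup"`. When `sigma_g^2` is at
#'   its floor the predictor is all-zero, with a warning.
#' @export
blup_predictor <- function(fit, X_train) {
  if (length(fit$m2) != 1L) stop2("blup_predictor: single-kernel fit required")
  if (is.null(fit$y)) stop2("blup_predictor: fit was made with store_kernels = FALSE")
  vals <- if (is_feature_matrix(X_train)) X_train$values else as.matrix(X_train)
  p <- ncol(vals)
  mu <- colMeans(vals)
  sds <- apply(vals, 2L, stats::sd)
  s2g <- fit$sigma2[[1]]; s2e <- fit$sigma2[["residual"]]
  ids <- colnames(vals) %||% paste0("F", seq_len(p))
  if (s2g <= 1e-6 * (s2g + s2e)) {
    warning("blup_predictor: sigma_g^2 is at the boundary; returning a zero predictor")
    return(new_linear_predictor(ids, rep(0, p), mu, sds, "blup"))
  }
  # W chosen so that W W' is the trace-normalized kernel (mean diagonal 1),
  # matching the MRM construction; then A = W W' and u = s2g W' V^-1 r.
  Z <- sweep(sweep(vals, 2L, mu, "-"), 2L, ifelse(sds > 0, sds, 1), "/")
  sc <- sqrt(nrow(vals) / sum(Z^2))
  W <- Z * sc
  r <- fit$y - drop(fit$C %*% fit$beta)
  Vi_r <- .solve_v(fit$kernels, fit$sigma2, r)
  u <- s2g * drop(crossprod(W, Vi_r))
  # weights apply to standardized features, so fold the W scaling back in
  new_linear_predictor(ids, u * sc, mu, sds, "blup")
}

# Kernel-form BLUP scores for new samples (used by the dual-identity check).
blup_scores_kernel <- function(fit, X_train, X_new) {
  vt <- if (is_feature_matrix(X_train)) X_train$values else as.matrix(X_train)
  vn <- if (is_feature_matrix(X_new)) X_new$values else as.matrix(X_new)
  mu <- colMeans(vt)
  sds <- apply(vt, 2L, stats::sd)
  sds <- ifelse(sds > 0, sds, 1)
  Zt <- sweep(sweep(vt, 2L, mu, "-"), 2L, sds, "/")
  sc <- sqrt(nrow(vt) / sum(Zt^2))
  Wt <- Zt * sc
  Wn <- sweep(sweep(vn[, colnames(vt), drop = FALSE], 2L, mu, "-"), 2L, sds, "/") * sc
  A <- tcrossprod(Wt)
  Across <- tcrossprod(Wn, Wt)
  s2g <- fit$sigma2[[1]]; s2e <- fit$sigma2[["residual"]]
  lambda <- s2e / s2g
  r <- fit$y - drop(fit$C %*% fit$beta)
  drop(Across %*% solve(A + diag(lambda, nrow(A)), r))
}

#' Evaluate a predictor on held-out data
#'
#' Incremental R2 of the scores over the covariates: the difference in R2
#' between the nested least-squares fits `y ~ C + score` and `y ~ C`, with a
#' likelihood-ratio test `n * log(RSS_reduced / RSS_full)` against chi2 with
#' 1 df.
#'
#' @param scores per-sample predictor scores.
#' @param y_eval evaluation trait.
#' @param C_eval evaluation covariate design (or `NULL`).
#' @return List of class `"prediction_eval"`: `r2` (incremental), `lrt_p`,
#'   `n_eval`.
#' @export
evaluate_prediction <- function(scores, y_eval, C_eval = NULL) {
  y <- as.numeric(y_eval)
  n <- length(y)
  if (is.null(C_eval)) C_eval <- covariate_matrix(NULL, n = n)
  C_eval <- as.matrix(C_eval)
  if (n <= qr(C_eval)$rank + 2L) stop2("evaluate_prediction: too few samples")
  if (stats::sd(scores) == 0)
    return(structure(list(r2 = 0, lrt_p = 1, n_eval = n),
                     class = "prediction_eval"))
  qc <- qr(C_eval)
  rss_red <- sum(qr.resid(qc, y)^2)
  rss_full <- sum(qr.resid(qr(cbind(C_eval, score = scores)), y)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- max(0, (rss_red - rss_full) / tss)
  lrt <- n * log(rss_red / rss_full)
  structure(list(r2 = r2,
                 lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 n_eval = n),
            class = "prediction_eval")
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat(sprintf("<prediction_eval> incremental R2 = %.4f (LRT p = %.3g, n = %d)\n",
              x$r2, x$lrt_p, x$n_eval))
  invisible(x)
}

#' Fraction of morphometricity captured by a predictor
#'
#' `r2 / m2` using the evaluation-sample morphometricity as denominator
#' (the discovery-sample denominator is a caller choice: pass that fit
#' instead). Undefined (NA) when the morphometricity is not significantly
#' positive.
#'
#' @param eval a [evaluate_prediction()] result.
#' @param vc_eval a [morpho()] fit on the evaluation sample.
#' @param alpha significance level required of the morphometricity LRT.
#' @return The ratio, or `NA` when `m2` is zero or not significant.
#' @export
fraction_predicted <- function(eval, vc_eval, alpha = 0.05) {
  m2 <- sum(vc_eval$m2)
  if (!is.finite(m2) || m2 <= 0) return(NA_real_)
  if (is.finite(vc_eval$lrt_p) && vc_eval$lrt_p >= alpha) return(NA_real_)
  eval$r2 / m2
}

#' BLUP prediction from a morphometricity fit
#'
#' Convenience method: builds the BLUP weights from the training features and
#' scores the new samples. `form = "kernel"` uses the similarity-matrix form
#' instead of explicit per-feature weights; the two agree to numerical
#' precision.
#'
#' @param object a converged single-kernel [morpho()] fit.
#' @param X_train training [feature_matrix()].
#' @param X_new [feature_matrix()] to score (defaults to the training data).
#' @param form `"primal"` (feature weights) or `"kernel"`.
#' @param ... ignored.
#' @return Numeric score per sample of `X_new`.
#' @export
predict.morpho <- function(object, X_train, X_new = X_train,
                           form = c("primal", "kernel"), ...) {
  form <- match.arg(form)
  if (form == "kernel") return(blup_scores_kernel(object, X_train, X_new))
  predict(blup_predictor(object, X_train), X_new)
}
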
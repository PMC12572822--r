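#' Fit the morphometricity mixed model by REML
#'
#' Estimates how much trait variance is jointly captured by all brain
#' features: the model is `y = C beta + g + e` with `g ~ N(0, sigma_g^2 A)`
#' and `e ~ N(0, sigma_e^2 I)`, where A is a morphometric relatedness matrix
#' from [build_mrm()]. Morphometricity is
#' `m2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`. With a single kernel the
#' restricted likelihood is maximized exactly by a 1-D profile search on the
#' eigenbasis of A projected off the covariates; with several kernels
#' (brain-part decomposition, or features from two processings fitted
#' jointly) average-information REML with EM fallback steps is used, with
#' components constrained to be non-negative.
#'
#' @param y a [trait_vector()] or numeric vector.
#' @param mrm a single `"mrm"` matrix or a list of them (multi-kernel fit).
#' @param C covariate design from [covariate_matrix()]; intercept-only design
#'   is used when `NULL`.
#' @param max_iter,tol AI-REML iteration cap and `|delta logL|` convergence
#'   tolerance.
#' @param store_kernels keep kernels/covariates in the fit (needed by
#'   [predict.morpho()], [simulate.morpho()] and [blup_predictor()]).
#' @return An object of class `"morpho"`: variance components (`sigma2`,
#'   named per kernel plus `"residual"`), per-kernel variance fractions
#'   (`m2`), standard errors, restricted log-likelihoods under the full and
#'   null model, the boundary-corrected likelihood-ratio p value, GLS fixed
#'   effects and convergence information.
#' @export
morpho <- function(y, mrm, C = NULL, max_iter = 100L, tol = 1e-6,
                   store_kernels = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  kernels <- if (is.list(mrm)) mrm else list(mrm)
  K <- length(kernels)
  labels <- vapply(seq_len(K), function(k)
    attr(kernels[[k]], "label") %||% paste0("kernel", k), character(1))
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  for (A in kernels) {
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      stop2("morpho: kernel dimension does not match trait length")
  }
  if (K > 1L) .check_proportional(kernels)
  if (is.null(C)) C <- covariate_matrix(NULL, n = n)
  C <- as.matrix(C)
  qc <- qr(C)
  if (qc$rank < ncol(C)) {
    # drop redundant columns (e.g. a covariate supplied twice)
    C <- C[, qc$pivot[seq_len(qc$rank)], drop = FALSE]
    qc <- qr(C)
  }
  if (n < qc$rank + 5L) stop2("morpho: too few complete cases")
  fit <- if (K == 1L)
    .reml_single(y, kernels[[1]], C, tol = tol)
  else
    .reml_ai(y, kernels, C, max_iter = max_iter, tol = tol)
  names(fit$sigma2) <- c(labels, "residual")
  tot <- sum(fit$sigma2)
  m2 <- fit$sigma2[seq_len(K)] / tot
  se_m2 <- .delta_m2_se(fit$sigma2, fit$vcov)
  structure(list(sigma2 = fit$sigma2, m2 = m2, se_m2 = se_m2,
                 vcov = fit$vcov, logL = fit$logL, logL0 = fit$logL0,
                 lrt_p = fit$lrt_p, beta = fit$beta, n = n,
                 n_iter = fit$n_iter, converged = fit$converged,
                 labels = labels,
                 kernels = if (store_kernels) kernels,
                 C = if (store_kernels) C,
                 y = if (store_kernels) y),
            class = "morpho")
}

.check_proportional <- function(kernels) {
  K <- length(kernels)
  for (a in seq_len(K - 1L)) for (b in seq((a + 1L), K)) {
    A <- kernels[[a]] / sqrt(sum(kernels[[a]]^2))
    B <- kernels[[b]] / sqrt(sum(kernels[[b]]^2))
    if (sum((A - B)^2) < 1e-10)
      stop2(sprintf("morpho: kernels %d and %d are proportional; the model is unidentifiable", a, b))
  }
}

# ---- single kernel: exact profile REML on the eigenbasis ------------------

.reml_single <- function(y, A, C, tol = 1e-6) {
  n <- length(y)
  c_rank <- qr(C)$rank
  m <- n - c_rank
  Qfull <- qr.Q(qr(C), complete = TRUE)
  Tm <- Qfull[, (c_rank + 1L):n, drop = FALSE]   # error-contrast basis
  M <- crossprod(Tm, A %*% Tm)
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  lam <- ee$values
  if (max(lam) - min(lam) < 1e-6)
    stop2("morpho: kernel is (numerically) proportional to the identity; morphometricity is unidentifiable")
  w2 <- drop(crossprod(ee$vectors, crossprod(Tm, y)))^2
  # profile restricted log-likelihood of phi = sigma_g^2 / sigma_e^2
  prof <- function(phi) {
    d <- phi * lam + 1
    s2e <- mean(w2 / d)
    -0.5 * (sum(log(d)) + m * log(s2e) + m + m * log(2 * pi))
  }
  opt <- stats::optimize(function(t) -prof(t / (1 - t)),
                         interval = c(0, 1 - 1e-9), tol = 1e-12)
  phi <- opt$minimum / (1 - opt$minimum)
  logL <- prof(phi)
  logL0 <- prof(0)
  if (logL0 >= logL) { phi <- 0; logL <- logL0 }
  d <- phi * lam + 1
  s2e <- mean(w2 / d)
  s2g <- phi * s2e
  v <- s2g * lam + s2e
  # expected (Fisher) information for (sigma_g^2, sigma_e^2)
  I <- 0.5 * matrix(c(sum((lam / v)^2), sum(lam / v^2),
                      sum(lam / v^2), sum(1 / v^2)), 2L, 2L)
  vcov <- tryCatch(solve(I), error = function(e) matrix(NA_real_, 2L, 2L))
  lrt_stat <- max(0, 2 * (logL - logL0))
  lrt_p <- if (lrt_stat <= 0) 1 else
    min(1, 0.5 * stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE))
  # GLS fixed effects at the REML estimates
  Vi_y <- .solve_v(list(A), c(s2g, s2e), y)
  Vi_C <- .solve_v(list(A), c(s2g, s2e), C)
  beta <- drop(solve(crossprod(C, Vi_C), crossprod(C, Vi_y)))
  names(beta) <- colnames(C)
  list(sigma2 = c(s2g, s2e), vcov = vcov, logL = logL, logL0 = logL0,
       lrt_p = lrt_p, beta = beta, n_iter = 1L, converged = TRUE)
}

.solve_v <- function(kernels, sigma2, rhs) {
  n <- nrow(kernels[[1]])
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(kernels)) V <- V + sigma2[k] * kernels[[k]]
  solve(V, rhs)
}

# ---- multiple kernels: average-information REML ---------------------------

.reml_ai <- function(y, kernels, C, max_iter = 100L, tol = 1e-6) {
  n <- length(y)
  K <- length(kernels)
  vy <- stats::var(y)
  floor_v <- 1e-8 * vy

  # restricted log-likelihood and the quantities shared by score/AI updates
  state_at <- function(theta) {
    V <- diag(theta[K + 1L], n)
    for (k in seq_len(K)) V <- V + theta[k] * kernels[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViC <- Vi %*% C
    CtViC <- crossprod(C, ViC)
    P <- Vi - ViC %*% solve(CtViC, t(ViC))
    Py <- drop(P %*% y)
    logL <- -0.5 * (2 * sum(log(diag(ch))) + determinant(CtViC)$modulus[1] +
                      sum(y * Py) + (n - ncol(C)) * log(2 * pi))
    list(P = P, Py = Py, logL = logL)
  }

  # start from the best of a few variance splits (cheap insurance against the
  # poor local solutions near-collinear kernels can produce)
  starts <- list(rep(vy / (K + 1L), K + 1L),
                 c(rep(vy * 0.1 / K, K), vy * 0.9),
                 c(rep(vy * 0.6 / K, K), vy * 0.4))
  theta <- NULL; st <- NULL
  for (s in starts) {
    cand <- state_at(s)
    if (!is.null(cand) && (is.null(st) || cand$logL > st$logL)) {
      st <- cand; theta <- s
    }
  }
  if (is.null(st)) stop2("morpho: could not evaluate the restricted likelihood")
  converged <- FALSE
  AI <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    APy <- vector("list", K + 1L)
    for (k in seq_len(K)) APy[[k]] <- drop(kernels[[k]] %*% Py)
    APy[[K + 1L]] <- Py
    score <- numeric(K + 1L)
    for (k in seq_len(K))
      score[k] <- -0.5 * (sum(P * kernels[[k]]) - sum(Py * APy[[k]]))
    score[K + 1L] <- -0.5 * (sum(diag(P)) - sum(Py * Py))
    PAPy <- lapply(APy, function(a) drop(P %*% a))
    AI <- matrix(0, K + 1L, K + 1L)
    for (j in seq_len(K + 1L)) for (k in j:(K + 1L)) {
      AI[j, k] <- 0.5 * sum(APy[[j]] * PAPy[[k]])
      AI[k, j] <- AI[j, k]
    }
    # components pinned at the floor with a downhill score stay put
    active <- theta <= floor_v & score < 0
    step <- tryCatch({
      s <- numeric(K + 1L)
      free <- !active
      s[free] <- solve(AI[free, free, drop = FALSE], score[free])
      s
    }, error = function(e) NULL)
    if (is.null(step) || iter == 1L) {
      # EM update: guaranteed uphill, slow but safe
      em <- numeric(K + 1L)
      for (k in seq_len(K))
        em[k] <- theta[k]^2 * (sum(Py * APy[[k]]) - sum(P * kernels[[k]])) / n
      em[K + 1L] <- theta[K + 1L]^2 * (sum(Py * Py) - sum(diag(P))) / n
      step <- em
    }
    # monotone line search with projection onto the feasible region
    improved <- FALSE
    for (half in 0:25) {
      theta_try <- pmax(theta + step / 2^half, floor_v)
      st_try <- state_at(theta_try)
      if (!is.null(st_try) && st_try$logL >= st$logL - 1e-10) {
        improved <- TRUE
        break
      }
    }
    if (!improved) { converged <- TRUE; break }   # no uphill move left
    delta <- st_try$logL - st$logL
    theta <- theta_try
    st <- st_try
    if (delta < tol && iter > 1L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("morpho: AI-REML did not converge within max_iter")
  V <- diag(theta[K + 1L], n)
  for (k in seq_len(K)) V <- V + theta[k] * kernels[[k]]
  Vi <- chol2inv(chol(V))
  ViC <- Vi %*% C
  beta <- drop(solve(crossprod(C, ViC), crossprod(ViC, y)))
  names(beta) <- colnames(C)
  vcov <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, K + 1L, K + 1L))
  list(sigma2 = theta, vcov = vcov, logL = st$logL, logL0 = NA_real_,
       lrt_p = NA_real_, beta = beta, n_iter = iter, converged = converged)
}

.delta_m2_se <- function(sigma2, vcov) {
  K <- length(sigma2) - 1L
  tot <- sum(sigma2)
  se <- rep(NA_real_, K)
  if (any(!is.finite(vcov))) return(se)
  for (k in seq_len(K)) {
    grad <- rep(-sigma2[k] / tot^2, K + 1L)
    grad[k] <- (tot - sigma2[k]) / tot^2
    se[k] <- sqrt(max(0, drop(t(grad) %*% vcov %*% grad)))
  }
  se
}

# ---- methods ---------------------------------------------------------------

#' @export
print.morpho <- function(x, digits = 4, ...) {
  K <- length(x$m2)
  cat("Morphometricity mixed model (REML)\n")
  cat(sprintf("  n = %d, %d kernel(s)%s\n", x$n, K,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  for (k in seq_len(K))
    cat(sprintf("  m2[%s] = %.*f (SE %.*f)\n", x$labels[k], digits, x$m2[k],
                digits, x$se_m2[k]))
  if (is.finite(x$lrt_p))
    cat(sprintf("  LRT p (sigma_g^2 = 0, 0.5*chi2_0 + 0.5*chi2_1): %.3g\n",
                x$lrt_p))
  invisible(x)
}

#' @export
summary.morpho <- function(object, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci_lo <- pmax(0, object$m2 - z * object$se_m2)
  ci_hi <- pmin(1, object$m2 + z * object$se_m2)
  out <- list(fit = object,
              table = data.frame(kernel = object$labels,
                                 sigma2 = object$sigma2[seq_along(object$m2)],
                                 m2 = object$m2, se_m2 = object$se_m2,
                                 ci_lower = ci_lo, ci_upper = ci_hi,
                                 row.names = NULL),
              sigma2_residual = unname(object$sigma2[length(object$sigma2)]),
              logL = object$logL, logL0 = object$logL0, lrt_p = object$lrt_p,
              level = level)
  class(out) <- "summary.morpho"
  out
}

#' @export
print.summary.morpho <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %.0f%% CI (truncated to [0,1]):\n", 100 * x$level))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.morpho <- function(object, ...) object$beta

#' @export
logLik.morpho <- function(object, ...) {
  structure(object$logL, df = length(object$sigma2) + length(object$beta),
            class = "logLik")
}

#' Residuals of a morphometricity fit
#'
#' `"marginal"` residuals are `y - C beta`; `"conditional"` residuals
#' additionally subtract the BLUP of the random effect g.
#'
#' @param object a [morpho()] fit with stored kernels.
#' @param type `"marginal"` or `"conditional"`.
#' @param ... ignored.
#' @export
residuals.morpho <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  if (is.null(object$y)) stop2("residuals: fit was made with store_kernels = FALSE")
  r <- object$y - drop(object$C %*% object$beta)
  if (type == "marginal") return(r)
  K <- length(object$kernels)
  Vi_r <- .solve_v(object$kernels, object$sigma2, r)
  ghat <- rep(0, object$n)
  for (k in seq_len(K))
    ghat <- ghat + object$sigma2[k] * drop(object$kernels[[k]] %*% Vi_r)
  r - ghat
}

#' Simulate traits from a fitted morphometricity model
#'
#' Draws `y* = C beta + sum_k g_k + e` with `g_k ~ N(0, sigma_k^2 A_k)`.
#'
#' @param object a [morpho()] fit with stored kernels.
#' @param nsim number of simulated traits.
#' @param seed optional RNG seed.
#' @param ... ignored.
#' @return A matrix with `nsim` columns.
#' @export
simulate.morpho <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$kernels))
    stop2("simulate: fit was made with store_kernels = FALSE")
  n <- object$n
  K <- length(object$kernels)
  V <- diag(object$sigma2[K + 1L], n)
  for (k in seq_len(K)) V <- V + object$sigma2[k] * object$kernels[[k]]
  ch <- chol(V + diag(1e-10 * mean(diag(V)), n))
  mu <- drop(object$C %*% object$beta)
  mu + crossprod(ch, matrix(stats::rnorm(n * nsim), n, nsim))
}
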
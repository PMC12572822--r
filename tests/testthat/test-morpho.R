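test_that("the MRM is a valid trace-normalized similarity matrix", {
  X <- rand_features(60, c(5, 4, 3), seed = 2)
  A <- build_mrm(X)
  expect_lt(max(abs(A - t(A))), 1e-10)
  expect_equal(mean(diag(A)), 1, tolerance = 1e-10)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(A)) / nrow(A))
  # single standardized feature: rank-1 outer product
  z <- scale(X$values[, 1])
  A1 <- build_mrm(X, feature_subset = 1)
  expect_equal(unclass(A1), tcrossprod(z) * (60 / sum(z^2)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(abs(eigen(A1)$values) > 1e-8), 1)
})

test_that("duplicated individuals are maximally similar; independent blocks are not", {
  set.seed(3)
  p <- 300
  vals <- matrix(rnorm(30 * p), 30, p)
  vals[2, ] <- vals[1, ]                       # identical twin rows
  A <- build_mrm(vals)
  expect_equal(A[1, 2], A[1, 1], tolerance = 1e-10)
  # samples carry independent features: off-diagonal entries are random-matrix
  # small, |A_ij| < 3/sqrt(p) on average
  B <- build_mrm(matrix(rnorm(40 * p), 40, p))
  expect_lt(mean(abs(B[upper.tri(B)])), 3 / sqrt(p))
  expect_warning(build_mrm(cbind(rnorm(10), rep(1, 10))), "constant")
  expect_error(build_mrm(matrix(1, 10, 3)), "constant")
})

test_that("single-kernel REML matches a brute-force profiled-likelihood grid", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 50
    X <- matrix(rnorm(n * 5), n, 5)
    A <- build_mrm(X)
    C <- covariate_matrix(data.frame(a = rnorm(n)))
    y <- rnorm(n) + 0.5 * scale(X[, 1])
    fit <- morpho(y, A, C)
    # oracle: profile out sigma_e^2 on a ratio grid of resolution 1e-4 and
    # evaluate the restricted likelihood from its definition
    qc <- qr(C)
    Tm <- qr.Q(qr(C), complete = TRUE)[, (qc$rank + 1):n]
    M <- crossprod(Tm, A %*% Tm)
    lam <- eigen((M + t(M)) / 2, symmetric = TRUE)$values
    w2 <- drop(crossprod(eigen((M + t(M)) / 2, symmetric = TRUE)$vectors,
                         crossprod(Tm, y)))^2
    m <- n - qc$rank
    logL_at <- function(phi) {
      d <- phi * lam + 1
      s2e <- mean(w2 / d)
      -0.5 * (sum(log(d)) + m * log(s2e) + m + m * log(2 * pi))
    }
    grid <- seq(0, 5, by = 1e-4)
    best <- max(vapply(grid, logL_at, numeric(1)))
    expect_lt(abs(fit$logL - best), 1e-6)
    expect_gte(fit$logL, best - 1e-9)
  }
})

test_that("REML recovers a planted morphometricity and its uncertainty", {
  m2_hat <- cover <- numeric(6)
  for (i in seq_len(6)) {
    cfg <- sim_config(400, c(10, 8, 5), smoothing_fwhm = 2, target_m2 = 0.3,
                      seed = 100 + i)
    C <- simulate_covariates(400, cfg$covariate_spec, seed = 200 + i)
    X <- simulate_features(cfg, C)
    y <- simulate_trait(X, C, cfg)
    fit <- morpho(y, build_mrm(X), C, store_kernels = FALSE)
    m2_hat[i] <- fit$m2
    cover[i] <- abs(fit$m2 - 0.3) <= 1.96 * fit$se_m2
  }
  expect_lt(abs(mean(m2_hat) - 0.3), 0.08)
  expect_gte(mean(cover), 0.5)
})

test_that("the morphometricity LRT controls type I error at the boundary null", {
  ps <- m2s <- numeric(150)
  for (i in seq_along(ps)) {
    set.seed(3000 + i)
    n <- 100
    X <- matrix(rnorm(n * 150), n, 150)
    y <- rnorm(n)
    fit <- morpho(y, build_mrm(X), store_kernels = FALSE)
    ps[i] <- fit$lrt_p
    m2s[i] <- fit$m2
  }
  # boundary mixture: about half the fits sit at m2 = 0 (p = 1); rejections at
  # level alpha stay near alpha
  expect_lt(mean(ps < 0.05), 0.05 + 2.5 * sqrt(0.05 * 0.95 / length(ps)))
  expect_gt(mean(ps < 0.2), 0.2 - 3 * sqrt(0.2 * 0.8 / length(ps)))
  expect_lt(mean(m2s), 0.2)
})

test_that("morphometricity is invariant to trait scale and redundant covariates", {
  cfg <- sim_config(150, c(6, 5, 4), smoothing_fwhm = 1.5, target_m2 = 0.4,
                    seed = 5)
  C <- simulate_covariates(150, cfg$covariate_spec, seed = 6)
  X <- simulate_features(cfg, C)
  y <- simulate_trait(X, C, cfg)
  A <- build_mrm(X)
  f1 <- morpho(y, A, C, store_kernels = FALSE)
  f2 <- morpho(as.numeric(y) * 3, A, C, store_kernels = FALSE)
  expect_equal(f2$m2, f1$m2, tolerance = 1e-6)
  expect_equal(f2$se_m2, f1$se_m2, tolerance = 1e-5)
  expect_equal(f2$lrt_p, f1$lrt_p, tolerance = 1e-6)
  expect_equal(unname(f2$sigma2), unname(f1$sigma2) * 9, tolerance = 1e-5)
  f3 <- morpho(y, A, cbind(C, again = C[, 2]), store_kernels = FALSE)
  expect_equal(f3$m2, f1$m2, tolerance = 1e-8)
  # near-normal synthetic data: RINT of the features barely moves the estimate
  f4 <- morpho(y, build_mrm(rint(X)), C, store_kernels = FALSE)
  expect_lt(abs(f4$m2 - f1$m2), 2 * f1$se_m2)
})

test_that("identity-like kernels are rejected as unidentifiable", {
  y <- rnorm(30)
  A <- diag(30)
  class(A) <- c("mrm", "matrix")
  expect_error(morpho(y, A), "unidentifiable")
})

test_that("multi-kernel REML decomposes variance across disjoint feature sets", {
  # proportional kernels are detected
  X <- rand_features(50, c(5, 4, 3), seed = 9)
  A <- build_mrm(X)
  expect_error(morpho(rnorm(50), list(A, A)), "proportional")

  cfg <- sim_config(500, c(10, 8, 5), smoothing_fwhm = 0, target_m2 = 0.3,
                    seed = 31)
  C <- simulate_covariates(500, cfg$covariate_spec, seed = 32)
  X <- simulate_features(cfg, C)
  p <- ncol(X$values)
  set.seed(33)
  # plant 0.2 on the first half, 0.1 on the second half of the features
  Z1 <- scale(X$values[, 1:(p / 2)])
  Z2 <- scale(X$values[, (p / 2 + 1):p])
  g1 <- drop(Z1 %*% rnorm(p / 2)); g1 <- g1 / sd(g1) * sqrt(0.2)
  g2 <- drop(Z2 %*% rnorm(p / 2)); g2 <- g2 / sd(g2) * sqrt(0.1)
  e <- rnorm(500); e <- e / sd(e) * sqrt(0.7)
  y <- g1 + g2 + e
  A1 <- build_mrm(X, 1:(p / 2), label = "first")
  A2 <- build_mrm(X, (p / 2 + 1):p, label = "second")
  fit <- morpho(y, list(A1, A2), C)
  expect_true(fit$converged)
  expect_equal(unname(fit$m2[1]), 0.2, tolerance = 0.5)
  expect_equal(unname(fit$m2[2]), 0.1, tolerance = 0.8)
  expect_equal(sum(fit$m2) + fit$sigma2[["residual"]] / sum(fit$sigma2), 1,
               tolerance = 1e-6)
  # a kernel with no planted signal gets a near-zero share
  ynull <- g1 + e
  fit0 <- morpho(ynull / sd(ynull), list(A1, A2), C)
  expect_lt(unname(fit0$m2[2]), 0.08)
})

test_that("shared/unique analysis attributes joint variance correctly", {
  cfg <- sim_config(400, c(10, 8, 5), smoothing_fwhm = 0, target_m2 = 0.3,
                    seed = 41)
  C <- simulate_covariates(400, cfg$covariate_spec, seed = 42)
  X <- simulate_features(cfg, C)
  y <- simulate_trait(X, C, cfg)
  p <- ncol(X$values)
  A_all <- build_mrm(X, label = "all")
  # a second kernel carrying the same features (after a monotone transform)
  # tags the same variance: ratios ~ 1
  A_same <- build_mrm(rint(X), label = "same")
  su_same <- shared_unique(y, A_all, A_same, C)
  expect_equal(su_same$increase_ratio_1, 1, tolerance = 0.15)
  # a pure-noise second kernel adds nothing
  set.seed(43)
  A_noise <- build_mrm(matrix(rnorm(400 * 300), 400, 300), label = "noise")
  su_noise <- shared_unique(y, A_all, A_noise, C)
  expect_equal(su_noise$increase_ratio_1, 1, tolerance = 0.15)
})
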
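test_that("the partial-regression fast path equals per-feature full regressions", {
  # direct normal-equations oracle, n = 30, 3 covariates, 1 feature
  set.seed(1)
  n <- 30
  C <- covariate_matrix(data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n)))
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  a <- run_bwas(y, cbind(f = x), C)
  D <- cbind(x / sd(x), C)
  bh <- solve(crossprod(D), crossprod(D, y))
  res <- y - D %*% bh
  df <- n - ncol(D)
  seh <- sqrt(sum(res^2) / df * solve(crossprod(D))[1, 1])
  expect_equal(a$beta, bh[1], tolerance = 1e-10)
  expect_equal(a$se, seh, tolerance = 1e-10)
  expect_equal(a$p, 2 * pt(-abs(bh[1] / seh), df), tolerance = 1e-10)

  # 50 random instances against lm()
  for (i in 1:50) {
    set.seed(100 + i)
    n <- 40
    C <- covariate_matrix(data.frame(a = rnorm(n), s = rbinom(n, 1, .5)))
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rnorm(n)
    a <- run_bwas(y, X, C)
    for (j in 1:4) {
      f <- summary(lm(y ~ I(X[, j] / sd(X[, j])) + C - 1))$coefficients
      expect_equal(a$beta[j], f[1, 1], tolerance = 1e-8)
      expect_equal(a$se[j], f[1, 2], tolerance = 1e-8)
      expect_equal(a$p[j], f[1, 4], tolerance = 1e-8)
    }
  }
})

test_that("perfect association underflows; constant features are flagged", {
  set.seed(2)
  x <- rnorm(100)
  a <- run_bwas(x, cbind(hit = x, const = rep(1, 100), noise = rnorm(100)))
  expect_equal(a$p[1], .Machine$double.xmin)
  expect_gt(abs(a$z[1]), 1e6)
  expect_true(a$flagged[2])
  expect_equal(a$beta[2], 0)
  expect_equal(a$p[2], 1)
})

test_that("null z scores are standard normal and p values uniform", {
  set.seed(3)
  n <- 400
  X <- rand_features(n, c(10, 5, 4), seed = 4)
  C <- simulate_covariates(n, seed = 5)
  zs <- ps <- vector("list", 100)
  for (b in 1:100) {
    a <- run_bwas(rnorm(n), X, C)
    zs[[b]] <- a$z; ps[[b]] <- a$p
  }
  z <- unlist(zs); p <- unlist(ps)
  expect_lt(abs(mean(z)), 0.01)
  expect_gt(var(z), 0.98); expect_lt(var(z), 1.02)
  expect_lt(unname(ks.test(p, "punif")$statistic), 0.015)
  expect_equal(median(abs(z)), qnorm(0.75), tolerance = 0.03)
})

test_that("BWAS summaries are the median and mean absolute z", {
  a <- structure(data.frame(feature_id = c("a", "b", "c"),
                            z = c(-1, 2, -3)), class = c("assoc_table", "data.frame"))
  s <- summarize_bwas(a)
  expect_equal(s$median_abs_z, 2)
  expect_equal(s$mean_abs_z, 2)
  a0 <- a; a0$z <- rep(0, 3)
  expect_equal(summarize_bwas(a0)$median_abs_z, 0)
})

test_that("null calibration is reproducible and FWER behaves analytically", {
  n <- 300
  X <- rand_features(n, c(8, 5, 5), seed = 7)   # independent features
  C <- simulate_covariates(n, seed = 8)
  cal1 <- simulate_null_calibration(X, C, n_traits = 500, seed = 99)
  cal2 <- simulate_null_calibration(X, C, n_traits = 500, seed = 99)
  expect_identical(cal1$minp, cal2$minp)
  expect_identical(cal1$threshold_bonferroni, 0.05 / 200)
  # independence: empirical FWER at Bonferroni close to the Sidak value
  sidak <- 1 - (1 - cal1$threshold_bonferroni)^200
  fw <- fwer_at(cal1, cal1$threshold_bonferroni)
  se <- sqrt(sidak * (1 - sidak) / cal1$n_traits)
  expect_lt(abs(fw$fwer - sidak), 3 * se)
  expect_gt(fw$fwer, 0.02)
  # trivial thresholds
  expect_equal(fwer_at(cal1, 1)$fwer, 1)
  expect_equal(fwer_at(cal1, min(cal1$minp) / 2)$fwer, 0)
  # monotone in the threshold
  thr <- sort(runif(20, 1e-6, 0.5))
  fws <- vapply(thr, function(t) fwer_at(cal1, t)$fwer, numeric(1))
  expect_true(all(diff(fws) >= 0))
})

test_that("smoothing-induced dependence lowers the Bonferroni FWER", {
  n <- 300
  fwer_for <- function(fwhm, seed) {
    cfg <- sim_config(n, c(12, 5, 4), smoothing_fwhm = fwhm, seed = seed)
    X <- simulate_features(cfg)
    cal <- simulate_null_calibration(X, NULL, n_traits = 500, seed = 1000 + seed)
    fwer_at(cal, cal$threshold_bonferroni)$fwer
  }
  # paired over matched seeds
  diffs <- vapply(1:4, function(s) fwer_for(0, s) - fwer_for(8, s), numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the optimal threshold is the prescribed order statistic and calibrates FWER", {
  cal <- structure(list(minp = seq(0.001, 0.1, by = 0.001), n_traits = 100L,
                        p_features = 1000L, threshold_bonferroni = 5e-5),
                   class = "null_calibration")
  expect_equal(optimal_threshold(cal, 0.05), 0.005)   # 5th smallest
  expect_equal(optimal_threshold(cal, 1 / cal$n_traits), min(cal$minp))
  expect_lt(abs(optimal_threshold(cal, 0.05, method = "quantile") - 0.005),
            0.002)
  # by construction the calibration-set FWER stays at or below alpha
  expect_lte(fwer_at(cal, optimal_threshold(cal, 0.05))$fwer, 0.05)
  # binomial CI half-width closed form at p-hat = 0.05, n = 1000
  cal2 <- structure(list(minp = rep(c(1e-9, 0.5), c(50, 950)), n_traits = 1000L),
                    class = "null_calibration")
  expect_equal(fwer_at(cal2, 1e-6)$ci_halfwidth,
               1.959964 * sqrt(0.05 * 0.95 / 1000), tolerance = 1e-6)
})

test_that("QQ data flags deflation and sits on the diagonal for uniform p", {
  p <- (seq_len(1000) - 0.5) / 1000
  a <- structure(data.frame(feature_id = as.character(seq_along(p)), p = p),
                 class = c("assoc_table", "data.frame"))
  qq <- qq_data(a)
  expect_lt(max(abs(qq$expected_log10p - qq$observed_log10p)), 0.01)
  a2 <- a; a2$p <- pmin(1, p * 2)            # deflated p values
  qq2 <- qq_data(a2)
  expect_true(all(qq2$observed_log10p <= qq2$expected_log10p + 1e-12))
})

test_that("feature-level replication distinguishes planted signal from chance", {
  # identical ultra-significant tables replicate fully
  a <- structure(data.frame(feature_id = c("a", "b"), beta = c(1, -1),
                            p = c(1e-30, 1e-30)),
                 class = c("assoc_table", "data.frame"))
  r <- replicate_features(a, 1e-6, a)
  expect_equal(r$vertex_rate, 1)
  expect_equal(r$replication_threshold, 0.05 / 2)
  # mismatched feature sets are an alignment error
  b <- a; b$feature_id <- c("a", "zzz")
  expect_error(replicate_features(a, 1e-6, b), "aligned")

  # planted blobs present in both samples replicate far above chance
  ps <- planted_two_sample(1)
  rep_sig <- replicate_features(ps$assoc1, 1e-3, ps$assoc2)
  # chance expectation at the replication threshold
  null_rate <- rep_sig$replication_threshold * 2   # two-sided sign-free bound
  expect_gt(rep_sig$n_discovery_signif, 5)
  expect_gt(rep_sig$vertex_rate, 10 * null_rate)
  # re-randomized replication trait: (near) zero replication
  set.seed(9)
  y_perm <- trait_vector(sample(as.numeric(ps$y2)),
                         sample_ids = rownames(ps$X2$values))
  a_perm <- run_bwas(y_perm, ps$X2, ps$C2)
  r_perm <- replicate_features(ps$assoc1, 1e-3, a_perm)
  expect_lte(r_perm$n_replicating, 1)
})
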
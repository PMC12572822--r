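#' Simulation configuration
#'
#' Describes a synthetic study: spatially correlated gray-matter-like features
#' on a 3D lattice, covariates, and a trait with known morphometricity and a
#' chosen layout of causal features. The generator exists so that every
#' downstream stage (QC, descriptive statistics, REML, BWAS, FWER calibration,
#' clustering, replication, prediction) can be exercised against known ground
#' truth.
#'
#' @param n_individuals number of samples (>= 3).
#' @param grid_shape integer triple; features sit on a `prod(grid_shape)`-point
#'   lattice with unit spacing, so `p = prod(grid_shape)`.
#' @param smoothing_fwhm Gaussian smoothing kernel full-width at half-maximum
#'   in lattice units (0 = independent features). FWHM relates to the kernel
#'   standard deviation via `sigma = fwhm / 2.3548`.
#' @param target_m2 desired in-sample morphometricity of the simulated trait,
#'   in `[0, 1)`.
#' @param n_causal number of features with nonzero trait effect, or `"all"`.
#' @param causal_layout `"scattered"` (uniformly random causal features) or
#'   `"blobs"` (causal features grouped in spatial blobs; see `blob_k`,
#'   `blob_radius`).
#' @param blob_k,blob_radius number of blobs and their lattice radius when
#'   `causal_layout = "blobs"`.
#' @param skewness_target,kurtosis_target marginal moment targets for the
#'   feature columns (kurtosis is non-excess; normal = 3). Must satisfy
#'   `kurtosis_target >= skewness_target^2 + 1`.
#' @param baseline_range range of per-feature baseline means (uniform draw);
#'   gives voxel-QC something meaningful to threshold.
#' @param global_sd standard deviation of an optional per-individual global
#'   scale component added to every feature (0 = off).
#' @param confounder_effects named list/vector: covariate name -> scale of
#'   per-feature loadings through which that covariate leaks into the features.
#' @param covariate_spec named character vector describing covariates, values
#'   in `c("continuous", "binary")`.
#' @param covar_beta named numeric vector of covariate effects on the trait
#'   (defaults to zero).
#' @param seed master seed; per-stage child seeds are derived by fixed offsets.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals, grid_shape, smoothing_fwhm = 0,
                       target_m2 = 0.3, n_causal = "all",
                       causal_layout = c("scattered", "blobs"),
                       blob_k = 3L, blob_radius = 2,
                       skewness_target = 0, kurtosis_target = 3,
                       baseline_range = c(0.3, 0.8), global_sd = 0,
                       confounder_effects = NULL,
                       covariate_spec = c(age = "continuous", sex = "binary"),
                       covar_beta = NULL, seed = 1L) {
  causal_layout <- match.arg(causal_layout)
  grid_shape <- as.integer(grid_shape)
  p <- prod(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop2("sim_config: grid_shape must be a positive integer triple")
  if (p < 2L || n_individuals < 3L)
    stop2("sim_config: need p >= 2 features and n >= 3 individuals")
  if (target_m2 < 0 || target_m2 >= 1)
    stop2("sim_config: target_m2 must be in [0, 1)")
  if (smoothing_fwhm < 0) stop2("sim_config: smoothing_fwhm must be >= 0")
  if (kurtosis_target < skewness_target^2 + 1)
    stop2("sim_config: infeasible moment pair (need kurtosis >= skewness^2 + 1)")
  if (!identical(n_causal, "all")) {
    n_causal <- as.integer(n_causal)
    if (n_causal > p) stop2("sim_config: n_causal exceeds number of features")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 grid_shape = grid_shape, smoothing_fwhm = smoothing_fwhm,
                 target_m2 = target_m2, n_causal = n_causal,
                 causal_layout = causal_layout, blob_k = as.integer(blob_k),
                 blob_radius = blob_radius,
                 skewness_target = skewness_target,
                 kurtosis_target = kurtosis_target,
                 baseline_range = baseline_range, global_sd = global_sd,
                 confounder_effects = confounder_effects,
                 covariate_spec = covariate_spec, covar_beta = covar_beta,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# 1D Gaussian smoothing matrix with reflecting boundaries, rows normalised.
gauss_smooth_matrix <- function(m, sigma) {
  if (sigma <= 0 || m == 1L) return(diag(m))
  h <- max(1L, ceiling(4 * sigma))
  K <- matrix(0, m, m)
  w <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  for (i in seq_len(m)) {
    idx <- i + seq(-h, h)
    # reflect indices at the boundaries (1-based reflection without repeat)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > m, 2L * m - idx, idx)
    for (t in seq_along(idx)) K[i, idx[t]] <- K[i, idx[t]] + w[t]
  }
  K / rowSums(K)
}

lattice_coords <- function(grid_shape) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  as.matrix(g)
}

#' Generate spatially correlated synthetic features
#'
#' Draws white-noise fields on the lattice for every individual, applies a
#' separable Gaussian smoothing kernel with reflecting boundaries
#' (`sigma = fwhm / 2.3548`), rescales every column to unit variance, adds an
#' optional per-individual global component and a per-feature baseline mean,
#' then (optionally) injects non-normality via a monotone sinh-arcsinh
#' transform so that realized column skewness/kurtosis approach the configured
#' targets. Correlation between feature columns decays with lattice distance
#' at a rate set by `smoothing_fwhm`.
#'
#' @param cfg a [sim_config()].
#' @param covariates optional covariate matrix used for configured confounder
#'   leakage into the features.
#' @return A [feature_matrix()] with lattice coordinates.
#' @export
simulate_features <- function(cfg, covariates = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_individuals
  gs <- cfg$grid_shape
  p <- prod(gs)
  set.seed(child_seed(cfg$seed, .stage_offsets[["features"]]))
  X <- matrix(stats::rnorm(n * p), n, p)
  if (cfg$smoothing_fwhm > 0) {
    sigma <- cfg$smoothing_fwhm / 2.3548
    S <- kronecker(gauss_smooth_matrix(gs[3], sigma),
                   kronecker(gauss_smooth_matrix(gs[2], sigma),
                             gauss_smooth_matrix(gs[1], sigma)))
    X <- X %*% t(S)
  }
  # unit-variance columns keep marginals comparable across smoothing levels
  X <- sweep(X, 2L, apply(X, 2L, stats::sd), "/")
  if (cfg$global_sd > 0)
    X <- X + stats::rnorm(n, sd = cfg$global_sd)
  if (!is.null(cfg$confounder_effects) && !is.null(covariates)) {
    for (nm in names(cfg$confounder_effects)) {
      if (!nm %in% colnames(covariates)) next
      load <- stats::rnorm(p, sd = cfg$confounder_effects[[nm]])
      X <- X + outer(covariates[, nm], load)
    }
  }
  if (cfg$skewness_target != 0 || cfg$kurtosis_target != 3) {
    X <- .apply_sas(X, cfg$skewness_target, cfg$kurtosis_target)
  }
  baseline <- stats::runif(p, cfg$baseline_range[1], cfg$baseline_range[2])
  X <- sweep(X, 2L, baseline, "+")
  feature_matrix(X, lattice_coords(gs), kind = "voxel",
                 modality = "density", units = "arbitrary")
}

# ---- sinh-arcsinh non-normality ------------------------------------------

# Raw moments of Y = sinh((asinh(X) + eps) / delta), X ~ N(0,1), in closed
# form through the Bessel-K function; standardized skewness / non-excess
# kurtosis follow from the raw moments.
.sas_shape <- function(eps, delta) {
  Pq <- function(q) exp(0.25) *
    (besselK(0.25, (q + 1) / 2) + besselK(0.25, (q - 1) / 2)) / sqrt(8 * pi)
  m1 <- sinh(eps / delta) * Pq(1 / delta)
  m2 <- 0.5 * (cosh(2 * eps / delta) * Pq(2 / delta) - 1)
  m3 <- 0.25 * (sinh(3 * eps / delta) * Pq(3 / delta) -
                  3 * sinh(eps / delta) * Pq(1 / delta))
  m4 <- 0.125 * (cosh(4 * eps / delta) * Pq(4 / delta) -
                   4 * cosh(2 * eps / delta) * Pq(2 / delta) + 3)
  v <- m2 - m1^2
  c(skew = (m3 - 3 * m1 * m2 + 2 * m1^3) / v^1.5,
    kurt = (m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4) / v^2)
}

# Solve for (eps, delta) hitting target (skewness, kurtosis).
.sas_solve <- function(skewness_target, kurtosis_target, tol = 0.02) {
  if (kurtosis_target < skewness_target^2 + 1)
    stop2("infeasible moment pair: need kurtosis >= skewness^2 + 1")
  if (abs(skewness_target) < 1e-12 && abs(kurtosis_target - 3) < 1e-12)
    return(c(eps = 0, delta = 1))
  obj <- function(par) {
    sh <- .sas_shape(par[1], exp(par[2]))
    if (any(!is.finite(sh))) return(1e6)
    (sh[["skew"]] - skewness_target)^2 + (sh[["kurt"]] - kurtosis_target)^2
  }
  best <- NULL
  for (start in list(c(0, 0), c(sign(skewness_target) * 0.3, -0.2),
                     c(sign(skewness_target) * 0.6, 0.2))) {
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  got <- .sas_shape(best$par[1], exp(best$par[2]))
  if (abs(got[["skew"]] - skewness_target) > tol ||
      abs(got[["kurt"]] - kurtosis_target) > max(tol, 0.05))
    warning(sprintf("sinh-arcsinh family reaches (%.3f, %.3f) for target (%.3f, %.3f)",
                    got[["skew"]], got[["kurt"]],
                    skewness_target, kurtosis_target))
  c(eps = best$par[1], delta = exp(best$par[2]))
}

.apply_sas <- function(X, skewness_target, kurtosis_target) {
  par <- .sas_solve(skewness_target, kurtosis_target)
  mu <- colMeans(X); s <- apply(X, 2L, stats::sd)
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, s, "/")
  Y <- sinh((asinh(Z) + par[["eps"]]) / par[["delta"]])
  # restore the original per-column location/scale (affine; moments unchanged)
  Y <- sweep(Y, 2L, colMeans(Y), "-")
  Y <- sweep(Y, 2L, apply(Y, 2L, stats::sd), "/")
  sweep(sweep(Y, 2L, s, "*"), 2L, mu, "+")
}

#' Inject non-normality into a feature matrix
#'
#' Applies a per-column monotone sinh-arcsinh transform so that realized
#' column skewness and (non-excess) kurtosis approach the targets; rank order
#' within each column is preserved. The single transform is solved once from
#' the normal reference, so realized moments converge to the targets as n
#' grows when the input columns are approximately normal.
#'
#' @param X a [feature_matrix()].
#' @param skewness_target,kurtosis_target targets; must satisfy
#'   `kurtosis_target >= skewness_target^2 + 1`.
#' @return A transformed [feature_matrix()].
#' @export
inject_nonnormality <- function(X, skewness_target, kurtosis_target) {
  stopifnot(is_feature_matrix(X))
  X$values <- .apply_sas(X$values, skewness_target, kurtosis_target)
  X
}
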
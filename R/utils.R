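# Internal helpers shared across modules.

#' Derive a per-stage child seed from a master seed
#'
#' One master seed drives a whole simulated study; each stage (features,
#' covariates, trait, null traits, ...) draws from its own stream obtained by a
#' fixed offset so that re-running a single stage is reproducible. The result
#' always stays below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param offset fixed non-negative integer offset identifying the stage.
#' @return An integer seed.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) + as.numeric(offset)) %% 2147483647)
}

# Fixed stage offsets (logged in the run manifest).
.stage_offsets <- c(
  features = 101L, nonnormal = 211L, covariates = 307L, trait = 401L,
  null_calibration = 503L, null_fresh = 601L, subsample = 701L,
  replication = 809L
)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# Column-wise central sample moments m_k (no bias correction); the moment
# convention deliberately matches the classical skewness/kurtosis estimators
# (skew = m3/m2^1.5, kurt = m4/m2^2, non-excess).
col_central_moment <- function(x, k) {
  mu <- colMeans(x)
  colMeans(sweep(x, 2L, mu, "-")^k)
}

sample_skewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  mean(x^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  mean(x^4) / m2^2
}
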
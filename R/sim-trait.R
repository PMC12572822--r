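#' Simulate covariates
#'
#' Continuous covariates are standard normal, binary covariates Bernoulli(0.5).
#'
#' @param n number of samples.
#' @param spec named character vector, values `"continuous"` or `"binary"`;
#'   empty spec yields an intercept-only design.
#' @param seed RNG seed.
#' @return A design matrix from [covariate_matrix()].
#' @export
simulate_covariates <- function(n, spec = c(age = "continuous", sex = "binary"),
                                seed = 1L) {
  if (n < 3L) stop2("simulate_covariates: need n >= 3")
  set.seed(seed)
  if (length(spec) == 0L) return(covariate_matrix(NULL, n = n))
  cols <- lapply(spec, function(type) {
    switch(type,
           continuous = stats::rnorm(n),
           binary = stats::rbinom(n, 1L, 0.5),
           stop2("simulate_covariates: unknown covariate type ", type))
  })
  covariate_matrix(as.data.frame(cols))
}

# Pick causal feature indices according to the configured layout.
.causal_indices <- function(cfg, coords) {
  p <- nrow(coords)
  n_causal <- if (identical(cfg$n_causal, "all")) p else cfg$n_causal
  if (cfg$causal_layout == "scattered") {
    idx <- if (n_causal == p) seq_len(p) else sort(sample.int(p, n_causal))
    return(list(idx = idx, blobs = NULL))
  }
  # blobs: pick well-separated centres (pairwise distance > 2*(radius+1) when
  # the lattice allows it), take all lattice points within radius
  centres <- integer(0)
  min_sep <- 2 * (cfg$blob_radius + 1)
  for (attempt in seq_len(500L)) {
    cand <- sample.int(p, 1L)
    if (length(centres) == 0L ||
        all(sqrt(rowSums(sweep(coords[centres, , drop = FALSE], 2L,
                               coords[cand, ], "-")^2)) > min_sep))
      centres <- c(centres, cand)
    if (length(centres) == cfg$blob_k) break
  }
  if (length(centres) < cfg$blob_k) {
    warning("could not place well-separated blob centres; relaxing separation")
    centres <- c(centres, sample.int(p, cfg$blob_k - length(centres)))
  }
  blobs <- lapply(centres, function(ctr) {
    d <- sqrt(rowSums(sweep(coords, 2L, coords[ctr, ], "-")^2))
    which(d <= cfg$blob_radius)
  })
  list(idx = sort(unique(unlist(blobs))), blobs = blobs)
}

#' Simulate a trait with known morphometricity
#'
#' Generates `y = C beta + g + e` where `g` is a weighted sum of the
#' standardized causal feature columns (weights drawn normal) rescaled so that
#' the in-sample variance ratio `Var(g) / (Var(g) + Var(e))` equals
#' `target_m2` exactly.
#'
#' @param X a [feature_matrix()].
#' @param C covariate design from [covariate_matrix()].
#' @param cfg a [sim_config()].
#' @return A [trait_vector()] with attribute `"truth"`: a list with the causal
#'   indices, weights, blob membership (if any) and the realized m2.
#' @export
simulate_trait <- function(X, C, cfg) {
  stopifnot(is_feature_matrix(X), inherits(cfg, "sim_config"))
  n <- nrow(X$values)
  set.seed(child_seed(cfg$seed, .stage_offsets[["trait"]]))
  causal <- .causal_indices(cfg, X$coords)
  beta <- rep(0, ncol(C))
  names(beta) <- colnames(C)
  if (!is.null(cfg$covar_beta)) {
    common <- intersect(names(cfg$covar_beta), names(beta))
    beta[common] <- cfg$covar_beta[common]
  }
  fixed <- drop(C %*% beta)
  e <- stats::rnorm(n)
  e <- e / stats::sd(e) * sqrt(1 - cfg$target_m2)
  if (cfg$target_m2 > 0) {
    Z <- scale(X$values[, causal$idx, drop = FALSE])
    w <- stats::rnorm(length(causal$idx))
    if (!is.null(causal$blobs)) {
      # each blob gets a coherent effect direction (spatially smooth causal
      # fields would cancel under mixed signs) and an equal share of the
      # causal variance, so every planted blob is detectable by construction
      for (b in causal$blobs) {
        pos <- match(b, causal$idx)
        w[pos] <- abs(w[pos]) * sample(c(-1, 1), 1L)
        gb <- drop(Z[, pos, drop = FALSE] %*% w[pos])
        w[pos] <- w[pos] / stats::sd(gb)
      }
    }
    g <- drop(Z %*% w)
    g <- g / stats::sd(g) * sqrt(cfg$target_m2)
  } else {
    g <- rep(0, n)
    w <- numeric(0)
  }
  y <- trait_vector(fixed + g + e, sample_ids = rownames(X$values),
                    trait_name = "simulated")
  realized <- if (cfg$target_m2 > 0)
    stats::var(g) / (stats::var(g) + stats::var(e)) else 0
  attr(y, "truth") <- list(causal_idx = causal$idx, weights = w,
                           blobs = causal$blobs, realized_m2 = realized,
                           beta = beta)
  y
}
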
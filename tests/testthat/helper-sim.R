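# Shared fixture builders: everything is generated in code at test time.

# Small random feature matrix with lattice coordinates (no smoothing).
rand_features <- function(n, grid = c(5, 4, 3), seed = 1, kind = "voxel") {
  set.seed(seed)
  p <- prod(grid)
  feature_matrix(matrix(rnorm(n * p), n, p),
                 as.matrix(expand.grid(x = seq_len(grid[1]),
                                       y = seq_len(grid[2]),
                                       z = seq_len(grid[3]))),
                 kind = kind)
}

# Discovery + replication samples with planted blob signal, plus the BWAS and
# cluster outputs both tests and acceptance checks reuse.
planted_two_sample <- function(seed, n = 300, grid = c(12, 10, 6),
                               target_m2 = 0.5, sig_threshold = 1e-3,
                               k = 10L, fwhm = 2) {
  cfg <- sim_config(n, grid, smoothing_fwhm = fwhm, target_m2 = target_m2,
                    n_causal = 0L, causal_layout = "blobs", blob_k = 3L,
                    blob_radius = 2, seed = seed)
  C1 <- simulate_covariates(n, cfg$covariate_spec, seed = child_seed(seed, 7))
  X1 <- simulate_features(cfg, C1)
  y1 <- simulate_trait(X1, C1, cfg)
  cfg2 <- cfg
  cfg2$seed <- child_seed(seed, 500009L)
  C2 <- simulate_covariates(n, cfg$covariate_spec, seed = child_seed(seed, 11))
  X2 <- simulate_features(cfg2, C2)
  # same causal structure in both samples: rebuild y2 from the sample-1 truth
  truth <- attr(y1, "truth")
  set.seed(child_seed(seed, 13))
  Z2 <- scale(X2$values[, truth$causal_idx, drop = FALSE])
  g2 <- drop(Z2 %*% truth$weights)
  g2 <- g2 / sd(g2) * sqrt(target_m2)
  e2 <- rnorm(n); e2 <- e2 / sd(e2) * sqrt(1 - target_m2)
  y2 <- trait_vector(g2 + e2, sample_ids = rownames(X2$values))
  a1 <- run_bwas(y1, X1, C1)
  a2 <- run_bwas(y2, X2, C2)
  sig <- which(a1$p < sig_threshold)
  cs <- find_clusters(sig, X1$coords, k = k, p = a1$p)
  list(cfg = cfg, X1 = X1, y1 = y1, C1 = C1, X2 = X2, y2 = y2, C2 = C2,
       assoc1 = a1, assoc2 = a2, sig = sig, clusters = cs, truth = truth)
}

# Independent connected-components oracle over the same k-NN adjacency
# (igraph; a different code path from the BFS in the package). `universe`
# mirrors the `neighbours` argument of find_clusters().
oracle_components <- function(signif, coords, k, universe = "all") {
  ns <- length(signif)
  if (ns == 1L) return(1L)
  edges <- integer(0)
  if (universe == "significant") {
    D <- as.matrix(dist(coords[signif, , drop = FALSE]))
    for (i in seq_len(ns)) {
      o <- order(D[i, ], seq_len(ns))
      o <- o[o != i][seq_len(min(k, ns - 1L))]
      edges <- c(edges, rbind(i, o))
    }
  } else {
    Dall <- as.matrix(dist(coords))
    for (i in seq_len(ns)) {
      self <- signif[i]
      o <- order(Dall[self, ], seq_len(nrow(coords)))
      o <- o[o != self][seq_len(min(k, nrow(coords) - 1L))]
      hits <- match(intersect(o, signif), signif)
      if (length(hits)) edges <- c(edges, rbind(i, hits))
    }
  }
  g <- igraph::make_empty_graph(ns, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, edges)
  g <- igraph::simplify(g)
  igraph::components(g)$membership
}

# Canonical form of a partition for comparing memberships up to relabeling.
canonical_partition <- function(membership) {
  unname(split(seq_along(membership), membership)[
    order(vapply(split(seq_along(membership), membership), min, 1L))])
}
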
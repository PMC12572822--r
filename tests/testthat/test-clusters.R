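grid_coords <- function(g) as.matrix(expand.grid(x = seq_len(g[1]),
                                                 y = seq_len(g[2]),
                                                 z = seq_len(g[3])))

# Three spatial sites with dense non-significant filler points: two isolated
# significant features (-> singletons) and one adjacent significant pair.
three_site_coords <- function() {
  set.seed(42)
  ring <- function(center, m) {
    u <- matrix(rnorm(m * 3), m, 3)
    u <- u / sqrt(rowSums(u^2)) * runif(m, 1, 2)
    sweep(u, 2, center, "+")
  }
  rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0), c(100, 0.5, 0),
        ring(c(0, 0, 0), 20), ring(c(50, 0, 0), 20), ring(c(100, 0, 0), 20))
}

test_that("degenerate significant sets form the obvious clusters", {
  co <- grid_coords(c(6, 6, 3))
  expect_length(find_clusters(integer(0), co)$clusters, 0)
  cs1 <- find_clusters(5L, co)
  expect_length(cs1$clusters, 1)
  expect_equal(cs1$clusters[[1]]$size, 1)
  # two tight pairs far apart stay separate clusters
  cs2 <- find_clusters(c(1, 2, 100, 101), co, k = 10)
  expect_length(cs2$clusters, 2)
  expect_error(find_clusters(1L, co, k = 0), "k must be")
})

test_that("the k-NN partition matches an exhaustive connected-components oracle", {
  skip_if_not_installed("igraph")
  co <- grid_coords(c(8, 8, 4))
  for (seed in 1:8) {
    set.seed(seed)
    ns <- sample(10:60, 1)
    sig <- sort(sample(nrow(co), ns))
    k <- sample(c(3L, 5L, 10L), 1)
    cs <- find_clusters(sig, co, k = k)
    oracle <- oracle_components(sig, co, k, universe = "all")
    expect_identical(canonical_partition(cs$membership),
                     canonical_partition(oracle))
    # partition property: disjoint and exhaustive over the significant set
    members <- unlist(lapply(cs$clusters, `[[`, "members"))
    expect_identical(sort(members), sig)
    expect_identical(anyDuplicated(members), 0L)
    # alternative neighbour universe against its own oracle
    cs_s <- find_clusters(sig, co, k = k, neighbours = "significant")
    expect_identical(canonical_partition(cs_s$membership),
                     canonical_partition(oracle_components(sig, co, k,
                                                           universe = "significant")))
  }
})

test_that("the partition is invariant to feature order and coarsens with k", {
  # generic (tie-free) coordinates: with exact distance ties the k-NN sets
  # depend on the documented index tie-break, so invariance is up to ties
  set.seed(11)
  co <- grid_coords(c(7, 7, 3)) + matrix(runif(147 * 3, -0.2, 0.2), 147, 3)
  sig <- sort(sample(nrow(co), 40))
  base <- find_clusters(sig, co, k = 4)
  # permuting the coordinate rows (and mapping indices) relabels only
  perm <- sample(nrow(co))
  co_p <- co[perm, ]
  sig_p <- match(sig, perm)
  cs_p <- find_clusters(sig_p, co_p, k = 4)
  size_multiset <- function(cs) sort(vapply(cs$clusters, `[[`, numeric(1), "size"))
  expect_identical(size_multiset(cs_p), size_multiset(base))
  # monotone in k: more neighbours never split clusters
  for (k in 1:8) {
    n_k <- length(find_clusters(sig, co, k = k)$clusters)
    n_k1 <- length(find_clusters(sig, co, k = k + 1)$clusters)
    expect_lte(n_k1, n_k)
  }
})

test_that("cluster summaries report sizes and singleton fraction", {
  co <- three_site_coords()
  cs <- find_clusters(1:4, co, k = 10)
  s <- cluster_summary(cs)
  expect_equal(s$n_clusters, 3)
  expect_equal(s$median_size, 1)
  expect_equal(s$fraction_size_one, 2 / 3)
  empty <- cluster_summary(find_clusters(integer(0), co))
  expect_equal(empty$n_clusters, 0)
  expect_equal(empty$median_size, 0)
})

test_that("planted blobs are recovered as clusters covering their members", {
  ps <- planted_two_sample(3)
  truth <- ps$truth
  cs <- ps$clusters
  expect_gte(cluster_summary(cs)$n_clusters, 3)
  # at least 90% of blob members that reached significance sit in clusters
  # overlapping their blob
  planted <- unlist(truth$blobs)
  sig_planted <- intersect(ps$sig, planted)
  expect_gt(length(sig_planted), 10)
  in_cluster <- unlist(lapply(cs$clusters, `[[`, "members"))
  expect_gte(mean(sig_planted %in% in_cluster), 0.9)
  # each blob overlaps at least one detected cluster
  for (b in truth$blobs)
    expect_true(any(vapply(cs$clusters,
                           function(cl) length(intersect(cl$members, b)) > 0,
                           logical(1))))
})

test_that("ROI annotation counts hits and conserves totals", {
  co <- grid_coords(c(10, 4, 3))
  roi <- rep(c("A", "B", "C", "D"), each = 30)
  cs <- find_clusters(c(1, 2, 3), co, k = 3)        # one cluster inside ROI A
  ann <- annotate_rois(cs, roi)
  expect_identical(ann$roi_names, "A")
  expect_equal(ann$roi_counts, 1L)
  # a cluster straddling two ROIs hits both
  cs2 <- find_clusters(c(29, 30, 31, 32), co, k = 3)
  ann2 <- annotate_rois(cs2, roi)
  expect_true(all(c("A", "B") %in% ann2$roi_names))
  # conservation: cluster ROI hits sum over per-cluster distinct labels
  set.seed(5)
  roi_r <- sample(LETTERS[1:20], 120, replace = TRUE)
  sing <- find_clusters(seq(1, 120, by = 7), co, k = 2)
  ann3 <- annotate_rois(sing, roi_r)
  expect_equal(sum(ann3$roi_counts),
               sum(vapply(sing$clusters, function(cl)
                 length(unique(roi_r[cl$members])), numeric(1))))
})

test_that("cross-processing robustness counts shared ROIs", {
  mk <- function(rois) structure(list(roi_names = rois), class = "roi_annotation")
  same <- roi_robustness(list(a = mk(c("r1", "r2")), b = mk(c("r1", "r2"))))
  expect_equal(same$n_rois_ge2, 2)
  disj <- roi_robustness(list(a = mk("r1"), b = mk("r2")))
  expect_equal(disj$n_rois_ge2, 0)
  three <- roi_robustness(list(a = mk(paste0("r", 1:6)),
                               b = mk(paste0("r", 2:6)),
                               c = mk("r9")))
  expect_equal(three$n_rois_ge2, 5)
  expect_error(roi_robustness(list(a = mk("r1"))), "at least two")
  expect_error(roi_robustness(list(a = mk("r1"), b = mk("weird")),
                              vocabulary = c("r1", "r2")), "vocabulary")
})

test_that("cluster replication requires a surviving member with consistent sign", {
  co <- grid_coords(c(6, 4, 3))
  disc <- structure(data.frame(feature_id = paste0("F", 1:72),
                               beta = rep(1, 72), p = rep(0.5, 72)),
                    class = c("assoc_table", "data.frame"))
  disc$p[1:3] <- 1e-9
  cs <- find_clusters(1:3, co, k = 3)
  repl <- disc
  repl$p[1:3] <- 1e-9
  r <- replicate_clusters(cs, disc, repl)
  expect_equal(r$cluster_rate, 1)
  repl2 <- repl; repl2$p[1:3] <- 0.9
  expect_equal(replicate_clusters(cs, disc, repl2)$cluster_rate, 0)
  repl3 <- repl; repl3$beta[1:3] <- -1
  expect_equal(replicate_clusters(cs, disc, repl3)$cluster_rate, 0)
  expect_equal(replicate_clusters(cs, disc, repl3, require_sign = FALSE)$cluster_rate, 1)
})
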
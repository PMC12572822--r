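#' Spatial clusters of significant features via k-nearest neighbours
#'
#' Groups significant features into spatial clusters: each significant
#' feature is linked to its k nearest neighbours (Euclidean distance on the
#' 3D coordinates) drawn from the set of significant features, edges are
#' symmetrized, and clusters are the connected components of that graph,
#' grown by breadth-first search from unassigned seeds in ascending feature
#' index (deterministic). Exact distance ties are broken by feature index.
#'
#' @param signif integer indices (into `coords`) of significant features; an
#'   empty set yields an empty cluster set.
#' @param coords p x 3 coordinate matrix (or a [feature_matrix()]).
#' @param k number of nearest neighbours (default 10).
#' @param p optional per-feature p values (used to pick each cluster's top
#'   feature; ties broken by smallest index).
#' @param neighbours neighbour universe for the k-NN step. `"all"` (default)
#'   takes each significant feature's k nearest neighbours among ALL features
#'   and keeps the significant ones, so spatially isolated significant
#'   features form singleton clusters. `"significant"` draws neighbours from
#'   the significant set itself, which links features regardless of distance
#'   (every feature then has k neighbours; singletons cannot occur).
#' @return An object of class `"cluster_set"`: a list of clusters (member
#'   indices, size, top feature, centroid), plus `k` and the membership map.
#' @export
find_clusters <- function(signif, coords, k = 10L, p = NULL,
                          neighbours = c("all", "significant")) {
  neighbours <- match.arg(neighbours)
  if (is_feature_matrix(coords)) coords <- coords$coords
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop2("find_clusters: coords must be finite")
  if (k < 1L) stop2("find_clusters: k must be >= 1")
  signif <- sort(unique(as.integer(signif)))
  ns <- length(signif)
  if (ns == 0L)
    return(structure(list(clusters = list(), k = k, signif = integer(0),
                          membership = integer(0)), class = "cluster_set"))
  adj <- .knn_adjacency(signif, coords, k, neighbours)
  comp <- .bfs_components(ns, adj)
  clusters <- lapply(seq_len(max(comp)), function(ci) {
    members <- signif[comp == ci]
    top <- if (!is.null(p)) {
      pm <- p[members]
      members[which(pm == min(pm))][1]
    } else members[1]
    list(members = members, size = length(members), top_feature = top,
         centroid = colMeans(coords[members, , drop = FALSE]))
  })
  structure(list(clusters = clusters, k = k, signif = signif,
                 membership = comp), class = "cluster_set")
}

# Symmetrized directed k-NN adjacency among the significant features,
# returned as a list of integer neighbour vectors (positions within signif).
.knn_adjacency <- function(signif, coords, k, neighbours) {
  ns <- length(signif)
  if (neighbours == "significant") {
    cs <- coords[signif, , drop = FALSE]
    D <- as.matrix(stats::dist(cs))
    nn <- lapply(seq_len(ns), function(i) {
      o <- order(D[i, ], seq_len(ns))   # distance, then index tie-break
      o <- o[o != i]
      o[seq_len(min(k, ns - 1L))]
    })
  } else {
    # neighbours drawn from all features, then restricted to significant ones
    D2 <- outer(rowSums(coords[signif, , drop = FALSE]^2),
                rowSums(coords^2), "+") -
      2 * coords[signif, , drop = FALSE] %*% t(coords)
    D <- sqrt(pmax(D2, 0))
    pos <- match(seq_len(nrow(coords)), signif)
    nn <- lapply(seq_len(ns), function(i) {
      o <- order(D[i, ], seq_len(ncol(D)))
      o <- o[o != signif[i]]
      keep <- pos[o[seq_len(min(k, ncol(D) - 1L))]]
      keep[!is.na(keep)]
    })
  }
  adj <- vector("list", ns)
  for (i in seq_len(ns)) {
    for (j in nn[[i]]) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

.bfs_components <- function(ns, adj) {
  comp <- integer(ns)
  cur <- 0L
  for (seed in seq_len(ns)) {
    if (comp[seed] != 0L) next
    cur <- cur + 1L
    queue <- seed
    comp[seed] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) if (comp[u] == 0L) {
        comp[u] <- cur
        queue <- c(queue, u)
      }
    }
  }
  comp
}

#' @export
print.cluster_set <- function(x, ...) {
  s <- cluster_summary(x)
  cat(sprintf("<cluster_set> %d cluster(s) over %d significant features (k = %d)\n",
              s$n_clusters, length(x$signif), x$k))
  if (s$n_clusters > 0)
    cat(sprintf("  median size %.1f; fraction of singletons %.2f\n",
                s$median_size, s$fraction_size_one))
  invisible(x)
}

#' Descriptive summaries of a cluster set
#'
#' @param cs a [find_clusters()] result.
#' @return List with `n_clusters`, `median_size`, `fraction_size_one`.
#' @export
cluster_summary <- function(cs) {
  sizes <- vapply(cs$clusters, `[[`, numeric(1), "size")
  if (length(sizes) == 0L)
    return(list(n_clusters = 0L, median_size = 0, fraction_size_one = 0))
  list(n_clusters = length(sizes), median_size = stats::median(sizes),
       fraction_size_one = mean(sizes == 1))
}

#' Annotate clusters with region-of-interest labels
#'
#' A cluster hits every ROI that any of its members belongs to; unlabeled
#' features fall into the `"none"` bucket.
#'
#' @param cs a [find_clusters()] result.
#' @param roi_labels per-feature label vector (length p, indexable by the
#'   cluster member indices), or a [feature_matrix()] carrying `roi`.
#' @return List of class `"roi_annotation"`: per-cluster label sets,
#'   per-ROI cluster counts, `n_rois_hit`.
#' @export
annotate_rois <- function(cs, roi_labels) {
  if (is_feature_matrix(roi_labels)) roi_labels <- roi_labels$roi
  roi_labels <- as.character(roi_labels)
  roi_labels[is.na(roi_labels)] <- "none"
  hits <- lapply(cs$clusters, function(cl) sort(unique(roi_labels[cl$members])))
  all_hit <- unlist(hits)
  counts <- if (length(all_hit)) table(all_hit) else table(character(0))
  structure(list(cluster_rois = hits,
                 roi_counts = as.integer(counts),
                 roi_names = names(counts),
                 n_rois_hit = length(counts)),
            class = "roi_annotation")
}

#' Robustness of ROI findings across processings
#'
#' For every ROI, counts the number of processings whose clusters hit it, and
#' reports how many ROIs are identified by at least two processings.
#'
#' @param annotations named list (processing name -> [annotate_rois()]
#'   result).
#' @param vocabulary optional character vector of allowed ROI names; a label
#'   outside it raises an error.
#' @return List with the per-ROI processing counts (`roi_names`,
#'   `n_processings`) and `n_rois_ge2`.
#' @export
roi_robustness <- function(annotations, vocabulary = NULL) {
  if (length(annotations) < 2L)
    stop2("roi_robustness: need at least two processings")
  per_proc <- lapply(annotations, function(a) a$roi_names)
  all_rois <- sort(unique(unlist(per_proc)))
  if (!is.null(vocabulary) && !all(all_rois %in% c(vocabulary, "none")))
    stop2("roi_robustness: ROI labels outside the shared vocabulary: ",
          paste(setdiff(all_rois, c(vocabulary, "none")), collapse = ", "))
  cnt <- vapply(all_rois, function(r)
    sum(vapply(per_proc, function(v) r %in% v, logical(1))), integer(1))
  list(roi_names = all_rois, n_processings = cnt,
       n_rois_ge2 = sum(cnt >= 2L))
}

#' Cluster-level replication
#'
#' A discovery cluster replicates when at least one member passes the
#' cluster-wise replication threshold (`0.05 /` total discovery clusters,
#' pooled) in the replication sample, by default with a sign consistent with
#' the discovery effect. Rates are reported with and without size-one
#' clusters.
#'
#' @param cs a [find_clusters()] result (discovery).
#' @param discovery,replication `"assoc_table"`s on aligned features.
#' @param n_total_clusters pooled count of discovery clusters; defaults to
#'   the number of clusters in `cs`.
#' @param alpha base level.
#' @param require_sign require sign consistency (default `TRUE`).
#' @return List with cluster counts and replication rates overall, for
#'   size-one clusters, and excluding size-one clusters.
#' @export
replicate_clusters <- function(cs, discovery, replication,
                               n_total_clusters = NULL, alpha = 0.05,
                               require_sign = TRUE) {
  if (!identical(discovery$feature_id, replication$feature_id))
    stop2("replicate_clusters: feature ids are not aligned")
  n_cl <- length(cs$clusters)
  n_total <- n_total_clusters %||% n_cl
  if (n_cl == 0L)
    return(list(n_clusters = 0L, n_replicating = 0L, cluster_rate = NA_real_,
                rate_size_one = NA_real_, rate_size_ge2 = NA_real_,
                replication_threshold = NA_real_))
  thr <- alpha / max(1L, n_total)
  rep_ok <- vapply(cs$clusters, function(cl) {
    m <- cl$members
    ok <- replication$p[m] < thr
    if (require_sign)
      ok <- ok & sign(replication$beta[m]) == sign(discovery$beta[m])
    any(ok)
  }, logical(1))
  sizes <- vapply(cs$clusters, `[[`, numeric(1), "size")
  rate <- function(sel) if (any(sel)) mean(rep_ok[sel]) else NA_real_
  list(n_clusters = n_cl, n_replicating = sum(rep_ok),
       cluster_rate = mean(rep_ok),
       rate_size_one = rate(sizes == 1),
       rate_size_ge2 = rate(sizes >= 2),
       replication_threshold = thr)
}
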
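#' Feature-level replication of discovery associations
#'
#' A discovery-significant feature replicates when its replication-sample p
#' value passes the Bonferroni-adjusted threshold `0.05 / n_total_discoveries`
#' (the total number of significant associations carried to the replication
#' sample, pooled across traits/processings) and, by default, the effect sign
#' matches.
#'
#' @param discovery an `"assoc_table"` from the discovery sample.
#' @param threshold discovery significance threshold (e.g. the optimal
#'   threshold from [optimal_threshold()]).
#' @param replication an `"assoc_table"` on the same features from the
#'   replication sample.
#' @param n_total_discoveries pooled count of discovery-significant
#'   associations; defaults to the count within `discovery` itself.
#' @param alpha base level for the replication threshold.
#' @param require_sign require sign consistency (default `TRUE`; the
#'   sign-free count is always reported as well).
#' @return List of class `"replication_report"`: counts, the replication
#'   threshold, `vertex_rate`, and the sign-consistency bookkeeping.
#' @export
replicate_features <- function(discovery, threshold, replication,
                               n_total_discoveries = NULL, alpha = 0.05,
                               require_sign = TRUE) {
  if (!identical(discovery$feature_id, replication$feature_id))
    stop2("replicate_features: feature ids are not aligned")
  sig <- which(discovery$p < threshold)
  n_sig <- length(sig)
  n_total <- n_total_discoveries %||% n_sig
  if (n_total < 1L)
    return(structure(list(n_discovery_signif = 0L, replication_threshold = NA_real_,
                          n_replicating = 0L, n_replicating_any_sign = 0L,
                          sign_consistent = 0L, vertex_rate = NA_real_),
                     class = "replication_report"))
  thr_rep <- alpha / n_total
  rep_p_ok <- replication$p[sig] < thr_rep
  same_sign <- sign(replication$beta[sig]) == sign(discovery$beta[sig])
  n_rep <- sum(rep_p_ok & (!require_sign | same_sign))
  structure(list(n_discovery_signif = n_sig, replication_threshold = thr_rep,
                 n_replicating = n_rep,
                 n_replicating_any_sign = sum(rep_p_ok),
                 sign_consistent = sum(rep_p_ok & same_sign),
                 vertex_rate = if (n_sig > 0) n_rep / n_sig else NA_real_),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report> %d significant, %d replicating (rate %.2f) at p < %.3g\n",
              x$n_discovery_signif, x$n_replicating,
              x$vertex_rate %||% NA_real_, x$replication_threshold))
  invisible(x)
}

#' Pooled replication bookkeeping across processings
#'
#' Given per-processing counts of significant and replicating features and of
#' clusters, computes the pooled multiple-testing denominators used for
#' replication (total significant associations and total clusters across all
#' traits and processings) and the per-processing replication fractions.
#'
#' @param counts data frame with columns `processing`, `n_signif`,
#'   `n_replicating`, `n_clusters`.
#' @return List with `pooled_signif`, `pooled_clusters`,
#'   `feature_threshold = 0.05 / pooled_signif`,
#'   `cluster_threshold = 0.05 / pooled_clusters`, and the input with an added
#'   `fraction` column (`n_replicating / n_signif`).
#' @export
pooled_replication <- function(counts) {
  need <- c("processing", "n_signif", "n_replicating", "n_clusters")
  if (!all(need %in% names(counts)))
    stop2("pooled_replication: counts needs columns ", paste(need, collapse = ", "))
  pooled_signif <- sum(counts$n_signif)
  pooled_clusters <- sum(counts$n_clusters)
  counts$fraction <- counts$n_replicating / counts$n_signif
  list(pooled_signif = pooled_signif, pooled_clusters = pooled_clusters,
       feature_threshold = 0.05 / pooled_signif,
       cluster_threshold = 0.05 / pooled_clusters,
       table = counts)
}
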
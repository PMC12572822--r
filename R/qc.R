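#' Quality control for voxel features
#'
#' Retains voxels whose column mean and variance both reach the thresholds,
#' keeping only the gray-matter voxels that are non-null across most
#' participants. Feature order is preserved.
#'
#' @param X a [feature_matrix()] with `kind = "voxel"`.
#' @param mean_min minimum column mean (default 0.1).
#' @param var_min minimum column variance (default 0.01).
#' @return The filtered [feature_matrix()]; attribute `"kept"` holds the
#'   indices of retained features and `"n_dropped"` the exclusion count.
#' @export
qc_voxels <- function(X, mean_min = 0.1, var_min = 0.01) {
  stopifnot(is_feature_matrix(X))
  if (X$kind != "voxel") stop2("qc_voxels: expected voxel features")
  mu <- colMeans(X$values)
  v <- apply(X$values, 2L, stats::var)
  keep <- unname(which(mu >= mean_min & v >= var_min))
  if (length(keep) == 0L)
    stop2(sprintf("qc_voxels: no features survive (mean rule drops %d, variance rule drops %d of %d)",
                  sum(mu < mean_min), sum(v < var_min), ncol(X$values)))
  out <- X[, keep]
  attr(out, "kept") <- keep
  attr(out, "n_dropped") <- ncol(X$values) - length(keep)
  out
}

#' Quality control for vertex features
#'
#' Drops exactly the columns that are zero for all participants.
#'
#' @param X a [feature_matrix()] with `kind = "vertex"`.
#' @return The filtered [feature_matrix()] with attributes as in [qc_voxels()].
#' @export
qc_vertices <- function(X) {
  stopifnot(is_feature_matrix(X))
  if (X$kind != "vertex") stop2("qc_vertices: expected vertex features")
  keep <- unname(which(colSums(X$values != 0) > 0L))
  if (length(keep) == 0L)
    stop2(sprintf("qc_vertices: all %d features are all-zero", ncol(X$values)))
  out <- X[, keep]
  attr(out, "kept") <- keep
  attr(out, "n_dropped") <- ncol(X$values) - length(keep)
  out
}
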
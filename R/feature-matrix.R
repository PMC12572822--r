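#' Feature matrix container
#'
#' Holds an n x p table of voxel- or vertex-wise gray-matter measurements
#' together with per-feature 3D coordinates and metadata. Voxel features are
#' typically gray-matter density; vertex features cortical thickness or
#' surface area (units are carried as metadata and never enter arithmetic).
#'
#' @param values numeric matrix, n samples x p features.
#' @param coords numeric p x 3 matrix of feature positions (any consistent
#'   unit, e.g. lattice spacing or mm).
#' @param kind `"voxel"` or `"vertex"`.
#' @param sample_ids character vector of length n; defaults to rownames or
#'   `"S1"..."Sn"`.
#' @param feature_ids character vector of length p.
#' @param modality optional per-feature tag (e.g. `"density"`, `"thickness"`).
#' @param roi optional per-feature region-of-interest label; `NA` means
#'   unannotated.
#' @param units free-text unit tag (metadata only).
#' @return An object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(values, coords, kind = c("voxel", "vertex"),
                           sample_ids = NULL, feature_ids = NULL,
                           modality = NULL, roi = NULL, units = NA_character_) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  coords <- as.matrix(coords)
  n <- nrow(values); p <- ncol(values)
  if (p < 1L) stop2("feature_matrix: need at least one feature")
  if (n < 3L) stop2("feature_matrix: need at least 3 samples")
  if (nrow(coords) != p || ncol(coords) != 3L)
    stop2("feature_matrix: coords must be p x 3")
  if (any(!is.finite(coords))) stop2("feature_matrix: coords must be finite")
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("S", seq_len(n))
  feature_ids <- feature_ids %||% colnames(values) %||% paste0("F", seq_len(p))
  if (anyDuplicated(sample_ids)) stop2("feature_matrix: duplicated sample ids")
  if (anyDuplicated(feature_ids)) stop2("feature_matrix: duplicated feature ids")
  dimnames(values) <- list(sample_ids, feature_ids)
  rownames(coords) <- feature_ids
  if (!is.null(modality)) modality <- rep_len(as.character(modality), p)
  if (!is.null(roi)) roi <- rep_len(as.character(roi), p)
  structure(list(values = values, coords = coords, kind = kind,
                 modality = modality, roi = roi, units = units),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d %s features\n",
              nrow(x$values), ncol(x$values), x$kind))
  if (!is.null(x$roi))
    cat(sprintf("  ROI labels: %d distinct\n", length(unique(stats::na.omit(x$roi)))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix
#'
#' `i` selects samples, `j` features; metadata (coords, modality, ROI) follows
#' the feature subset.
#'
#' @param x a [feature_matrix()].
#' @param i,j sample / feature indices (any standard indexing vector).
#' @param ... ignored.
#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  feature_matrix(x$values[i, j, drop = FALSE], x$coords[j, , drop = FALSE],
                 kind = x$kind,
                 modality = if (!is.null(x$modality)) x$modality[j],
                 roi = if (!is.null(x$roi)) x$roi[j],
                 units = x$units)
}

#' @rdname feature_matrix
#' @param x object to coerce/test.
#' @export
is_feature_matrix <- function(x) inherits(x, "feature_matrix")

#' Build a covariate design matrix
#'
#' Assembles a fixed-effect design with an intercept column from a data frame
#' or matrix of covariates (continuous or 0/1 coded). The design must be full
#' column rank after adding the intercept.
#'
#' @param data data frame or matrix of covariates (may be `NULL` for an
#'   intercept-only design).
#' @param n number of samples, required when `data` is `NULL`.
#' @param sample_ids optional sample identifiers (checked against rownames).
#' @return A numeric matrix with first column `"(Intercept)"` and attribute
#'   `"sample_ids"`.
#' @export
covariate_matrix <- function(data = NULL, n = NULL, sample_ids = NULL) {
  if (is.null(data)) {
    if (is.null(n)) stop2("covariate_matrix: need n for intercept-only design")
    C <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    data <- as.data.frame(data)
    n <- nrow(data)
    M <- stats::model.matrix(~ ., data = data)
    C <- M
  }
  if (qr(C)$rank < ncol(C))
    stop2("covariate_matrix: design is rank deficient")
  sample_ids <- sample_ids %||% rownames(data) %||% paste0("S", seq_len(n))
  rownames(C) <- sample_ids
  attr(C, "sample_ids") <- sample_ids
  C
}

#' Trait vector container
#'
#' @param values numeric trait values.
#' @param sample_ids sample identifiers (defaults to names or `"S1"...`).
#' @param trait_name label used in reports.
#' @return A named numeric vector with attribute `"trait_name"`.
#' @export
trait_vector <- function(values, sample_ids = NULL, trait_name = "trait") {
  sample_ids <- sample_ids %||% names(values) %||% paste0("S", seq_along(values))
  v <- as.numeric(values)
  if (length(unique(v[is.finite(v)])) < 2L)
    stop2("trait_vector: trait needs at least 2 distinct values")
  names(v) <- sample_ids
  attr(v, "trait_name") <- trait_name
  v
}
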
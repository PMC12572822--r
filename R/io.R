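# Plain-text persistence: TSV for tabular data (header row, sample id first
# column), JSON for small structured records.

#' Write / read a feature matrix as a TSV pair
#'
#' `<stem>_values.tsv` holds the n x p table (first column `sample_id`);
#' `<stem>_features.tsv` the per-feature metadata (`feature_id`, `x`, `y`,
#' `z`, `modality`, `roi`) plus a `kind` column.
#'
#' @param X a [feature_matrix()].
#' @param stem path stem (directory must exist).
#' @return `write_features()` returns the stem invisibly; `read_features()`
#'   the reconstructed [feature_matrix()].
#' @export
write_features <- function(X, stem) {
  stopifnot(is_feature_matrix(X))
  vals <- data.frame(sample_id = rownames(X$values), X$values,
                     check.names = FALSE)
  utils::write.table(vals, paste0(stem, "_values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(feature_id = colnames(X$values),
                     x = X$coords[, 1], y = X$coords[, 2], z = X$coords[, 3],
                     kind = X$kind,
                     modality = X$modality %||% NA_character_,
                     roi = X$roi %||% NA_character_)
  utils::write.table(meta, paste0(stem, "_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_features
#' @export
read_features <- function(stem) {
  vals <- utils::read.delim(paste0(stem, "_values.tsv"), check.names = FALSE)
  meta <- utils::read.delim(paste0(stem, "_features.tsv"))
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$sample_id
  feature_matrix(m, as.matrix(meta[, c("x", "y", "z")]),
                 kind = meta$kind[1],
                 feature_ids = meta$feature_id,
                 modality = if (!all(is.na(meta$modality))) meta$modality,
                 roi = if (!all(is.na(meta$roi))) meta$roi)
}

#' Write / read a trait or covariate table as TSV
#'
#' Header row; first column `sample_id`.
#'
#' @param x named trait vector or covariate matrix/data frame.
#' @param path output file.
#' @export
write_phenotype <- function(x, path) {
  if (is.null(dim(x))) {
    df <- data.frame(sample_id = names(x) %||% seq_along(x), value = as.numeric(x))
  } else {
    df <- data.frame(sample_id = rownames(x) %||% seq_len(nrow(x)), x,
                     check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) == 2L) {
    trait_vector(df[[2]], sample_ids = as.character(df[[1]]),
                 trait_name = names(df)[2])
  } else {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  }
}

#' Write an association table as TSV
#'
#' Columns: feature_id, coordinates (when available), beta, se, z, p.
#'
#' @param assoc an `"assoc_table"`.
#' @param path output file.
#' @param coords optional p x 3 coordinates to include.
#' @export
write_assoc <- function(assoc, path, coords = NULL) {
  out <- assoc
  if (!is.null(coords)) {
    out$coord_x <- coords[, 1]; out$coord_y <- coords[, 2]
    out$coord_z <- coords[, 3]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
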
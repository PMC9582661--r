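# Plain-text persistence: TSV matrices with residue-number headers, JSON
# label maps, merge tables and edge lists.

#' Write / read a symmetric matrix as TSV
#'
#' The first row and column carry the residue numbers of the selected
#' atoms, so the file is self-describing.
#'
#' @param M matrix.
#' @param path file path.
#' @param ids row/column identifiers (residue numbers); default `1..n`.
#' @return `path` (write) or the matrix with ids as dimnames (read).
#' @export
write_matrix_tsv <- function(M, path, ids = NULL) {
  ids <- ids %||% seq_len(nrow(M))
  df <- data.frame(residue = ids, M, check.names = FALSE)
  colnames(df) <- c("residue", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(ids, ids)
  if (nrow(M) != ncol(M)) abort_format("matrix TSV is not square: ", path)
  M
}

#' Write / read cluster labels as JSON
#'
#' Serialised as a map from residue number to label.
#'
#' @param labels integer labels.
#' @param path file path.
#' @param ids residue numbers; default `1..n`.
#' @return `path` (write); read returns a list with `labels` and `ids`.
#' @export
write_labels_json <- function(labels, path, ids = NULL) {
  ids <- ids %||% seq_along(labels)
  obj <- as.list(as.integer(unclass(labels)))
  names(obj) <- as.character(ids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels_json
#' @export
read_labels_json <- function(path) {
  obj <- jsonlite::read_json(path)
  list(labels = as.integer(unlist(obj, use.names = FALSE)),
       ids = as.integer(names(obj)))
}

#' Write a dendrogram merge table as TSV
#'
#' Columns `left`, `right` (hclust coding: negative = singleton atom,
#' positive = earlier merge), `height` and `size` of the created cluster.
#'
#' @param dend an [agglomerate()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_merge_tsv <- function(dend, path) {
  sizes <- lengths(merge_members(dend))
  df <- data.frame(left = dend$merge[, 1], right = dend$merge[, 2],
                   height = dend$height, size = sizes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a consensus edge list as TSV
#' @param edges data frame from [circular_edges()].
#' @param path file path.
#' @param ids residue numbers mapping atom indices to reported ids.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(edges, path, ids = NULL) {
  out <- edges
  if (!is.null(ids)) {
    out$residue_i <- ids[edges$i]
    out$residue_j <- ids[edges$j]
    out <- out[, c("residue_i", "residue_j", "delta")]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
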
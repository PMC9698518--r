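#' Paired spliced/unspliced count dataset
#'
#' The container passed between all pipeline stages: two cells x genes
#' layers (spliced and unspliced), per-cell and per-gene metadata, and
#' provenance flags recording which transformations have been applied.
#'
#' @param spliced,unspliced numeric cells x genes matrices of identical
#'   shape with non-negative entries.
#' @param cell_meta data.frame with at least a \code{cell_id} column; a
#'   \code{cluster} column is required before feature selection.
#' @param gene_meta data.frame with at least a \code{gene_id} column.
#' @param normalized,logged provenance flags (set by [normalize_counts()]).
#' @param log_spliced optional cells x genes log1p-transformed spliced layer.
#' @return an object of class \code{"count_dataset"}.
#' @export
count_dataset <- function(spliced, unspliced, cell_meta = NULL, gene_meta = NULL,
                          normalized = FALSE, logged = FALSE, log_spliced = NULL) {
  spliced <- as.matrix(spliced); unspliced <- as.matrix(unspliced)
  if (!identical(dim(spliced), dim(unspliced)))
    stopf("spliced and unspliced layers must have identical shape")
  if (any(spliced < 0) || any(unspliced < 0))
    stopf("count layers must be non-negative")
  n <- nrow(spliced); p <- ncol(spliced)
  if (is.null(cell_meta))
    cell_meta <- data.frame(cell_id = sprintf("cell_%d", seq_len(n)))
  if (is.null(gene_meta))
    gene_meta <- data.frame(gene_id = sprintf("gene_%d", seq_len(p)))
  if (nrow(cell_meta) != n) stopf("cell_meta has %d rows, expected %d", nrow(cell_meta), n)
  if (nrow(gene_meta) != p) stopf("gene_meta has %d rows, expected %d", nrow(gene_meta), p)
  rownames(spliced) <- rownames(unspliced) <- cell_meta$cell_id
  colnames(spliced) <- colnames(unspliced) <- gene_meta$gene_id
  structure(list(spliced = spliced, unspliced = unspliced,
                 cell_meta = cell_meta, gene_meta = gene_meta,
                 normalized = normalized, logged = logged,
                 log_spliced = log_spliced),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d cells x %d genes\n", nrow(x$spliced), ncol(x$spliced)))
  if (!is.null(x$cell_meta$cluster)) {
    tab <- table(x$cell_meta$cluster)
    cat(sprintf("  clusters: %s\n",
                paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  }
  frac <- sum(x$unspliced) / max(sum(x$unspliced) + sum(x$spliced), .Machine$double.eps)
  cat(sprintf("  unspliced fraction: %.3f\n", frac))
  cat(sprintf("  normalized: %s, log layer: %s\n", x$normalized,
              !is.null(x$log_spliced)))
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$spliced)

# Subset genes (columns) of every layer consistently.
subset_genes <- function(ds, idx) {
  ds$spliced <- ds$spliced[, idx, drop = FALSE]
  ds$unspliced <- ds$unspliced[, idx, drop = FALSE]
  if (!is.null(ds$log_spliced)) ds$log_spliced <- ds$log_spliced[, idx, drop = FALSE]
  ds$gene_meta <- ds$gene_meta[idx, , drop = FALSE]
  rownames(ds$gene_meta) <- NULL
  ds
}

#' Write a count dataset to an MTX + TSV bundle
#'
#' Writes \code{spliced.mtx} and \code{unspliced.mtx} (MatrixMarket
#' coordinate format), \code{cells.tsv} and \code{genes.tsv} into
#' \code{dir}. The inverse of [read_dataset()].
#'
#' @param ds a [count_dataset()].
#' @param dir output directory, created if missing.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "count_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(ds$spliced, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "spliced.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(ds$unspliced, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "unspliced.mtx"))
  utils::write.table(ds$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count dataset from an MTX + TSV bundle
#'
#' @param dir directory holding \code{spliced.mtx}, \code{unspliced.mtx},
#'   \code{cells.tsv}, \code{genes.tsv} as written by [write_dataset()].
#' @return a [count_dataset()].
#' @export
read_dataset <- function(dir) {
  spliced <- as.matrix(Matrix::readMM(file.path(dir, "spliced.mtx")))
  unspliced <- as.matrix(Matrix::readMM(file.path(dir, "unspliced.mtx")))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  count_dataset(spliced, unspliced, cell_meta = cells, gene_meta = genes)
}
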
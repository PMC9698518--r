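#' Rank velocity genes per cluster
#'
#' Orders genes, within each cluster, by the descending Welch t-statistic
#' of their velocity values in-cluster versus all other cells — genes
#' whose velocity most distinguishes the cluster rank first. Ties break
#' by gene id. With a single cluster the ranking is global, by descending
#' absolute mean velocity.
#'
#' @param v a \code{"velocity_field"}.
#' @param clusters per-cell cluster labels (length = cells).
#' @param min_cells clusters smaller than this are skipped with a warning.
#' @return named list: cluster -> character vector of gene ids, ordered.
#' @export
rank_velocity_genes <- function(v, clusters, min_cells = 3) {
  stopifnot(inherits(v, "velocity_field"))
  if (length(clusters) != nrow(v$velocity))
    stopf("clusters length must match the number of cells")
  genes <- as.character(v$genes)
  uc <- sort(unique(as.character(clusters)))
  if (length(uc) == 1) {
    stat <- abs(colMeans(v$velocity))
    return(stats::setNames(list(genes[order(-stat, genes)]), uc))
  }
  out <- list()
  for (cl in uc) {
    sel <- clusters == cl
    if (sum(sel) < min_cells) {
      warnf("cluster %s has < %d cells; skipped in gene ranking", cl, min_cells)
      next
    }
    a <- v$velocity[sel, , drop = FALSE]
    b <- v$velocity[!sel, , drop = FALSE]
    na <- nrow(a); nb <- nrow(b)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
    se <- sqrt(va / na + vb / nb)
    tt <- ifelse(se > 0, (ma - mb) / se, 0)
    out[[cl]] <- genes[order(-tt, genes)]
  }
  if (length(out) == 0) stopf("no cluster had >= %d cells", min_cells)
  out
}

#' Build the classifier feature matrix
#'
#' Takes the top \code{k} ranked genes of each cluster, unions them
#' (deduplicating while preserving first occurrence) and extracts the
#' corresponding columns of the log-normalized spliced layer. The
#' features are expression values — the classifier's task is to predict
#' the velocity direction of a cell from its gene expression.
#'
#' @param ds a normalized [count_dataset()] with the log layer.
#' @param rankings per-cluster gene rankings from [rank_velocity_genes()].
#' @param k genes taken per cluster (default 20).
#' @return object of class \code{"feature_table"} with \code{matrix}
#'   (cells x p), \code{gene_ids} and \code{per_cluster_rankings}.
#' @export
build_features <- function(ds, rankings, k = 20) {
  stopifnot(inherits(ds, "count_dataset"))
  if (k < 1) stopf("k must be >= 1")
  if (is.null(ds$log_spliced))
    stopf("build_features requires the log layer; run normalize_counts() first")
  sel <- unlist(lapply(rankings, function(g) g[seq_len(min(k, length(g)))]),
                use.names = FALSE)
  sel <- sel[!duplicated(sel)]
  if (length(sel) == 0) stopf("empty feature union")
  idx <- match(sel, ds$gene_meta$gene_id)
  if (anyNA(idx)) stopf("ranked gene ids missing from dataset")
  m <- ds$log_spliced[, idx, drop = FALSE]
  colnames(m) <- sel
  structure(list(matrix = m, gene_ids = sel, per_cluster_rankings = rankings,
                 k = as.integer(k)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d cells x %d features (top %d per cluster, %d clusters)\n",
              nrow(x$matrix), length(x$gene_ids), x$k,
              length(x$per_cluster_rankings)))
  invisible(x)
}
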
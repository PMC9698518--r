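#' Filter genes by shared spliced/unspliced counts
#'
#' Keeps genes whose summed spliced counts and summed unspliced counts each
#' reach \code{min_shared_counts}; both layers are subset identically.
#'
#' @param ds a [count_dataset()] with raw counts.
#' @param min_shared_counts non-negative threshold (default 20).
#' @return the filtered [count_dataset()].
#' @export
filter_genes <- function(ds, min_shared_counts = 20) {
  stopifnot(inherits(ds, "count_dataset"))
  if (min_shared_counts < 0) stopf("min_shared_counts must be >= 0")
  keep <- colSums(ds$spliced) >= min_shared_counts &
    colSums(ds$unspliced) >= min_shared_counts
  if (!any(keep))
    stopf("filter_genes removed every gene (min_shared_counts = %s)",
          format(min_shared_counts))
  subset_genes(ds, which(keep))
}

#' Tiered highly-variable-gene count rule
#'
#' Maps a dataset's cell count to the number of highly variable genes to
#' retain: 2000 below 3000 cells, 2500 between 3000 and 6000 cells, 3000
#' above 6000 cells. The boundaries 3000 and 6000 fall in the middle tier.
#'
#' @param n_cells number of cells (>= 1).
#' @return integer HVG count (2000, 2500 or 3000).
#' @examples
#' hvg_count_rule(2930) # 2000
#' hvg_count_rule(3696) # 2500
#' hvg_count_rule(7202) # 3000
#' @export
hvg_count_rule <- function(n_cells) {
  if (any(n_cells < 1)) stopf("n_cells must be >= 1")
  ifelse(n_cells < 3000, 2000L, ifelse(n_cells <= 6000, 2500L, 3000L))
}

#' Select highly variable genes
#'
#' Ranks genes by the binned normalized dispersion of log-normalized
#' spliced expression (dispersion = variance/mean, z-scored within 20
#' mean-quantile bins) and keeps the top \code{n_top}. Ties break by gene
#' id, so the selection is deterministic.
#'
#' @param ds a normalized [count_dataset()] (see [normalize_counts()]).
#' @param n_top number of genes to keep (all genes if fewer exist).
#' @param n_bins number of mean-expression bins (default 20).
#' @return the subset [count_dataset()], genes in original column order.
#' @export
select_hvgs <- function(ds, n_top, n_bins = 20) {
  stopifnot(inherits(ds, "count_dataset"))
  if (n_top < 1) stopf("n_top must be >= 1")
  if (is.null(ds$log_spliced))
    stopf("select_hvgs requires the log layer; run normalize_counts() first")
  p <- ncol(ds$spliced)
  if (n_top >= p) return(ds)
  expr <- expm1(ds$log_spliced)
  m <- colMeans(expr)
  v <- apply(expr, 2, stats::var)
  disp <- ifelse(m > 0, v / m, 0)
  # keep >= 5 genes per bin so within-bin z-scores stay meaningful
  n_bins <- max(1L, min(n_bins, length(m) %/% 5L))
  bins <- cut(rank(m, ties.method = "first"),
              breaks = seq(0, length(m), length.out = n_bins + 1),
              labels = FALSE, include.lowest = TRUE)
  z <- disp
  for (bn in unique(bins)) {
    idx <- bins == bn
    mu <- mean(disp[idx]); sdv <- stats::sd(disp[idx])
    z[idx] <- if (is.na(sdv) || sdv == 0) 0 else (disp[idx] - mu) / sdv
  }
  ord <- order(-z, ds$gene_meta$gene_id)
  keep <- sort(ord[seq_len(n_top)])
  subset_genes(ds, keep)
}

#' Depth-normalize counts and add the log layer
#'
#' Applies per-cell size-factor scaling separately to the spliced and
#' unspliced layers: each cell's counts in a layer are scaled so its total
#' equals the median of that layer's cell totals. A log1p-transformed copy
#' of the normalized spliced layer is stored for HVG selection and
#' embedding; the velocity layers remain normalized but unlogged.
#' Re-normalizing an already normalized dataset is rejected.
#'
#' @param ds a raw [count_dataset()].
#' @return the normalized [count_dataset()] with \code{log_spliced} set.
#' @export
normalize_counts <- function(ds) {
  stopifnot(inherits(ds, "count_dataset"))
  if (isTRUE(ds$normalized))
    stopf("dataset is already normalized; refusing to compound size factors")
  norm_layer <- function(m) {
    tot <- rowSums(m)
    med <- stats::median(tot[tot > 0])
    if (any(tot == 0)) {
      warnf("%d cell(s) with zero total counts get size factor 1", sum(tot == 0))
      tot[tot == 0] <- med
    }
    m * (med / tot)
  }
  ds$spliced <- norm_layer(ds$spliced)
  ds$unspliced <- norm_layer(ds$unspliced)
  ds$log_spliced <- log1p(ds$spliced)
  ds$normalized <- TRUE
  ds$logged <- TRUE
  ds
}

#' Neighborhood moments of the count layers
#'
#' Builds a k-nearest-neighbour graph on Euclidean distance in the top
#' \code{n_pcs} principal components of the log layer, then computes the
#' first and second moments of the unspliced and spliced layers over each
#' cell's neighbor set (the cell itself included, so \code{k_neighbors = 1}
#' is the identity).
#'
#' @param ds a normalized [count_dataset()].
#' @param n_pcs number of principal components for the graph (default 30,
#'   capped at the data rank).
#' @param k_neighbors neighborhood size including self (default 30, must be
#'   less than the number of cells).
#' @return a list of class \code{"moments_result"} with \code{Mu},
#'   \code{Ms}, \code{Mu2}, \code{Ms2} (cells x genes) and
#'   \code{knn_indices} (cells x k).
#' @export
compute_moments <- function(ds, n_pcs = 30, k_neighbors = 30) {
  stopifnot(inherits(ds, "count_dataset"))
  if (k_neighbors <= 0) stopf("k_neighbors must be positive")
  if (is.null(ds$log_spliced))
    stopf("compute_moments requires the log layer; run normalize_counts() first")
  n <- nrow(ds$spliced)
  if (k_neighbors >= n && k_neighbors > 1)
    stopf("k_neighbors (%d) must be < n_cells (%d)", k_neighbors, n)
  n_pcs <- min(n_pcs, ncol(ds$log_spliced), n - 1)
  pcs <- stats::prcomp(ds$log_spliced, center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  nn <- knn_indices(pcs, k_neighbors)
  smooth <- function(m) {
    out <- matrix(0, n, ncol(m))
    for (i in seq_len(n)) out[i, ] <- colMeans(m[nn[i, ], , drop = FALSE])
    dimnames(out) <- dimnames(m)
    out
  }
  structure(list(Mu = smooth(ds$unspliced), Ms = smooth(ds$spliced),
                 Mu2 = smooth(ds$unspliced^2), Ms2 = smooth(ds$spliced^2),
                 knn_indices = nn),
            class = "moments_result")
}
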
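#' Two-dimensional principal-component embedding
#'
#' Top-2 principal components of the log-normalized spliced layer over a
#' given gene set, with a deterministic sign convention (the
#' largest-magnitude loading of each component is made positive) so
#' repeated runs are bit-identical.
#'
#' @param ds a normalized [count_dataset()] with the log layer present.
#' @param genes optional character vector of gene ids to embed on
#'   (default: all genes in \code{ds}).
#' @return object of class \code{"embedding2d"} with \code{coords}
#'   (cells x 2), \code{loadings} (genes x 2), \code{center} and
#'   \code{genes}.
#' @export
embed_pca2 <- function(ds, genes = NULL) {
  stopifnot(inherits(ds, "count_dataset"))
  if (is.null(ds$log_spliced))
    stopf("embed_pca2 requires the log layer; run normalize_counts() first")
  X <- ds$log_spliced
  if (!is.null(genes)) {
    idx <- match(genes, ds$gene_meta$gene_id)
    if (anyNA(idx)) stopf("unknown gene ids in embedding gene set")
    X <- X[, idx, drop = FALSE]
  } else {
    genes <- ds$gene_meta$gene_id
  }
  if (ncol(X) < 2) stopf("embedding needs at least 2 genes")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  load <- pc$rotation[, 1:2, drop = FALSE]
  for (k in 1:2) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  ctr <- pc$center
  coords <- sweep(X, 2, ctr) %*% load
  structure(list(coords = coords, loadings = load, center = ctr,
                 genes = genes, method = "pca"),
            class = "embedding2d")
}

#' Project a velocity field into a 2D embedding
#'
#' Exact linear pushforward: \code{displacement = velocity \%*\% loadings}.
#' Valid only for linear embeddings whose gene set matches the field's.
#'
#' @param v a \code{"velocity_field"}.
#' @param emb an [embed_pca2()] result.
#' @return cells x 2 matrix of displacements \code{(dx, dy)}.
#' @export
project_velocity <- function(v, emb) {
  stopifnot(inherits(v, "velocity_field"), inherits(emb, "embedding2d"))
  if (!identical(as.character(v$genes), as.character(emb$genes)))
    stopf("velocity field and embedding are over different gene sets")
  d <- v$velocity %*% emb$loadings
  colnames(d) <- c("dx", "dy")
  d
}

#' Map a 2D displacement to an angular class
#'
#' The plane is divided into \code{d} equal half-open angular segments
#' \eqn{[2\pi c/d, 2\pi (c+1)/d)}, counterclockwise from the +x axis;
#' the class is \eqn{\lfloor d\,\theta / 2\pi \rfloor} with
#' \eqn{\theta = \mathrm{atan2}(dy, dx)} mapped into \eqn{[0, 2\pi)}.
#'
#' @param dx,dy displacement components (vectors allowed).
#' @param d number of classes (>= 2).
#' @return integer class in \code{0..d-1}; \code{NA} for zero
#'   displacements (no direction is fabricated for them).
#' @examples
#' angle_to_class(1, 0, 4)   # 0
#' angle_to_class(0, 1, 4)   # 1 (boundary goes to the higher class)
#' angle_to_class(-1, -1, 8) # 5
#' @export
angle_to_class <- function(dx, dy, d = 4) {
  if (d < 2) stopf("d must be >= 2, got %d", d)
  theta <- atan2(dy, dx) %% (2 * pi)
  cls <- as.integer(floor(d * theta / (2 * pi))) %% d
  cls[dx == 0 & dy == 0] <- NA_integer_
  cls
}

#' Assign direction classes to every cell
#'
#' Projects the velocity field through the 2D embedding and discretizes
#' the displacement angle into \code{d} classes. Cells with exactly zero
#' displacement are left unlabeled (\code{NA}) and reported, rather than
#' being assigned an arbitrary direction.
#'
#' @param v a \code{"velocity_field"}.
#' @param emb an [embed_pca2()] result over the same genes.
#' @param d number of angular classes (default 4).
#' @return object of class \code{"direction_labels"}: data.frame-like list
#'   with \code{displacement}, \code{angle}, \code{class_label}, \code{d}.
#' @export
direction_labels <- function(v, emb, d = 4) {
  disp <- project_velocity(v, emb)
  cls <- angle_to_class(disp[, 1], disp[, 2], d)
  theta <- atan2(disp[, 2], disp[, 1]) %% (2 * pi)
  theta[is.na(cls)] <- NA_real_
  n_zero <- sum(is.na(cls))
  if (n_zero > 0)
    message(sprintf("direction_labels: %d cell(s) with zero displacement left unlabeled", n_zero))
  structure(list(displacement = disp, angle = theta,
                 class_label = cls, d = as.integer(d)),
            class = "direction_labels")
}

#' @export
print.direction_labels <- function(x, ...) {
  cat(sprintf("direction_labels: %d cells, d = %d\n",
              length(x$class_label), x$d))
  print(table(class = x$class_label, useNA = "ifany"))
  invisible(x)
}
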
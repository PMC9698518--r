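#' SMOTE oversampling
#'
#' Oversamples every minority class up to the majority-class count with
#' synthetic points interpolated between a class member \eqn{x_i} and one
#' of its \code{k_neighbors} nearest same-class neighbors \eqn{x_{nn}}:
#' \eqn{x_i + \lambda (x_{nn} - x_i)}, \eqn{\lambda \sim U(0,1)}. All
#' original rows are kept unchanged; the same seed gives bit-identical
#' synthetic rows.
#'
#' @param x numeric n x p feature matrix.
#' @param y length-n class labels.
#' @param k_neighbors candidate same-class neighbors per base point
#'   (default 5, capped at class size - 1).
#' @param seed integer seed.
#' @return object of class \code{"resampled_set"}: \code{matrix},
#'   \code{labels}, \code{synthetic_flag}, \code{removed_ids} (empty).
#' @export
smote <- function(x, y, k_neighbors = 5, seed = 1) {
  x <- as.matrix(x); y <- as.character(y)
  if (nrow(x) != length(y)) stopf("x rows and y length differ")
  if (k_neighbors < 1) stopf("k_neighbors must be >= 1")
  tab <- table(y)
  if (any(tab < 2)) {
    bad <- names(tab)[tab < 2]
    stopf("SMOTE needs >= 2 samples per class; singleton class(es): %s",
          paste(bad, collapse = ", "))
  }
  maj <- max(tab)
  syn_x <- list(); syn_y <- character(0)
  with_seed(derive_seed(seed, 303), {
    for (cl in sort(names(tab))) {
      need <- maj - tab[[cl]]
      if (need == 0) next
      rows <- which(y == cl)
      xc <- x[rows, , drop = FALSE]
      k <- min(k_neighbors, length(rows) - 1)
      d <- as.matrix(stats::dist(xc))
      diag(d) <- Inf
      nn_ord <- apply(d, 1, function(r) order(r, seq_along(r))[seq_len(k)])
      nn <- if (k == 1) matrix(nn_ord, ncol = 1) else t(nn_ord)
      base <- sample.int(length(rows), need, replace = TRUE)
      pick <- sample.int(k, need, replace = TRUE)
      lam <- stats::runif(need)
      xi <- xc[base, , drop = FALSE]
      xn <- xc[nn[cbind(base, pick)], , drop = FALSE]
      syn_x[[cl]] <- xi + lam * (xn - xi)
      syn_y <- c(syn_y, rep(cl, need))
    }
  })
  new_x <- rbind(x, do.call(rbind, unname(syn_x)))
  new_y <- c(y, syn_y)
  rownames(new_x) <- NULL
  structure(list(matrix = new_x, labels = new_y,
                 synthetic_flag = c(rep(FALSE, nrow(x)), rep(TRUE, length(syn_y))),
                 removed_ids = integer(0)),
            class = "resampled_set")
}

# 1-nearest-neighbour index per row (self excluded, ties by row index).
.nn1 <- function(x) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  apply(d, 1, function(r) order(r, seq_along(r))[1])
}

#' Find Tomek links
#'
#' A Tomek link is a pair of mutual nearest neighbors (Euclidean) with
#' different class labels. Exposed separately so the detection can be
#' audited against brute force.
#'
#' @param x numeric n x p matrix.
#' @param y length-n labels.
#' @return two-column integer matrix of row pairs (i < j).
#' @export
tomek_links <- function(x, y) {
  x <- as.matrix(x); y <- as.character(y)
  nn <- .nn1(x)
  i <- seq_len(nrow(x))
  sel <- nn[nn[i]] == i & y[i] != y[nn[i]] & i < nn[i]
  cbind(i = i[sel], j = nn[i][sel])
}

#' Tomek-link cleaning
#'
#' Removes, from every Tomek link, the member(s) that do not belong to a
#' minority class (a class of minimal count); minority members are never
#' removed, limiting information loss. Deterministic.
#'
#' @param x numeric n x p matrix.
#' @param y length-n labels (>= 2 classes).
#' @param minority character vector of protected class labels; defaults
#'   to the class(es) of minimal count in \code{y}. [smote_tomek()]
#'   passes the originally under-represented classes so cleaning still
#'   trims the majority side after exact balancing.
#' @return object of class \code{"resampled_set"} with \code{removed_ids}
#'   holding the original row indices dropped.
#' @export
tomek_clean <- function(x, y, minority = NULL) {
  x <- as.matrix(x); y <- as.character(y)
  if (length(unique(y)) < 2) stopf("tomek_clean needs >= 2 classes")
  tab <- table(y)
  if (is.null(minority)) minority <- names(tab)[tab == min(tab)]
  links <- tomek_links(x, y)
  cand <- unique(as.vector(links))
  remove <- cand[!(y[cand] %in% minority)]
  keep <- setdiff(seq_len(nrow(x)), remove)
  structure(list(matrix = x[keep, , drop = FALSE], labels = y[keep],
                 synthetic_flag = rep(FALSE, length(keep)),
                 removed_ids = sort(remove)),
            class = "resampled_set")
}

#' SMOTE followed by Tomek-link cleaning
#'
#' The combined resampler applied to training data: oversample minority
#' classes to exact balance, then clean boundary pairs.
#'
#' @inheritParams smote
#' @return a \code{"resampled_set"}; \code{removed_ids} indexes rows of
#'   the post-SMOTE matrix.
#' @export
smote_tomek <- function(x, y, k_neighbors = 5, seed = 1) {
  tab <- table(as.character(y))
  minority <- names(tab)[tab < max(tab)]
  if (length(minority) == 0) minority <- names(tab)
  sm <- smote(x, y, k_neighbors = k_neighbors, seed = seed)
  tk <- tomek_clean(sm$matrix, sm$labels, minority = minority)
  tk$synthetic_flag <- sm$synthetic_flag[setdiff(seq_len(nrow(sm$matrix)),
                                                 tk$removed_ids)]
  tk
}

#' @export
print.resampled_set <- function(x, ...) {
  cat(sprintf("resampled_set: %d rows (%d synthetic, %d removed)\n",
              nrow(x$matrix), sum(x$synthetic_flag), length(x$removed_ids)))
  print(table(x$labels))
  invisible(x)
}
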
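#' Confusion matrix
#'
#' \code{counts[i, j]} is the number of samples with true class \code{i-1}
#' predicted as class \code{j-1}; rows carry the true-class marginals
#' \eqn{a_i}, columns the predicted-class marginals \eqn{b_i}.
#'
#' @param true_labels,predicted_labels integer vectors in \code{0..C-1}.
#' @param C number of classes (default: inferred from the labels).
#' @return object of class \code{"confusion_matrix"}.
#' @export
confusion <- function(true_labels, predicted_labels, C = NULL) {
  t0 <- as.integer(true_labels); p0 <- as.integer(predicted_labels)
  if (length(t0) != length(p0)) stopf("label vectors differ in length")
  if (is.null(C)) C <- max(t0, p0) + 1L
  if (any(t0 < 0 | t0 >= C | p0 < 0 | p0 >= C))
    stopf("labels out of range 0..%d", C - 1)
  counts <- matrix(0L, C, C,
                   dimnames = list(true = 0:(C - 1), pred = 0:(C - 1)))
  for (i in seq_along(t0))
    counts[t0[i] + 1L, p0[i] + 1L] <- counts[t0[i] + 1L, p0[i] + 1L] + 1L
  structure(list(counts = counts, n = length(t0), C = as.integer(C)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: %d classes, n = %d\n", x$C, x$n))
  print(x$counts)
  invisible(x)
}

as_cm <- function(cm) {
  if (inherits(cm, "confusion_matrix")) return(cm)
  m <- as.matrix(cm)
  structure(list(counts = m, n = sum(m), C = nrow(m)), class = "confusion_matrix")
}

#' Classification accuracy
#'
#' Fraction of correct predictions, \eqn{\mathrm{trace}/n} — the
#' multiclass generalization of (TP+TN)/(TP+FP+TN+FN).
#'
#' @param cm a [confusion()] result (or a plain square count matrix).
#' @return scalar in \eqn{[0, 1]}.
#' @export
accuracy <- function(cm) {
  cm <- as_cm(cm)
  sum(diag(cm$counts)) / cm$n
}

per_class_pr <- function(cm) {
  cm <- as_cm(cm)
  tp <- diag(cm$counts)
  pred_tot <- colSums(cm$counts) # TP + FP
  true_tot <- rowSums(cm$counts) # TP + FN
  P <- ifelse(pred_tot > 0, tp / pred_tot, NA_real_)
  R <- ifelse(true_tot > 0, tp / true_tot, NA_real_)
  list(precision = P, recall = R)
}

#' Macro-averaged F1
#'
#' The harmonic mean of the macro-averaged precision and macro-averaged
#' recall, \eqn{2 P_{macro} R_{macro} / (P_{macro} + R_{macro})}. Note
#' this is not the mean of per-class F1 scores, which is a different
#' quantity. A class with no predicted instances has undefined precision;
#' it contributes 0 with a warning.
#'
#' @param cm a [confusion()] result (or a plain square count matrix).
#' @return scalar in \eqn{[0, 1]}.
#' @export
macro_f1 <- function(cm) {
  pr <- per_class_pr(cm)
  if (anyNA(pr$precision))
    warnf("%d class(es) never predicted: precision counted as 0", sum(is.na(pr$precision)))
  if (anyNA(pr$recall))
    warnf("%d class(es) absent from truth: recall counted as 0", sum(is.na(pr$recall)))
  Pm <- mean(ifelse(is.na(pr$precision), 0, pr$precision))
  Rm <- mean(ifelse(is.na(pr$recall), 0, pr$recall))
  if (Pm + Rm == 0) return(0)
  2 * Pm * Rm / (Pm + Rm)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{(p_0 - p_e)/(1 - p_e)} with
#' \eqn{p_0 = \mathrm{trace}/n} and \eqn{p_e = \sum_i a_i b_i / n^2} from
#' the confusion-matrix marginals. The degenerate case \eqn{p_e = 1}
#' (a single class on both sides) is defined as 0 with a warning.
#'
#' @param cm a [confusion()] result (or a plain square count matrix).
#' @return scalar in \eqn{[-1, 1]}.
#' @export
kappa_score <- function(cm) {
  cm <- as_cm(cm)
  p0 <- sum(diag(cm$counts)) / cm$n
  pe <- sum(rowSums(cm$counts) * colSums(cm$counts)) / cm$n^2
  if (pe >= 1) {
    warnf("degenerate single-class confusion matrix: kappa defined as 0")
    return(0)
  }
  (p0 - pe) / (1 - pe)
}

#' Full metrics report
#'
#' @param true_labels,predicted_labels integer class vectors in
#'   \code{0..C-1}.
#' @param C number of classes (default: inferred).
#' @return object of class \code{"metrics_report"} with \code{accuracy},
#'   \code{macro_precision}, \code{macro_recall}, \code{macro_f1},
#'   \code{kappa}, per-class precision/recall and the confusion matrix.
#' @export
metrics_report <- function(true_labels, predicted_labels, C = NULL) {
  cm <- confusion(true_labels, predicted_labels, C)
  pr <- per_class_pr(cm)
  Pm <- mean(ifelse(is.na(pr$precision), 0, pr$precision))
  Rm <- mean(ifelse(is.na(pr$recall), 0, pr$recall))
  structure(list(accuracy = accuracy(cm),
                 macro_precision = Pm, macro_recall = Rm,
                 macro_f1 = suppressWarnings(macro_f1(cm)),
                 kappa = suppressWarnings(kappa_score(cm)),
                 per_class_precision = pr$precision,
                 per_class_recall = pr$recall,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("accuracy %.4f | macro_F1 %.4f | kappa %.4f\n",
              x$accuracy, x$macro_f1, x$kappa))
  invisible(x)
}
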
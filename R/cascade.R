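#' Stratified k-fold assignment
#'
#' @param y factor of class labels.
#' @param n_folds number of folds; every class must have at least
#'   \code{n_folds} members so each fold contains every class.
#' @param seed integer seed.
#' @return integer fold id per sample.
#' @export
stratified_folds <- function(y, n_folds = 5, seed = 1) {
  y <- as.factor(y)
  tab <- table(y)
  if (any(tab < n_folds))
    stopf("stratification error: class(es) %s have fewer than %d samples",
          paste(names(tab)[tab < n_folds], collapse = ", "), n_folds)
  fold <- integer(length(y))
  with_seed(derive_seed(seed, 404), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

.ensure_colnames <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
  x
}

.aug_names <- function(n_est, d) {
  as.vector(t(outer(seq_len(n_est), seq_len(d) - 1L,
                    function(e, c) sprintf("cv_e%d_c%d", e, c))))
}

#' Fit a cascade forest classifier
#'
#' Grows a cascade of levels, each an ensemble of heterogeneous tree
#' ensembles (see [estimators]). At every level each estimator produces
#' out-of-fold (OOF) class-probability vectors via stratified
#' \code{n_folds}-fold cross-validation; the concatenated probability
#' vectors are appended to the original features to form the next
#' level's input, so level \eqn{\ell \ge 2} has input dimension
#' \eqn{p + E \cdot d} for \eqn{E} estimators and \eqn{d} classes. The
#' level score is the accuracy of the argmax of the estimators' averaged
#' OOF probabilities; growth stops when the score fails to improve by
#' more than \code{tol} for \code{patience} consecutive levels, and the
#' best-scoring level is used at prediction time. The per-fold models are
#' retained: inference averages them rather than refitting.
#'
#' @param x numeric n x p feature matrix (a data.frame is coerced).
#' @param y class labels (coerced to factor; >= 2 levels, each with at
#'   least \code{n_folds} members).
#' @param estimators list of estimator adapters (default: the four
#'   heterogeneous tree ensembles of [default_estimators()]).
#' @param n_folds folds for the OOF class vectors (default 5).
#' @param max_levels cap on cascade depth (default 8).
#' @param patience levels without improvement tolerated before stopping
#'   (default 1).
#' @param tol minimal score improvement that counts (default 1e-4).
#' @param seed integer seed; the whole fit is bit-reproducible given it.
#' @return an object of class \code{"cascade_forest"} with elements
#'   \code{levels} (per-level fold models and OOF matrices),
#'   \code{validation_history}, \code{best_level}, \code{classes},
#'   \code{p}, \code{fold_id}, \code{seed}.
#' @examples
#' \donttest{
#' set.seed(1)
#' x <- matrix(rnorm(200 * 4), 200)
#' y <- ifelse(x[, 1] + x[, 2] > 0, "a", "b")
#' fit <- cascade_forest(x, y, max_levels = 2, seed = 1)
#' table(predict(fit, x), y)
#' }
#' @export
cascade_forest <- function(x, y, estimators = default_estimators(),
                           n_folds = 5, max_levels = 8, patience = 1,
                           tol = 1e-4, seed = 1) {
  x <- .ensure_colnames(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stopf("need >= 2 classes")
  if (nrow(x) != length(y)) stopf("x rows and y length differ")
  d <- nlevels(y); n <- nrow(x); p <- ncol(x); E <- length(estimators)
  fold <- stratified_folds(y, n_folds, seed)

  levels_out <- list()
  history <- numeric(0)
  best <- -Inf; stall <- 0
  Z <- x
  for (lvl in seq_len(max_levels)) {
    oof <- vector("list", E)
    fits <- vector("list", E)
    for (e in seq_len(E)) {
      est <- estimators[[e]]
      po <- matrix(NA_real_, n, d, dimnames = list(NULL, levels(y)))
      fm <- vector("list", n_folds)
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        fit <- est$fit(Z[tr, , drop = FALSE], y[tr],
                       derive_seed(seed, lvl, e, f))
        fm[[f]] <- fit
        po[!tr, ] <- est$predict_proba(fit, Z[!tr, , drop = FALSE])
      }
      oof[[e]] <- po
      fits[[e]] <- fm
    }
    mean_oof <- Reduce(`+`, oof) / E
    score <- mean(levels(y)[max.col(mean_oof, ties.method = "first")] == y)
    history <- c(history, score)
    levels_out[[lvl]] <- list(fits = fits, oof = oof, score = score,
                              input_dim = ncol(Z))
    if (score > best + tol) {
      best <- score
      stall <- 0
    } else {
      stall <- stall + 1
    }
    if (stall >= patience) break
    aug <- do.call(cbind, oof)
    colnames(aug) <- .aug_names(E, d)
    Z <- cbind(x, aug)
  }

  structure(list(levels = levels_out, estimators = estimators,
                 validation_history = history,
                 best_level = which.max(history),
                 classes = levels(y), d = d, p = p,
                 feature_names = colnames(x),
                 n_folds = n_folds, fold_id = fold, seed = seed),
            class = "cascade_forest")
}

# Averaged fold-model probabilities of estimator e at one level.
.level_probs <- function(object, lvl, Z) {
  E <- length(object$estimators)
  lapply(seq_len(E), function(e) {
    est <- object$estimators[[e]]
    ps <- lapply(object$levels[[lvl]]$fits[[e]],
                 function(fit) est$predict_proba(fit, Z))
    Reduce(`+`, ps) / length(ps)
  })
}

#' Predict from a cascade forest
#'
#' Propagates new samples through levels 1..\code{best_level}; at each
#' level every estimator's class vector is the average over its retained
#' fold models, and the final probabilities average the estimators at the
#' best level. Argmax ties go to the lowest class index.
#'
#' @param object a [cascade_forest()] fit.
#' @param newdata numeric matrix with the original \code{p} columns.
#' @param type \code{"class"} for labels, \code{"prob"} for the class
#'   probability matrix.
#' @param ... unused.
#' @return a factor of labels, or an n x d probability matrix.
#' @export
predict.cascade_forest <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- .ensure_colnames(newdata)
  if (ncol(x) != object$p)
    stopf("newdata has %d columns, model expects %d", ncol(x), object$p)
  colnames(x) <- object$feature_names
  E <- length(object$estimators)
  Z <- x
  probs <- NULL
  for (lvl in seq_len(object$best_level)) {
    probs <- .level_probs(object, lvl, Z)
    if (lvl < object$best_level) {
      aug <- do.call(cbind, probs)
      colnames(aug) <- .aug_names(E, object$d)
      Z <- cbind(x, aug)
    }
  }
  pm <- Reduce(`+`, probs) / E
  colnames(pm) <- object$classes
  if (type == "prob") return(pm)
  factor(object$classes[max.col(pm, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.cascade_forest <- function(x, ...) {
  cat(sprintf("cascade_forest: %d level(s), %d classes, %d features\n",
              length(x$levels), x$d, x$p))
  cat(sprintf("  validation history: %s\n",
              paste(sprintf("%.4f", x$validation_history), collapse = " ")))
  cat(sprintf("  best level: %d (score %.4f)\n",
              x$best_level, x$validation_history[x$best_level]))
  invisible(x)
}

#' @export
summary.cascade_forest <- function(object, ...) {
  cat(sprintf("Cascade forest (seed %d)\n", object$seed))
  cat(sprintf("  estimators: %s\n",
              paste(vapply(object$estimators, `[[`, "", "kind"), collapse = ", ")))
  cat(sprintf("  %d-fold OOF class vectors, input dim level>=2: %d (= p + E*d)\n",
              object$n_folds,
              object$p + length(object$estimators) * object$d))
  print(object)
  oof <- Reduce(`+`, object$levels[[object$best_level]]$oof) /
    length(object$estimators)
  invisible(list(best_oof = oof))
}

#' @export
plot.cascade_forest <- function(x, ...) {
  plot(seq_along(x$validation_history), x$validation_history, type = "b",
       xlab = "cascade level", ylab = "OOF accuracy",
       main = "Cascade validation history", ...)
  graphics::abline(v = x$best_level, lty = 2)
  invisible(x)
}

.cascade_magic <- "velodirect_cascade_v1"

#' Save / load a cascade forest
#'
#' Round-trips a fitted cascade through a versioned file so that loaded
#' models predict bit-identically. Backend handles that do not survive R
#' serialization (e.g. boosted-tree pointers) are converted through the
#' adapters' \code{pack}/\code{unpack} hooks.
#'
#' @param model a [cascade_forest()] fit.
#' @param path file path.
#' @return \code{cascade_save}: \code{path} invisibly;
#'   \code{cascade_load}: the restored model.
#' @export
cascade_save <- function(model, path) {
  stopifnot(inherits(model, "cascade_forest"))
  for (lvl in seq_along(model$levels)) {
    for (e in seq_along(model$estimators)) {
      pk <- model$estimators[[e]]$pack
      if (!is.null(pk))
        model$levels[[lvl]]$fits[[e]] <-
          lapply(model$levels[[lvl]]$fits[[e]], pk)
    }
  }
  saveRDS(list(magic = .cascade_magic, model = model), path)
  invisible(path)
}

#' @rdname cascade_save
#' @export
cascade_load <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$magic, .cascade_magic))
    stopf("not a velodirect cascade model file (bad or missing magic header)")
  model <- obj$model
  for (lvl in seq_along(model$levels)) {
    for (e in seq_along(model$estimators)) {
      up <- model$estimators[[e]]$unpack
      if (!is.null(up))
        model$levels[[lvl]]$fits[[e]] <-
          lapply(model$levels[[lvl]]$fits[[e]], up)
    }
  }
  model
}
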
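#' Tree-ensemble estimator adapters for the cascade
#'
#' Each cascade level stacks four heterogeneous tree ensembles — two
#' bagging variants (a classical bootstrap random forest and an
#' extremely-randomized-trees forest) and two gradient-boosting variants
#' (depth-wise trees and shallow high-round trees). An adapter is a list
#' with fields \code{kind}, \code{fit(x, y, seed)} and
#' \code{predict_proba(model, x)}; the probability matrix has one column
#' per class level, rows summing to 1, and fits are deterministic given
#' the seed. Custom adapters honoring this contract can be passed to
#' [cascade_forest()], e.g. to bind other boosting libraries.
#'
#' @param ntree,nrounds ensemble sizes.
#' @return a single adapter, or for [default_estimators()] a list of the
#'   four default adapters.
#' @name estimators
NULL

# Probability matrix with a column for every level of `levels`, in order,
# filling zeros for classes the backend did not see (cannot occur under
# stratified folds, but keeps the contract total).
.full_prob <- function(p, levels) {
  out <- matrix(0, nrow(p), length(levels), dimnames = list(NULL, levels))
  out[, colnames(p)] <- p
  out
}

#' @rdname estimators
#' @export
estimator_rf <- function(ntree = 150) {
  list(
    kind = "bagging_rf",
    fit = function(x, y, seed) {
      with_seed(seed, {
        m <- randomForest::randomForest(x = as.data.frame(x), y = droplevels(y),
                                        ntree = ntree)
      })
      list(model = m, levels = levels(y))
    },
    predict_proba = function(fit, x) {
      p <- stats::predict(fit$model, as.data.frame(x), type = "prob")
      .full_prob(p, fit$levels)
    })
}

#' @rdname estimators
#' @export
estimator_extratrees <- function(ntree = 150) {
  list(
    kind = "bagging_extratrees",
    fit = function(x, y, seed) {
      m <- ranger::ranger(x = as.data.frame(x), y = y, num.trees = ntree,
                          probability = TRUE, splitrule = "extratrees",
                          num.random.splits = 1, seed = seed, num.threads = 1)
      list(model = m, levels = levels(y))
    },
    predict_proba = function(fit, x) {
      p <- stats::predict(fit$model, as.data.frame(x), num.threads = 1)$predictions
      .full_prob(p, fit$levels)
    })
}

.xgb_adapter <- function(kind, nrounds, params) {
  list(
    kind = kind,
    fit = function(x, y, seed) {
      nc <- nlevels(y)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                     label = as.integer(y) - 1L)
      m <- xgboost::xgb.train(
        params = c(params, list(objective = "multi:softprob", num_class = nc,
                                nthread = 1, seed = seed)),
        data = dtrain, nrounds = nrounds, verbose = 0)
      list(model = m, levels = levels(y))
    },
    predict_proba = function(fit, x) {
      p <- stats::predict(fit$model, xgboost::xgb.DMatrix(as.matrix(x)))
      p <- p / rowSums(p) # single-precision softmax drifts off 1
      colnames(p) <- fit$levels
      p
    },
    pack = function(fit) {
      fit$model <- xgboost::xgb.save.raw(fit$model)
      fit
    },
    unpack = function(fit) {
      fit$model <- xgboost::xgb.load.raw(fit$model)
      fit
    })
}

#' @rdname estimators
#' @export
estimator_boost_deep <- function(nrounds = 60) {
  .xgb_adapter("boosting_deep", nrounds,
               list(max_depth = 5, eta = 0.2, subsample = 0.8,
                    colsample_bytree = 0.8))
}

#' @rdname estimators
#' @export
estimator_boost_shallow <- function(nrounds = 80) {
  .xgb_adapter("boosting_shallow", nrounds,
               list(max_depth = 2, eta = 0.3, subsample = 0.9))
}

#' @rdname estimators
#' @export
default_estimators <- function() {
  list(estimator_rf(), estimator_extratrees(),
       estimator_boost_deep(), estimator_boost_shallow())
}
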
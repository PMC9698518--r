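#' Stratified train/test split
#'
#' Per-class proportional split: within each class, a seeded random
#' \code{ratio} fraction (rounded) goes to training and the rest to test;
#' the two index sets are disjoint and exhaustive.
#'
#' @param labels per-sample class labels (each class needs >= 2 members).
#' @param ratio training fraction in (0, 1) (default 0.8, the 8:2 split).
#' @param seed integer seed.
#' @return list with integer vectors \code{train} and \code{test}.
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1) {
  if (ratio <= 0 || ratio >= 1) stopf("ratio must be in (0, 1)")
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2))
    stopf("each class needs >= 2 members; too small: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  train <- integer(0)
  with_seed(derive_seed(seed, 505), {
    for (cl in sort(names(tab))) {
      idx <- which(labels == cl)
      n_tr <- min(max(round(ratio * length(idx)), 1), length(idx) - 1)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Experiment configuration
#'
#' Bundles the tunable parameters of the end-to-end run: velocity mode,
#' top genes per cluster \code{k}, number of direction classes \code{d},
#' the 8:2 train/test ratio, resampling toggle and preprocessing knobs.
#'
#' @param mode \code{"steady_state"} or \code{"dynamic"} velocity model.
#' @param k top velocity genes per cluster (default 20).
#' @param d number of angular direction classes (default 4).
#' @param split_ratio training fraction (default 0.8).
#' @param resample apply SMOTE-Tomek to the training split (default TRUE).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param min_shared_counts gene-filter threshold (default 20).
#' @param hvg \code{"auto"} for the tiered cell-count rule, or an integer
#'   override.
#' @param n_pcs,k_neighbors moment-smoothing graph parameters.
#' @param baselines also fit each estimator adapter standalone (default
#'   TRUE).
#' @param max_levels,patience,tol cascade growth controls.
#' @param em_n_grid,em_max_iter dynamic-model EM controls (see
#'   [fit_dynamic_em()]).
#' @return an object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(mode = c("steady_state", "dynamic"), k = 20, d = 4,
                              split_ratio = 0.8, resample = TRUE, smote_k = 5,
                              min_shared_counts = 20, hvg = "auto",
                              n_pcs = 30, k_neighbors = 30, baselines = TRUE,
                              max_levels = 8, patience = 1, tol = 1e-4,
                              em_n_grid = 240, em_max_iter = 50) {
  mode <- match.arg(mode)
  if (k < 1) stopf("k must be >= 1")
  if (d < 2) stopf("d must be >= 2")
  if (split_ratio <= 0 || split_ratio >= 1) stopf("split_ratio must be in (0, 1)")
  structure(as.list(environment()), class = "experiment_config")
}

#' Preprocess a raw dataset
#'
#' The standard stage chain: gene filter, depth normalization with log
#' layer, tiered HVG selection and kNN moment smoothing.
#'
#' @param ds a raw [count_dataset()].
#' @param config an [experiment_config()].
#' @return list with the processed \code{ds} and \code{moments}.
#' @export
preprocess <- function(ds, config = experiment_config()) {
  ds <- filter_genes(ds, config$min_shared_counts)
  ds <- normalize_counts(ds)
  n_top <- if (identical(config$hvg, "auto")) hvg_count_rule(nrow(ds$spliced))
           else as.integer(config$hvg)
  ds <- select_hvgs(ds, n_top)
  k_nn <- min(config$k_neighbors, nrow(ds$spliced) - 1)
  moments <- compute_moments(ds, n_pcs = config$n_pcs, k_neighbors = k_nn)
  list(ds = ds, moments = moments)
}

#' Run the end-to-end direction-classification experiment
#'
#' Executes the full pipeline on a raw dataset: preprocess, estimate
#' velocity (steady-state or dynamic), project to 2D and assign \code{d}
#' angular classes, build the top-\code{k}-per-cluster feature matrix,
#' split 8:2 stratified by class, SMOTE-Tomek the training split only,
#' fit the cascade forest plus (optionally) each single-ensemble
#' baseline, and evaluate accuracy / macro-F1 / kappa on the untouched
#' test split. Unsupervised stages (velocity fits, gene ranking) see all
#' cells; classifier fitting sees only training rows.
#'
#' @param ds a raw [count_dataset()] with a \code{cluster} column, e.g.
#'   from [simulate_population()] or [make_directional_benchmark()].
#' @param config an [experiment_config()].
#' @param seed integer seed controlling split, resampling and fits.
#' @return object of class \code{"run_report"}: per-classifier
#'   \code{"metrics_report"}s, the fitted \code{models}, the
#'   \code{labels} and test predictions, and a dataset \code{summary}.
#' @export
run_experiment <- function(ds, config = experiment_config(), seed = 1) {
  stopifnot(inherits(ds, "count_dataset"))
  if (is.null(ds$cell_meta$cluster))
    stopf("stage preprocess: dataset has no cluster column")

  pp <- preprocess(ds, config)
  dsp <- pp$ds; moments <- pp$moments

  if (config$mode == "steady_state") {
    fit <- steady_state_fit(dsp, moments)
    vf <- steady_state_velocity(moments$Mu, moments$Ms, fit)
  } else {
    fit <- fit_dynamic(dsp, moments, n_grid = config$em_n_grid,
                       max_iter = config$em_max_iter)
    vf <- dynamic_velocity(moments$Mu, moments$Ms, fit)
  }
  if (ncol(vf$velocity) < 2) stopf("stage velocity: fewer than 2 velocity genes")

  emb <- embed_pca2(dsp, genes = vf$genes)
  lab <- direction_labels(vf, emb, d = config$d)

  rankings <- rank_velocity_genes(vf, dsp$cell_meta$cluster)
  feats <- build_features(dsp, rankings, k = config$k)

  keep <- which(!is.na(lab$class_label))
  X <- feats$matrix[keep, , drop = FALSE]
  y <- lab$class_label[keep]
  if (length(unique(y)) < 2) stopf("stage label: fewer than 2 direction classes present")

  sp <- stratified_split(y, config$split_ratio, seed)
  X_tr <- X[sp$train, , drop = FALSE]; y_tr <- y[sp$train]
  X_te <- X[sp$test, , drop = FALSE]; y_te <- y[sp$test]

  if (config$resample) {
    rs <- smote_tomek(X_tr, y_tr, k_neighbors = config$smote_k, seed = seed)
    X_tr <- rs$matrix; y_tr <- as.integer(rs$labels)
  }

  ests <- default_estimators()
  y_f <- factor(y_tr, levels = sort(unique(c(y_tr, y_te))))
  models <- list()
  metrics <- list()
  preds <- list()

  cf <- cascade_forest(X_tr, y_f, estimators = ests,
                       max_levels = config$max_levels,
                       patience = config$patience, tol = config$tol,
                       seed = derive_seed(seed, 606))
  pc <- as.integer(as.character(predict(cf, X_te)))
  models$cascade <- cf
  preds$cascade <- pc
  metrics$cascade <- metrics_report(y_te, pc, C = config$d)

  if (config$baselines) {
    for (e in seq_along(ests)) {
      kind <- ests[[e]]$kind
      bfit <- ests[[e]]$fit(X_tr, y_f, derive_seed(seed, 707, e))
      pp_b <- ests[[e]]$predict_proba(bfit, X_te)
      pb <- as.integer(colnames(pp_b)[max.col(pp_b, ties.method = "first")])
      models[[kind]] <- bfit
      preds[[kind]] <- pb
      metrics[[kind]] <- metrics_report(y_te, pb, C = config$d)
    }
  }

  structure(list(
    metrics = metrics, models = models,
    labels = lab, features = feats, velocity = vf,
    split = sp, test_truth = y_te, test_pred = preds,
    summary = list(n_cells = nrow(ds$spliced), n_genes_raw = ncol(ds$spliced),
                   n_genes_hvg = ncol(dsp$spliced),
                   n_features = length(feats$gene_ids),
                   n_unlabeled = sum(is.na(lab$class_label)),
                   class_histogram = table(y),
                   mode = config$mode, seed = seed)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("run_report (%s mode, seed %d): %d cells, %d -> %d genes, %d features\n",
              s$mode, s$seed, s$n_cells, s$n_genes_raw, s$n_genes_hvg, s$n_features))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-18s accuracy %.4f  macro_F1 %.4f  kappa %.4f\n",
                nm, m$accuracy, m$macro_f1, m$kappa))
  }
  invisible(x)
}
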
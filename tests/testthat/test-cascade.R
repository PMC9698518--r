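# smaller ensembles keep the suite fast; mechanics are size-independent
fast_estimators <- function() {
  list(estimator_rf(ntree = 60), estimator_extratrees(ntree = 60),
       estimator_boost_deep(nrounds = 25), estimator_boost_shallow(nrounds = 30))
}

test_that("stratified folds cover every class in every fold", {
  y <- factor(rep(0:2, times = c(20, 15, 10)))
  f <- stratified_folds(y, n_folds = 5, seed = 1)
  for (k in 1:5) expect_setequal(unique(y[f == k]), levels(y))
  expect_error(stratified_folds(factor(rep(0:1, c(20, 3))), 5),
               "stratification error")
})

test_that("cascade separates Gaussian blobs and stops by validation", {
  bl <- make_blobs(n = 400, d = 2, sep = 6, seed = 2)
  fit <- cascade_forest(bl$x, bl$y, estimators = fast_estimators(), seed = 3)
  expect_gte(max(fit$validation_history), 0.99)
  expect_equal(fit$validation_history[fit$best_level],
               max(fit$validation_history))
  pred <- predict(fit, bl$x)
  expect_gte(mean(pred == bl$y), 0.99)
})

test_that("level >= 2 input dimension is p + E*d", {
  bl <- make_blobs(n = 160, d = 4, p = 7, sep = 5, seed = 4)
  fit <- cascade_forest(bl$x, bl$y, estimators = fast_estimators(),
                        max_levels = 2, patience = 2, seed = 1)
  expect_equal(fit$levels[[1]]$input_dim, 7)
  expect_equal(fit$levels[[2]]$input_dim, 7 + 4 * 4)
})

test_that("max_levels = 1 degenerates to a single voting ensemble", {
  bl <- make_blobs(n = 120, d = 2, sep = 5, seed = 5)
  fit <- cascade_forest(bl$x, bl$y, estimators = fast_estimators(),
                        max_levels = 1, seed = 1)
  expect_equal(length(fit$levels), 1)
  expect_equal(fit$best_level, 1)
  expect_equal(fit$levels[[1]]$input_dim, ncol(bl$x))
})

test_that("out-of-fold probabilities come from models not trained on the row", {
  bl <- make_blobs(n = 150, d = 3, p = 5, sep = 4, seed = 6)
  est <- fast_estimators()[c(1, 3)]
  seed <- 8
  fit <- cascade_forest(bl$x, bl$y, estimators = est, max_levels = 1,
                        seed = seed)
  # independent reconstruction from the stored fold assignment
  x <- bl$x; colnames(x) <- sprintf("f%d", 1:5)
  for (e in seq_along(est)) {
    oof <- matrix(NA_real_, 150, 3)
    for (f in 1:5) {
      tr <- fit$fold_id != f
      m <- est[[e]]$fit(x[tr, , drop = FALSE], bl$y[tr],
                        velodirect:::derive_seed(seed, 1, e, f))
      oof[!tr, ] <- est[[e]]$predict_proba(m, x[!tr, , drop = FALSE])
    }
    expect_equal(unname(fit$levels[[1]]$oof[[e]]), oof)
  }
})

test_that("probability rows sum to one and permutation acts row-wise", {
  bl <- make_blobs(n = 140, d = 3, p = 4, sep = 5, seed = 7)
  fit <- cascade_forest(bl$x, bl$y, estimators = fast_estimators(), seed = 2)
  pm <- predict(fit, bl$x, type = "prob")
  expect_equal(unname(rowSums(pm)), rep(1, 140), tolerance = 1e-9)
  perm <- sample(140)
  pm2 <- predict(fit, bl$x[perm, ], type = "prob")
  expect_equal(pm2, pm[perm, ])
})

test_that("fit and predict are bit-reproducible under a fixed seed", {
  bl <- make_blobs(n = 130, d = 2, sep = 4, seed = 8)
  f1 <- cascade_forest(bl$x, bl$y, estimators = fast_estimators(), seed = 42)
  f2 <- cascade_forest(bl$x, bl$y, estimators = fast_estimators(), seed = 42)
  expect_identical(f1$validation_history, f2$validation_history)
  expect_identical(predict(f1, bl$x, type = "prob"),
                   predict(f2, bl$x, type = "prob"))
})

test_that("the cascade does not underperform its own first level", {
  bl <- make_blobs(n = 200, d = 3, sep = 2.2, seed = 9)
  fit <- cascade_forest(bl$x, bl$y, estimators = fast_estimators(), seed = 5)
  expect_gte(fit$validation_history[fit$best_level],
             fit$validation_history[1])
})

test_that("models round-trip through the versioned file format", {
  bl <- make_blobs(n = 120, d = 2, sep = 5, seed = 10)
  fit <- cascade_forest(bl$x, bl$y, estimators = fast_estimators(),
                        max_levels = 2, patience = 2, seed = 6)
  probe <- bl$x[sample(120, 30), ]
  before <- predict(fit, probe, type = "prob")
  path <- withr::local_tempfile(fileext = ".cfm")
  cascade_save(fit, path)
  back <- cascade_load(path)
  expect_identical(predict(back, probe, type = "prob"), before)
  expect_identical(back$validation_history, fit$validation_history)
  # tampered header is rejected
  bad <- withr::local_tempfile(fileext = ".cfm")
  saveRDS(list(magic = "something_else", model = 1), bad)
  expect_error(cascade_load(bad), "magic")
})
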
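make_embeddable <- function(n = 60, p = 6, seed = 2) {
  set.seed(seed)
  S <- matrix(rpois(n * p, 30), n, p) + outer(rnorm(n, 0, 6), c(1, 1, 0, 0, 0, 0))
  S <- pmax(S, 0)
  normalize_counts(count_dataset(S, S))
}

test_that("2D PCA embedding is orthonormal, deterministic and linear", {
  ds <- make_embeddable()
  emb <- embed_pca2(ds)
  expect_equal(crossprod(emb$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # deterministic sign convention: bit-identical repeat runs
  emb2 <- embed_pca2(ds)
  expect_identical(emb$coords, emb2$coords)
  expect_identical(emb$loadings, emb2$loadings)
  # coords are the centered data pushed through the loadings
  expect_equal(emb$coords,
               sweep(ds$log_spliced, 2, emb$center) %*% emb$loadings)
  # duplicated cells give duplicated coordinates
  ds2 <- ds
  ds2$log_spliced <- rbind(ds$log_spliced, ds$log_spliced[1, , drop = FALSE])
  ds2$spliced <- rbind(ds$spliced, ds$spliced[1, , drop = FALSE])
  ds2$unspliced <- rbind(ds$unspliced, ds$unspliced[1, , drop = FALSE])
  ds2$cell_meta <- rbind(ds$cell_meta, ds$cell_meta[1, , drop = FALSE])
  emb3 <- embed_pca2(ds2)
  expect_equal(unname(emb3$coords[61, ]), unname(emb3$coords[1, ]))
})

test_that("PCA on intrinsically 2D data recovers it up to rotation", {
  set.seed(3)
  n <- 50
  a <- rnorm(n, 0, 4); b <- rnorm(n, 0, 2)
  X <- outer(a, c(1, 0, 1, 0)) + outer(b, c(0, 1, 0, -1)) + 10
  ds <- count_dataset(pmax(X, 0), pmax(X, 0))
  ds$log_spliced <- X # exact plane, no log distortion
  emb <- embed_pca2(ds)
  # distances between all cell pairs are preserved exactly
  expect_equal(as.vector(dist(emb$coords)), as.vector(dist(X)),
               tolerance = 1e-8)
})

test_that("velocity projection is the exact linear pushforward", {
  ds <- make_embeddable()
  emb <- embed_pca2(ds)
  fit <- steady_state_fit(ds)
  v <- steady_state_velocity(ds$unspliced, ds$spliced, fit)
  disp <- project_velocity(v, emb)
  # zero velocity maps to zero
  v0 <- v; v0$velocity[] <- 0
  expect_equal(unname(project_velocity(v0, emb)), matrix(0, 60, 2),
               ignore_attr = TRUE)
  # finite-difference linearity: (embed(x + eps v) - embed(x))/eps
  eps <- 1e-6
  Xp <- ds$log_spliced + eps * v$velocity
  fd <- (sweep(Xp, 2, emb$center) %*% emb$loadings - emb$coords) / eps
  expect_lt(max(abs(fd - disp)), 1e-6)
  # homogeneity
  v3 <- v; v3$velocity <- 3 * v$velocity
  expect_equal(project_velocity(v3, emb), 3 * disp)
  # gene-set mismatch rejected
  vbad <- v; vbad$genes <- rev(v$genes)
  expect_error(project_velocity(vbad, emb), "gene sets")
})

test_that("angles map to half-open equal segments", {
  expect_equal(angle_to_class(1, 0, 4), 0L)
  expect_equal(angle_to_class(0, 1, 4), 1L) # boundary goes up
  expect_equal(angle_to_class(-1, -1, 8), 5L)
  expect_equal(angle_to_class(1, -1e-12, 4), 3L)
  expect_true(is.na(angle_to_class(0, 0, 4)))
  expect_error(angle_to_class(1, 0, 1), "d must be")
})

test_that("rotating by one segment shifts every class by +1 mod d", {
  set.seed(8)
  for (d in c(3, 4, 8)) {
    th <- runif(300, 0, 2 * pi)
    cls <- angle_to_class(cos(th), sin(th), d)
    rot <- th + 2 * pi / d
    cls_rot <- angle_to_class(cos(rot), sin(rot), d)
    expect_equal(cls_rot, (cls + 1L) %% d)
  }
})

test_that("class histogram of uniform angles is uniform (chi-squared)", {
  set.seed(4)
  th <- runif(1e5, 0, 2 * pi)
  cls <- angle_to_class(cos(th), sin(th), 4)
  pval <- chisq.test(table(cls))$p.value
  expect_gt(pval, 1e-4)
})

test_that("labels recover the benchmark's constructed classes", {
  ds <- make_directional_benchmark(n_cells = 400, d = 4, separation = 8, seed = 2)
  pp <- preprocess(ds, experiment_config())
  fit <- steady_state_fit(pp$ds, pp$moments)
  vf <- steady_state_velocity(pp$moments$Mu, pp$moments$Ms, fit)
  emb <- embed_pca2(pp$ds, genes = vf$genes)
  lab <- direction_labels(vf, emb, d = 4)
  expect_gte(mean(lab$class_label == ds$cell_meta$true_class, na.rm = TRUE), 0.99)
  expect_true(all(lab$class_label %in% 0:3 | is.na(lab$class_label)))
  # invariant: class == floor(d * angle / 2pi) wherever defined
  ok <- !is.na(lab$class_label)
  expect_equal(lab$class_label[ok],
               as.integer(floor(4 * lab$angle[ok] / (2 * pi))))
})
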
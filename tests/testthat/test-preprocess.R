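toy_dataset <- function(spliced, unspliced, cluster = NULL) {
  cm <- data.frame(cell_id = sprintf("c%d", seq_len(nrow(spliced))))
  if (!is.null(cluster)) cm$cluster <- cluster
  count_dataset(spliced, unspliced, cell_meta = cm)
}

test_that("gene filtering applies the shared-count rule to both layers", {
  S <- cbind(c(5, 5), c(10, 0), c(0, 0))
  U <- cbind(c(5, 5), c(0, 0), c(10, 0))
  ds <- toy_dataset(S, U)
  # threshold 0 keeps everything
  expect_equal(ncol(filter_genes(ds, 0)$spliced), 3)
  # gene 2: spliced total 10 but unspliced total 0 -> removed; only the
  # gene passing in both layers survives
  kept <- filter_genes(ds, 1)
  expect_equal(kept$gene_meta$gene_id, "gene_1")
  expect_equal(ncol(kept$unspliced), 1)
  expect_error(filter_genes(ds, 100), "every gene")
})

test_that("the HVG count rule is the printed step function", {
  expect_equal(hvg_count_rule(2930), 2000L)
  expect_equal(hvg_count_rule(3696), 2500L)
  expect_equal(hvg_count_rule(7202), 3000L)
  # boundaries: 3000 and 6000 go to the middle tier
  expect_equal(hvg_count_rule(c(1, 2999, 3000, 6000, 6001)),
               c(2000L, 2000L, 2500L, 2500L, 3000L))
  expect_error(hvg_count_rule(0), "n_cells")
})

test_that("HVG selection ranks by normalized dispersion, deterministically", {
  set.seed(11)
  n <- 80
  low <- matrix(rpois(n * 8, 20), n, 8)
  hi <- 20 + 8 * round(rnorm(n, 0, 1.5)) # same mean, much larger variance
  hi[hi < 0] <- 0
  S <- cbind(low[, 1:4], hi, low[, 5:8])
  ds <- normalize_counts(toy_dataset(S, S))
  sel <- select_hvgs(ds, 1)
  expect_equal(sel$gene_meta$gene_id, "gene_5")
  # n_top >= n_genes keeps everything
  expect_equal(ncol(select_hvgs(ds, 50)$spliced), 9)
  expect_identical(select_hvgs(ds, 3)$gene_meta,
                   select_hvgs(ds, 3)$gene_meta)
})

test_that("normalization equalizes depth per layer and is not repeatable", {
  S <- rbind(c(2, 2), c(4, 4), c(1, 3)) # totals 4, 8, 4 -> median 4
  U <- rbind(c(1, 1), c(1, 1), c(1, 1))
  ds <- normalize_counts(toy_dataset(S, U))
  expect_equal(unname(rowSums(ds$spliced)), c(4, 4, 4))
  # the 2x-depth cell is halved
  expect_equal(unname(ds$spliced[2, ]), c(2, 2))
  # unspliced already equal totals: unchanged
  expect_equal(unname(ds$unspliced), unname(U))
  expect_equal(unname(ds$log_spliced), log1p(unname(ds$spliced)))
  expect_error(normalize_counts(ds), "already normalized")
})

test_that("a zero-count cell gets size factor 1 with a warning", {
  S <- rbind(c(2, 2), c(0, 0), c(2, 2))
  U <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_warning(ds <- normalize_counts(toy_dataset(S, U)), "zero total")
  expect_equal(unname(ds$spliced[2, ]), c(0, 0))
})

test_that("moments with k = 1 are the identity and are convex combinations", {
  ds <- simulate_population(sim_config(n_cells = 40, n_genes = 6), seed = 2)
  ds <- suppressWarnings(normalize_counts(ds)) # sparse toy: a few empty cells
  m1 <- compute_moments(ds, n_pcs = 5, k_neighbors = 1)
  expect_equal(m1$Mu, ds$unspliced, tolerance = 1e-12)
  expect_equal(m1$Ms, ds$spliced, tolerance = 1e-12)
  m <- compute_moments(ds, n_pcs = 5, k_neighbors = 7)
  expect_true(all(m$knn_indices[, 1] == seq_len(40))) # self included
  for (j in seq_len(6)) {
    expect_gte(min(m$Ms[, j]), min(ds$spliced[, j]) - 1e-12)
    expect_lte(max(m$Ms[, j]), max(ds$spliced[, j]) + 1e-12)
  }
  expect_error(compute_moments(ds, k_neighbors = 0), "positive")
  expect_error(compute_moments(ds, k_neighbors = 40), "n_cells")
})

test_that("moments match hand-computed neighbor means on a 4-cell toy", {
  # cells sit at 0, 1, 10, 11 along one expressed gene: with k = 2 the
  # neighbor pairs are {1,2}, {2,1}, {3,4}, {4,3}
  S <- cbind(c(0, 1, 10, 11), c(5, 5, 5, 5))
  U <- cbind(c(0, 2, 20, 22), c(1, 1, 1, 1))
  ds <- count_dataset(S, U)
  ds$normalized <- TRUE
  ds$log_spliced <- log1p(S) # bypass depth scaling to pin coordinates
  m <- compute_moments(ds, n_pcs = 2, k_neighbors = 2)
  expect_equal(unname(m$Ms[, 1]), c(0.5, 0.5, 10.5, 10.5))
  expect_equal(unname(m$Mu[, 1]), c(1, 1, 21, 21))
  # constant gene: first moment constant, second moment its square
  expect_equal(unname(m$Ms[, 2]), rep(5, 4))
  expect_equal(unname(m$Ms2[, 2]), rep(25, 4))
  expect_equal(unname(m$Mu2[, 1]), c(2, 2, 442, 442))
})
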
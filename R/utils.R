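#' @keywords internal
"_PACKAGE"

# Derive a child seed from a base seed and a stream id; stays < 2^31.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (id in ids) s <- (s * 69069 + as.double(id) * 104729 + 12345) %% 2147483647
  as.integer(s)
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Exact k-nearest-neighbour indices (self included) by Euclidean distance.
# Returns an n x k integer matrix; ties broken by row index for determinism.
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  if (k < 1) stopf("k_neighbors must be >= 1, got %d", k)
  if (k > n) stopf("k_neighbors (%d) must not exceed the number of cells (%d)", k, n)
  d <- as.matrix(stats::dist(coords))
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d[i, i] <- -1 # force self first
    out[i, ] <- order(d[i, ], seq_len(n))[seq_len(k)]
  }
  out
}
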
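#' Configuration for the kinetic population simulator
#'
#' Defines the study conditions emulated by [simulate_population()]:
#' cluster-structured latent times along one induction/repression cycle,
#' per-gene kinetic rates, count scaling and a sampling-noise model.
#' The default unspliced target fraction (0.18) sits inside the 10--25%
#' range typical of droplet scRNA-seq protocols.
#'
#' @param n_cells,n_genes,n_clusters dataset dimensions; requires
#'   \code{n_cells >= n_clusters >= 1}.
#' @param noise one of \code{"poisson"} (counts drawn from Poisson with the
#'   kinetic expectation as mean), \code{"lognormal"} (multiplicative
#'   log-normal with sd \code{noise_sd} on the log scale, mean-one), or
#'   \code{"none"} (exact noiseless trajectory values).
#' @param noise_sd log-scale sd for the lognormal model.
#' @param count_scale multiplies the kinetic expectations to reach realistic
#'   count magnitudes (1 keeps trajectory units).
#' @param target_unspliced_frac dataset-wide unspliced fraction the
#'   unspliced layer is rescaled to; \code{NULL} disables rescaling so the
#'   layers equal the raw trajectory values.
#' @param cycle_length duration of one full induction/repression cycle;
#'   cluster time windows partition \code{[0, cycle_length]}.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_cells = 500, n_genes = 100, n_clusters = 3,
                       noise = c("poisson", "lognormal", "none"),
                       noise_sd = 0.1, count_scale = 10,
                       target_unspliced_frac = 0.18, cycle_length = 12) {
  noise <- tryCatch(match.arg(noise),
                    error = function(e) stopf("invalid noise spec: must be poisson, lognormal or none"))
  if (n_clusters < 1 || n_cells < n_clusters)
    stopf("need n_cells >= n_clusters >= 1 (got %d cells, %d clusters)", n_cells, n_clusters)
  if (!is.null(target_unspliced_frac) &&
      (target_unspliced_frac <= 0 || target_unspliced_frac >= 1))
    stopf("target_unspliced_frac must be in (0, 1) or NULL")
  if (noise == "lognormal" && (!is.finite(noise_sd) || noise_sd < 0))
    stopf("invalid noise spec: noise_sd must be a finite non-negative number")
  structure(list(n_cells = n_cells, n_genes = n_genes, n_clusters = n_clusters,
                 noise = noise, noise_sd = noise_sd, count_scale = count_scale,
                 target_unspliced_frac = target_unspliced_frac,
                 cycle_length = cycle_length),
            class = "sim_config")
}

#' Simulate a cluster-structured spliced/unspliced dataset
#'
#' Draws per-gene kinetic parameters, assigns each cluster a disjoint
#' latent-time window along one induction/repression cycle, evaluates the
#' exact closed-form trajectories and applies the configured sampling
#' noise. All randomness flows from \code{seed}; the same seed gives a
#' bit-identical dataset.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a [count_dataset()] whose \code{cell_meta} carries
#'   \code{cluster} and \code{latent_time} and whose \code{gene_meta}
#'   carries the true \code{alpha}, \code{beta}, \code{gamma},
#'   \code{t_switch}.
#' @export
simulate_population <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cells; p <- config$n_genes; K <- config$n_clusters
  Tc <- config$cycle_length
  with_seed(derive_seed(seed, 101), {
    alpha <- stats::runif(p, 2, 8)
    beta <- stats::runif(p, 0.8, 1.6)
    gamma <- stats::runif(p, 0.3, 0.9)
    t_switch <- stats::runif(p, 0.45, 0.65) * Tc
    cluster <- sort(rep_len(seq_len(K), n))
    lo <- (cluster - 1) * Tc / K
    latent_time <- stats::runif(n, lo, lo + Tc / K)

    U <- matrix(0, n, p); S <- matrix(0, n, p)
    ord <- order(latent_time)
    for (j in seq_len(p)) {
      pj <- kinetic_params(alpha[j], beta[j], gamma[j], t_switch[j])
      tr <- solve_kinetics(pj, latent_time[ord])
      U[ord, j] <- tr$u; S[ord, j] <- tr$s
    }
    U <- U * config$count_scale; S <- S * config$count_scale
    if (!is.null(config$target_unspliced_frac)) {
      f <- config$target_unspliced_frac
      tot_u <- sum(U); tot_s <- sum(S)
      if (tot_u > 0) U <- U * (f / (1 - f)) * (tot_s / tot_u)
    }
    if (config$noise == "poisson") {
      U <- matrix(stats::rpois(n * p, lambda = U), n, p)
      S <- matrix(stats::rpois(n * p, lambda = S), n, p)
    } else if (config$noise == "lognormal") {
      sdl <- config$noise_sd
      U <- U * matrix(stats::rlnorm(n * p, -sdl^2 / 2, sdl), n, p)
      S <- S * matrix(stats::rlnorm(n * p, -sdl^2 / 2, sdl), n, p)
    }
    count_dataset(
      S, U,
      cell_meta = data.frame(cell_id = sprintf("cell_%d", seq_len(n)),
                             cluster = sprintf("c%d", cluster),
                             latent_time = latent_time),
      gene_meta = data.frame(gene_id = sprintf("gene_%d", seq_len(p)),
                             alpha = alpha, beta = beta, gamma = gamma,
                             t_switch = t_switch))
  })
}

#' Simulate a benchmark with known velocity direction classes
#'
#' Constructs \code{d} cell populations whose true velocity vectors, pushed
#' through the package's own 2D principal-component projection, point into
#' the \code{d} equal angular segments of the plane. Expression lives on a
#' two-dimensional latent plane spanned by two disjoint gene blocks, so the
#' top two principal components recover the plane and the projected
#' velocity angle equals the constructed one up to small estimation error.
#' The per-cell ground truth is stored in \code{cell_meta$true_class}.
#'
#' The "true class" here is a simulator construct: real datasets carry no
#' observed direction label, so end-to-end evaluations against
#' \code{true_class} measure internal consistency of the pipeline, not
#' agreement with any experimentally observed direction.
#'
#' @param n_cells number of cells (split near-equally across classes).
#' @param d number of angular classes (>= 2).
#' @param separation positive scalar; the within-class angular spread is
#'   \code{(pi/d)/separation}, so larger values give cleaner classes.
#' @param seed integer seed.
#' @param n_block_genes genes per latent-plane block (two blocks).
#' @param n_background_genes genes carrying no directional signal.
#' @param noise_sd additive expression noise sd (counts scale).
#' @return a [count_dataset()] with \code{true_class} in \code{cell_meta}
#'   (integer in \code{0..d-1}) and the per-gene steady-state ratio
#'   \code{gamma} in \code{gene_meta}.
#' @export
make_directional_benchmark <- function(n_cells = 1000, d = 4, separation = 8,
                                       seed = 1, n_block_genes = 20,
                                       n_background_genes = 20, noise_sd = 0.5) {
  if (d < 2) stopf("d must be >= 2, got %d", d)
  if (separation <= 0) stopf("separation must be > 0, got %s", format(separation))
  if (n_block_genes < 8) stopf("need >= 8 genes per latent-plane block")
  with_seed(derive_seed(seed, 202), {
    nA <- n_block_genes; nB <- n_block_genes; nC <- n_background_genes
    p <- nA + nB + nC
    # zero-sum unit-norm block loadings: depth normalization then leaves
    # per-cell totals independent of the latent plane coordinates; the few
    # large positive entries pin the PCA sign convention deterministically
    block_w <- function(nb) {
      n_hi <- max(2L, nb %/% 5L)
      w <- c(rep(1, n_hi), rep(-n_hi / (nb - n_hi), nb - n_hi))
      w / sqrt(sum(w^2))
    }
    w1 <- c(block_w(nA), rep(0, nB + nC))
    w2 <- c(rep(0, nA), block_w(nB), rep(0, nC))

    cls <- rep_len(seq_len(d) - 1L, n_cells)
    centers <- (cls + 0.5) * 2 * pi / d
    spread <- (pi / d) / separation
    theta <- (centers + stats::runif(n_cells, -spread, spread)) %% (2 * pi)

    # positions: class blobs on a circle in the latent plane, slightly
    # anisotropic so PC1 aligns with the first block axis deterministically
    r_pos <- 12
    a <- 1.25 * (r_pos * cos(centers) + stats::rnorm(n_cells, 0, 1.5))
    b <- r_pos * sin(centers) + stats::rnorm(n_cells, 0, 1.5)

    base <- rep(30, p)
    S <- matrix(base, n_cells, p, byrow = TRUE) +
      outer(a, w1) + outer(b, w2) +
      matrix(stats::rnorm(n_cells * p, 0, noise_sd), n_cells, p)
    S <- pmax(S, 0)

    gamma <- stats::runif(p, 0.15, 0.30)
    mag <- 8
    V <- outer(cos(theta), w1) * mag + outer(sin(theta), w2) * mag
    U <- sweep(S, 2, gamma, "*") + V
    U <- pmax(U, 0)

    count_dataset(
      S, U,
      cell_meta = data.frame(cell_id = sprintf("cell_%d", seq_len(n_cells)),
                             cluster = sprintf("c%d", cls),
                             true_class = cls,
                             true_angle = theta),
      gene_meta = data.frame(gene_id = sprintf("gene_%d", seq_len(p)),
                             gamma = gamma))
  })
}
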
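#' Steady-state ratio of a single gene
#'
#' Least-squares slope through the origin of unspliced on spliced
#' abundance, \eqn{\tilde\gamma = u^T s / \lVert s\rVert^2}: the estimate of
#' \eqn{\gamma/\beta} under the steady-state assumption.
#'
#' @param u,s numeric vectors over cells (typically moment-smoothed).
#' @return the scalar ratio.
#' @examples
#' fit_gamma(c(1, 0), c(1, 1)) # 0.5
#' @export
fit_gamma <- function(u, s) {
  if (length(u) != length(s)) stopf("u and s must have equal length")
  ss <- sum(s^2)
  if (ss == 0) stopf("all-zero spliced vector: gene has no steady-state fit")
  sum(u * s) / ss
}

#' Fit the steady-state model to every gene
#'
#' Computes the per-gene steady-state ratio \eqn{\tilde\gamma} on
#' moment-smoothed layers by default (falling back to the normalized
#' layers when no moments are supplied), with an R-squared diagnostic of
#' the through-origin regression. Genes with an all-zero spliced signal
#' are flagged invalid and excluded from velocity genes.
#'
#' @param ds a normalized [count_dataset()].
#' @param moments optional [compute_moments()] result.
#' @param quantile_restrict optional fraction in (0, 0.5]; when set, the
#'   regression uses only cells in the extreme upper and lower quantiles
#'   of \code{s} (off by default: the plain projection formula).
#' @return object of class \code{"steady_state_fit"} with
#'   \code{gamma_tilde}, \code{r2} and \code{valid} per gene.
#' @export
steady_state_fit <- function(ds, moments = NULL, quantile_restrict = NULL) {
  stopifnot(inherits(ds, "count_dataset"))
  if (is.null(moments)) {
    U <- ds$unspliced; S <- ds$spliced
  } else {
    U <- moments$Mu; S <- moments$Ms
  }
  p <- ncol(S)
  gt <- rep(NA_real_, p); r2 <- rep(NA_real_, p); valid <- rep(FALSE, p)
  for (j in seq_len(p)) {
    s <- S[, j]; u <- U[, j]
    if (!is.null(quantile_restrict)) {
      q <- stats::quantile(s, c(quantile_restrict, 1 - quantile_restrict))
      sel <- s <= q[1] | s >= q[2]
      s <- s[sel]; u <- u[sel]
    }
    if (sum(s^2) == 0) next
    g <- sum(u * s) / sum(s^2)
    res <- u - g * s
    tot <- sum((u - mean(u))^2)
    gt[j] <- g
    r2[j] <- if (tot > 0) 1 - sum(res^2) / tot else 1
    valid[j] <- TRUE
  }
  structure(list(gamma_tilde = gt, r2 = r2, valid = valid,
                 gene_id = ds$gene_meta$gene_id),
            class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("steady_state_fit: %d genes (%d valid)\n",
              length(x$gamma_tilde), sum(x$valid)))
  cat(sprintf("  gamma_tilde median %.4g, IQR [%.4g, %.4g]\n",
              stats::median(x$gamma_tilde, na.rm = TRUE),
              stats::quantile(x$gamma_tilde, 0.25, na.rm = TRUE),
              stats::quantile(x$gamma_tilde, 0.75, na.rm = TRUE)))
  invisible(x)
}

#' Steady-state velocity field
#'
#' Per-cell, per-gene velocity \eqn{v_i = u_i - \tilde\gamma s_i}:
#' the deviation of unspliced abundance from its equilibrium expectation.
#' Invalid genes (no steady-state fit) are dropped from the field.
#'
#' @param u,s cells x genes matrices (typically moment-smoothed).
#' @param fit a [steady_state_fit()].
#' @return object of class \code{"velocity_field"} with \code{velocity}
#'   (cells x valid genes), \code{genes} and \code{mode}.
#' @export
steady_state_velocity <- function(u, s, fit) {
  stopifnot(inherits(fit, "steady_state_fit"))
  if (!identical(dim(u), dim(s)) || ncol(s) != length(fit$gamma_tilde))
    stopf("shape mismatch between layers and fit")
  keep <- which(fit$valid)
  v <- u[, keep, drop = FALSE] -
    sweep(s[, keep, drop = FALSE], 2, fit$gamma_tilde[keep], "*")
  structure(list(velocity = v, genes = fit$gene_id[keep], mode = "steady_state"),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field (%s): %d cells x %d genes\n",
              x$mode, nrow(x$velocity), ncol(x$velocity)))
  invisible(x)
}

# Closed-form (u, s) trajectory at arbitrary (unsorted) times for
# parameters theta = (alpha, beta, gamma, t_switch).
.trajectory <- function(times, alpha, beta, gamma, t_switch) {
  u <- numeric(length(times)); s <- numeric(length(times))
  ind <- times <= t_switch
  if (any(ind)) {
    ph <- .kinetics_phase(times[ind], alpha, beta, gamma, 0, 0)
    u[ind] <- ph$u; s[ind] <- ph$s
  }
  if (any(!ind)) {
    sw <- .kinetics_phase(t_switch, alpha, beta, gamma, 0, 0)
    ph <- .kinetics_phase(times[!ind] - t_switch, 0, beta, gamma, sw$u, sw$s)
    u[!ind] <- ph$u; s[!ind] <- ph$s
  }
  list(u = u, s = s)
}

#' Likelihood of the dynamic model
#'
#' Evaluates the per-gene likelihood
#' \deqn{\mathcal{L}(\theta) = \frac{1}{\sqrt{2\pi}\,\sigma}
#'   \exp\Big(-\frac{1}{2n}\sum_i \frac{\lVert x_i^{obs} - x_{t_i}(\theta)\rVert^2}{\sigma^2}\Big)}
#' where \eqn{x_i = (u_i, s_i)} and \eqn{x_{t_i}(\theta)} is the
#' closed-form trajectory at the cell's assigned time.
#'
#' @param theta list with \code{alpha}, \code{beta}, \code{gamma},
#'   \code{t_switch}.
#' @param sigma residual scale (> 0).
#' @param u,s observed vectors over cells.
#' @param times assigned latent times (same length).
#' @return the scalar likelihood value.
#' @export
dynamic_likelihood <- function(theta, sigma, u, s, times) {
  if (sigma <= 0) stopf("sigma must be > 0")
  n <- length(u)
  if (n < 1 || length(s) != n || length(times) != n)
    stopf("u, s and times must be non-empty and of equal length")
  tr <- .trajectory(times, theta$alpha, theta$beta, theta$gamma, theta$t_switch)
  ss <- sum((u - tr$u)^2 + (s - tr$s)^2)
  exp(.dynamic_loglik(ss, sigma, n))
}

.dynamic_loglik <- function(ss, sigma, n) {
  -0.5 * log(2 * pi) - log(sigma) - ss / (2 * n * sigma^2)
}

# E-step time grid: one induction phase [0, t_switch] and one repression
# phase extending far enough for the trajectory to decay.
.time_grid <- function(beta, gamma, t_switch, n_grid) {
  half <- max(2L, n_grid %/% 2L)
  t_rep <- 6 / min(beta, gamma)
  c(seq(0, t_switch, length.out = half),
    t_switch + seq(0, t_rep, length.out = half)[-1])
}

#' Fit the dynamic model to one gene by EM
#'
#' Hard-assignment EM against the likelihood of [dynamic_likelihood()].
#' The E-step assigns each cell the latent time, on a dense grid over one
#' induction/repression cycle, minimizing squared distance to the
#' closed-form trajectory; the M-step refines \eqn{(\beta, \gamma,
#' t_{switch})} by bounded least squares (Nelder-Mead on log-rates,
#' accepted only if the residual sum decreases) and sets \eqn{\sigma^2}
#' to the mean squared residual. The transcription rate is fixed at
#' \eqn{\alpha = 1} during fitting, which pins the gene's time scale:
#' fitted rates estimate \eqn{\beta/\alpha} and \eqn{\gamma/\alpha}, and
#' the fitted switch time estimates \eqn{\alpha\, t_{switch}}.
#'
#' @param u,s observed unspliced/spliced vectors over cells (typically
#'   moment-smoothed).
#' @param n_grid E-step time-grid size (default 240).
#' @param max_iter,tol EM stopping controls (log-likelihood change).
#' @param gamma_init optional starting value for \eqn{\gamma/\beta}
#'   (defaults to the steady-state ratio of the gene).
#' @return object of class \code{"dynamic_gene_fit"} with \code{beta},
#'   \code{gamma}, \code{t_switch}, \code{sigma}, \code{latent_time},
#'   \code{loglik_trace}, \code{converged}.
#' @export
fit_dynamic_em <- function(u, s, n_grid = 240, max_iter = 50, tol = 1e-8,
                           gamma_init = NULL) {
  n <- length(u)
  if (length(s) != n) stopf("u and s must have equal length")
  if (sum(u != 0 | s != 0) < 10)
    stopf("dynamic fit needs >= 10 cells with nonzero signal")

  u_scale <- max(stats::quantile(u, 0.98), .Machine$double.eps)
  beta <- 1 / u_scale
  gt <- if (is.null(gamma_init)) {
    if (sum(s^2) > 0) fit_gamma(u, s) else 1
  } else gamma_init
  gamma <- max(gt, 1e-3) * beta

  # E-step: argmin over the dense grid, augmented with the previous
  # assignment so the residual sum can never increase across iterations
  e_step <- function(beta, gamma, t_switch, extra = NULL) {
    grid <- c(.time_grid(beta, gamma, t_switch, n_grid), extra)
    tr <- .trajectory(grid, 1, beta, gamma, t_switch)
    d2 <- outer(u, tr$u, "-")^2 + outer(s, tr$s, "-")^2
    idx <- max.col(-d2, ties.method = "first")
    list(times = grid[idx], ss = sum(d2[cbind(seq_len(n), idx)]))
  }
  obj <- function(par, times) {
    tr <- .trajectory(times, 1, exp(par[1]), exp(par[2]), exp(par[3]))
    sum((u - tr$u)^2 + (s - tr$s)^2)
  }

  run_em <- function(beta, gamma, t_switch) {
    trace <- numeric(0)
    times <- NULL; ss <- Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      es <- e_step(beta, gamma, t_switch, extra = times)
      times <- es$times; ss <- es$ss
      # M-step: accept the refined parameters only when they reduce the
      # residual sum, preserving likelihood monotonicity
      opt <- stats::optim(c(log(beta), log(gamma), log(t_switch)), obj,
                          times = times, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-12))
      if (opt$value < ss) {
        beta <- exp(opt$par[1]); gamma <- exp(opt$par[2])
        t_switch <- exp(opt$par[3])
        es <- e_step(beta, gamma, t_switch, extra = times)
        times <- es$times; ss <- es$ss
      }
      sigma <- sqrt(max(ss, 1e-300) / n)
      ll <- .dynamic_loglik(ss, sigma, n)
      trace <- c(trace, ll)
      if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
        converged <- TRUE
        break
      }
    }
    list(beta = beta, gamma = gamma, t_switch = t_switch, ss = ss,
         times = times, trace = trace, converged = converged)
  }

  # Initialization: the unspliced arc rises until the switch and falls
  # after, so max(u) estimates the switch point u(t_s) = (1-e^{-b t_s})/b.
  # Parametrize candidate starts by the saturation level q = b*u_peak in
  # (0,1) -- from early-interrupted induction (small q) to the fully
  # saturated regime (q near 1) -- which fixes (beta, t_switch) jointly;
  # cross with a gamma/beta grid, rank by E-step residual, then run EM
  # from the best few distinct starts (the basins are separated and a
  # single start cannot escape, e.g. an all-induction reading of the
  # cycle).
  u_peak <- max(u)
  cand <- expand.grid(q = c(0.3, 0.5, 0.7, 0.85, 0.95, 0.995),
                      gr = c(0.3, 0.6, 1, 1.7, 3) * max(gt, 1e-3))
  cand$beta <- cand$q / u_peak
  cand$ts <- -log1p(-cand$q) / cand$beta
  ss_cand <- mapply(function(b0, g0, ts) e_step(b0, g0 * b0, ts)$ss,
                    cand$beta, cand$gr, cand$ts)
  starts <- order(ss_cand)[seq_len(min(3L, length(ss_cand)))]
  best <- NULL
  for (k in starts) {
    fit_k <- run_em(cand$beta[k], cand$gr[k] * cand$beta[k], cand$ts[k])
    if (is.null(best) || fit_k$ss < best$ss) best <- fit_k
  }

  # final polish on the profile objective (E-step folded into every
  # evaluation): follows the narrow valley that alternating EM steps
  # cannot descend; accepted only on improvement
  prof <- function(par) e_step(exp(par[1]), exp(par[2]), exp(par[3]))$ss
  opt <- stats::optim(log(c(best$beta, best$gamma, best$t_switch)), prof,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-12))
  if (opt$value < best$ss) {
    best$beta <- exp(opt$par[1]); best$gamma <- exp(opt$par[2])
    best$t_switch <- exp(opt$par[3])
    es <- e_step(best$beta, best$gamma, best$t_switch)
    best$times <- es$times; best$ss <- es$ss
    best$trace <- c(best$trace,
                    .dynamic_loglik(es$ss, sqrt(max(es$ss, 1e-300) / n), n))
  }

  structure(list(alpha = 1, beta = best$beta, gamma = best$gamma,
                 t_switch = best$t_switch,
                 sigma = sqrt(max(best$ss, 1e-300) / n),
                 latent_time = best$times,
                 loglik_trace = best$trace, converged = best$converged),
            class = "dynamic_gene_fit")
}

#' Fit the dynamic model to every gene
#'
#' Runs [fit_dynamic_em()] per gene on moment-smoothed layers (or the
#' normalized layers when no moments are given), seeding each gene's
#' \eqn{\gamma/\beta} from the steady-state fit. Genes that fail the
#' fit's preconditions are flagged invalid; non-converged genes are
#' flagged but kept.
#'
#' @param ds a normalized [count_dataset()].
#' @param moments optional [compute_moments()] result.
#' @param ... passed to [fit_dynamic_em()].
#' @return object of class \code{"dynamic_fit"}: data.frame \code{theta}
#'   (beta, gamma, t_switch, sigma, loglik, converged, valid) plus
#'   \code{latent_time} (cells x genes) and per-gene \code{traces}.
#' @export
fit_dynamic <- function(ds, moments = NULL, ...) {
  stopifnot(inherits(ds, "count_dataset"))
  ssf <- steady_state_fit(ds, moments)
  if (is.null(moments)) {
    U <- ds$unspliced; S <- ds$spliced
  } else {
    U <- moments$Mu; S <- moments$Ms
  }
  p <- ncol(S); n <- nrow(S)
  theta <- data.frame(gene_id = ds$gene_meta$gene_id,
                      beta = NA_real_, gamma = NA_real_, t_switch = NA_real_,
                      sigma = NA_real_, loglik = NA_real_,
                      converged = FALSE, valid = FALSE)
  latent <- matrix(NA_real_, n, p)
  traces <- vector("list", p)
  for (j in seq_len(p)) {
    fit <- tryCatch(
      fit_dynamic_em(U[, j], S[, j],
                     gamma_init = if (ssf$valid[j]) ssf$gamma_tilde[j] else NULL,
                     ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    theta$beta[j] <- fit$beta; theta$gamma[j] <- fit$gamma
    theta$t_switch[j] <- fit$t_switch; theta$sigma[j] <- fit$sigma
    theta$loglik[j] <- fit$loglik_trace[length(fit$loglik_trace)]
    theta$converged[j] <- fit$converged
    theta$valid[j] <- TRUE
    latent[, j] <- fit$latent_time
    traces[[j]] <- fit$loglik_trace
  }
  structure(list(theta = theta, latent_time = latent, traces = traces),
            class = "dynamic_fit")
}

#' @export
print.dynamic_fit <- function(x, ...) {
  cat(sprintf("dynamic_fit: %d genes (%d valid, %d converged)\n",
              nrow(x$theta), sum(x$theta$valid), sum(x$theta$converged)))
  invisible(x)
}

#' Dynamic-model velocity field
#'
#' Per-cell, per-gene velocity \eqn{v_i = \beta u_i - \gamma s_i}: the
#' spliced-mRNA time derivative of the kinetic model evaluated at the
#' observation, using each gene's fitted rates. Because rates are fitted
#' at \eqn{\alpha = 1}, each gene's velocity carries its own time unit;
#' signs and within-gene comparisons are meaningful, cross-gene
#' magnitudes only up to the per-gene scale.
#'
#' @param u,s cells x genes matrices matching the fit.
#' @param fit a [fit_dynamic()] result.
#' @return object of class \code{"velocity_field"} over the valid genes.
#' @export
dynamic_velocity <- function(u, s, fit) {
  stopifnot(inherits(fit, "dynamic_fit"))
  if (!identical(dim(u), dim(s)) || ncol(s) != nrow(fit$theta))
    stopf("shape mismatch between layers and fit")
  keep <- which(fit$theta$valid)
  v <- sweep(u[, keep, drop = FALSE], 2, fit$theta$beta[keep], "*") -
    sweep(s[, keep, drop = FALSE], 2, fit$theta$gamma[keep], "*")
  structure(list(velocity = v, genes = fit$theta$gene_id[keep], mode = "dynamic"),
            class = "velocity_field")
}
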
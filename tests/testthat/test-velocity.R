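test_that("the steady-state ratio is the through-origin slope", {
  s <- c(1, 2, 3)
  expect_equal(fit_gamma(2 * s, s), 2)
  expect_equal(fit_gamma(c(1, 0), c(1, 1)), 0.5)
  expect_equal(fit_gamma(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(fit_gamma(c(1, 0), c(0, 0)), "all-zero")
  expect_error(fit_gamma(1:3, 1:2), "equal length")
})

test_that("genes with no spliced signal are flagged invalid, not fitted", {
  S <- cbind(c(1, 2, 3), c(0, 0, 0))
  U <- cbind(c(2, 4, 6), c(1, 1, 1))
  fit <- steady_state_fit(count_dataset(S, U))
  expect_true(fit$valid[1])
  expect_false(fit$valid[2])
  expect_equal(fit$gamma_tilde[1], 2)
  v <- steady_state_velocity(U, S, fit)
  expect_equal(ncol(v$velocity), 1)
})

test_that("steady-state velocity is the deviation from equilibrium", {
  S <- cbind(c(1, 1), c(2, 4))
  gt <- c(0.5, 0.25)
  U <- sweep(S, 2, gt, "*")
  fit <- steady_state_fit(count_dataset(S, U))
  v <- steady_state_velocity(U, S, fit)
  expect_equal(unname(v$velocity), matrix(0, 2, 2))

  # hand example: u = (1, 0), s = (1, 1), gamma_tilde = 0.5 -> v = (0.5, -0.5)
  S1 <- matrix(c(1, 1), 2, 1); U1 <- matrix(c(1, 0), 2, 1)
  f1 <- steady_state_fit(count_dataset(S1, U1))
  v1 <- steady_state_velocity(U1, S1, f1)
  expect_equal(unname(v1$velocity[, 1]), c(0.5, -0.5))

  # homogeneity at fixed gamma_tilde
  v2 <- steady_state_velocity(2 * U1, 2 * S1, f1)
  expect_equal(v2$velocity, 2 * v1$velocity)
  expect_error(steady_state_velocity(U1[1, , drop = FALSE], S1, f1), "mismatch")
})

test_that("gamma recovery on equilibrium data with 10% noise is accurate", {
  panel <- make_equilibrium_panel(n_cells = 150, n_genes = 60,
                                  noise_sd = 0.1, seed = 3)
  gt <- vapply(seq_len(60), function(j) fit_gamma(panel$U[, j], panel$S[, j]),
               numeric(1))
  rel <- abs(gt / panel$gamma_over_beta - 1)
  expect_lt(median(rel), 0.05)
  # velocity centered at zero at the steady state
  fit <- steady_state_fit(count_dataset(panel$S, panel$U))
  v <- steady_state_velocity(panel$U, panel$S, fit)
  expect_lt(abs(mean(v$velocity)), 0.05 * mean(panel$U))
})

test_that("the dynamic likelihood matches its printed closed form", {
  th <- list(alpha = 2, beta = 1, gamma = 0.5, t_switch = Inf)
  tt <- c(0.5, 1.5, 3)
  tr <- solve_kinetics(kinetic_params(2, 1, 0.5), tt)
  # zero residuals: exponent vanishes, prefactor only
  expect_equal(dynamic_likelihood(th, 1, tr$u, tr$s, tt), 1 / sqrt(2 * pi))
  expect_equal(dynamic_likelihood(th, 2, tr$u, tr$s, tt), 1 / (2 * sqrt(2 * pi)))
  # two cells with residual norms 1 and 1, sigma = 1, n = 2:
  # (1/sqrt(2*pi)) * exp(-(1/(2*2)) * 2) = (1/sqrt(2*pi)) * exp(-0.5)
  tt2 <- c(1, 2)
  tr2 <- solve_kinetics(kinetic_params(2, 1, 0.5), tt2)
  expect_equal(dynamic_likelihood(th, 1, tr2$u + 1, tr2$s, tt2),
               exp(-0.5) / sqrt(2 * pi))
  expect_error(dynamic_likelihood(th, 0, tr$u, tr$s, tt), "sigma")
})

test_that("EM recovers time-normalized kinetics from noiseless data", {
  set.seed(21)
  rel <- matrix(NA_real_, 6, 3)
  for (i in 1:6) {
    cs <- draw_recovery_case()
    tr <- solve_kinetics(kinetic_params(cs$alpha, cs$beta, cs$gamma, cs$t_switch),
                         cs$times)
    f <- fit_dynamic_em(tr$u, tr$s)
    rel[i, ] <- abs(c(f$beta / (cs$beta / cs$alpha),
                      f$gamma / (cs$gamma / cs$alpha),
                      f$t_switch / (cs$alpha * cs$t_switch)) - 1)
    expect_true(all(diff(f$loglik_trace) > -1e-6))
  }
  expect_lt(median(rel[, 1]), 0.10)
  expect_lt(median(rel[, 2]), 0.10)
  expect_lt(median(rel[, 3]), 0.10)
})

test_that("EM is a fixed point on data lying exactly on a fitted trajectory", {
  set.seed(5)
  cs <- draw_recovery_case()
  tr <- solve_kinetics(kinetic_params(cs$alpha, cs$beta, cs$gamma, cs$t_switch),
                       cs$times)
  f <- fit_dynamic_em(tr$u, tr$s)
  # regenerate data exactly on the fitted trajectory at the assigned times
  tr2 <- solve_kinetics(kinetic_params(1, f$beta, f$gamma, f$t_switch),
                        sort(f$latent_time))
  f2 <- fit_dynamic_em(tr2$u, tr2$s)
  last <- length(f2$loglik_trace)
  expect_true(f2$converged)
  # residuals essentially zero: sigma collapses toward the grid resolution
  expect_lt(f2$sigma, 1e-3)
})

test_that("EM rejects genes with too little signal", {
  expect_error(fit_dynamic_em(rep(0, 20), rep(0, 20)), "nonzero signal")
  expect_error(fit_dynamic_em(c(1, 2), c(1, 2)), "nonzero signal")
})

test_that("dynamic velocity has the kinetic sign structure", {
  # v = beta*u - gamma*s with beta=1, gamma=0.5 at u=s=2 gives 1
  th <- data.frame(gene_id = "g1", beta = 1, gamma = 0.5, t_switch = 5,
                   sigma = 0.1, loglik = 0, converged = TRUE, valid = TRUE)
  fit <- structure(list(theta = th), class = "dynamic_fit")
  v <- dynamic_velocity(matrix(2), matrix(2), fit)
  expect_equal(unname(v$velocity[1, 1]), 1)
  # equilibrium u = (gamma/beta) s gives zero
  v0 <- dynamic_velocity(matrix(0.5 * 3), matrix(3), fit)
  expect_equal(unname(v0$velocity[1, 1]), 0)

  # induction-phase cells have positive ds/dt, repression negative
  p <- kinetic_params(2, 1, 0.4, t_switch = 3)
  tt <- c(seq(0.2, 2.8, length.out = 10), seq(3.5, 12, length.out = 10))
  tr <- solve_kinetics(p, tt)
  vtrue <- 1 * tr$u - 0.4 * tr$s
  expect_true(all(vtrue[1:10] > 0))
  expect_true(all(vtrue[15:20] < 0))
})

test_that("whole-panel dynamic fit flags invalid genes and keeps traces", {
  set.seed(13)
  cs <- draw_recovery_case()
  tr <- solve_kinetics(kinetic_params(cs$alpha, cs$beta, cs$gamma, cs$t_switch),
                       cs$times)
  S <- cbind(tr$s, 0)
  U <- cbind(tr$u, 0)
  ds <- count_dataset(S, U)
  fit <- fit_dynamic(ds, max_iter = 15)
  expect_true(fit$theta$valid[1])
  expect_false(fit$theta$valid[2])
  expect_true(all(diff(fit$traces[[1]]) > -1e-6))
  v <- dynamic_velocity(U, S, fit)
  expect_equal(ncol(v$velocity), 1)
})
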
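# Shared fixtures, all generated in code.

# Two well-separated Gaussian blobs (binary) or d blobs on a circle.
make_blobs <- function(n = 400, d = 2, p = 6, sep = 6, seed = 1) {
  set.seed(seed)
  cls <- rep_len(seq_len(d) - 1L, n)
  ang <- 2 * pi * cls / d
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + sep * cos(ang)
  x[, 2] <- x[, 2] + sep * sin(ang)
  list(x = x, y = factor(cls))
}

# Hand-rolled RK4 integration of the kinetic ODEs (independent oracle).
rk4_kinetics <- function(alpha, beta, gamma, t_switch, t_end, h = 1e-4) {
  y <- c(0, 0)
  t <- 0
  f <- function(t, y) {
    a <- if (t <= t_switch) alpha else 0
    c(a - beta * y[1], beta * y[1] - gamma * y[2])
  }
  n_steps <- round(t_end / h)
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y); k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2); k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# Tight-tolerance numeric ODE solution, integrated piecewise around the
# switch so the discontinuity in alpha is handled exactly.
ode_kinetics <- function(alpha, beta, gamma, t_switch, times) {
  f_on <- function(t, y, p) list(c(alpha - beta * y[1], beta * y[1] - gamma * y[2]))
  f_off <- function(t, y, p) list(c(-beta * y[1], beta * y[1] - gamma * y[2]))
  t1 <- times[times <= t_switch]; t2 <- times[times > t_switch]
  out <- matrix(NA_real_, length(times), 2)
  y_sw <- c(0, 0)
  if (length(t1) > 0 || length(t2) > 0) {
    tt <- unique(c(0, t1, t_switch))
    o1 <- deSolve::ode(c(0, 0), tt, f_on, NULL, rtol = 1e-12, atol = 1e-12)
    if (length(t1) > 0)
      out[seq_along(t1), ] <- o1[match(t1, o1[, 1]), 2:3, drop = FALSE]
    y_sw <- as.numeric(o1[nrow(o1), 2:3])
  }
  if (length(t2) > 0) {
    o2 <- deSolve::ode(y_sw, c(t_switch, t2), f_off, NULL,
                       rtol = 1e-12, atol = 1e-12)
    out[length(t1) + seq_along(t2), ] <- o2[match(t2, o2[, 1]), 2:3, drop = FALSE]
  }
  out
}

# Simulated steady-state (equilibrium) gene panel with multiplicative
# log-normal noise; returns layers plus the true gamma/beta ratios.
make_equilibrium_panel <- function(n_cells = 200, n_genes = 100,
                                   noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  alpha <- runif(n_genes, 2, 8)
  beta <- runif(n_genes, 0.8, 1.6)
  gamma <- runif(n_genes, 0.3, 0.9)
  u0 <- alpha / beta; s0 <- alpha / gamma
  U <- outer(rep(1, n_cells), u0) * matrix(rlnorm(n_cells * n_genes, 0, noise_sd),
                                           n_cells, n_genes)
  S <- outer(rep(1, n_cells), s0) * matrix(rlnorm(n_cells * n_genes, 0, noise_sd),
                                           n_cells, n_genes)
  list(U = U, S = S, gamma_over_beta = gamma / beta)
}

# Random kinetic parameters in the regime where the switch interrupts
# induction (all of beta, gamma and t_switch are identifiable), plus a
# time sample covering both phases.
draw_recovery_case <- function() {
  a <- runif(1, 1, 4); b <- runif(1, 0.8, 1.6); g <- runif(1, 0.3, 0.9)
  ts <- runif(1, 1.2, 2.5) / b
  tt <- sort(c(runif(40, 0, ts), ts + runif(40, 0, 6 / min(b, g))))
  list(alpha = a, beta = b, gamma = g, t_switch = ts, times = tt)
}

# Brute-force Tomek link enumeration over all pairs.
brute_tomek_links <- function(x, y) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  links <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (y[i] == y[j]) next
      # mutual NN with deterministic tie handling: j is i's first NN and
      # vice versa under (distance, index) ordering
      nn_i <- order(d[i, ], seq_len(n))[1]
      nn_j <- order(d[j, ], seq_len(n))[1]
      if (nn_i == j && nn_j == i) links <- rbind(links, c(i, j))
    }
  }
  links
}

# Brute-force metric recomputation from raw label vectors.
brute_metrics <- function(truth, pred, C) {
  acc <- mean(truth == pred)
  P <- R <- numeric(C)
  for (c in 0:(C - 1)) {
    P[c + 1] <- if (sum(pred == c) > 0) sum(truth == c & pred == c) / sum(pred == c) else 0
    R[c + 1] <- if (sum(truth == c) > 0) sum(truth == c & pred == c) / sum(truth == c) else 0
  }
  Pm <- mean(P); Rm <- mean(R)
  f1 <- if (Pm + Rm > 0) 2 * Pm * Rm / (Pm + Rm) else 0
  p0 <- acc
  pe <- sum(sapply(0:(C - 1), function(c) sum(truth == c) * sum(pred == c))) /
    length(truth)^2
  list(accuracy = acc, macro_f1 = f1,
       kappa = if (pe < 1) (p0 - pe) / (1 - pe) else 0)
}
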
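#' Per-gene kinetic parameters of the splicing model
#'
#' Bundles the rates of the two-species mRNA kinetic model
#' \deqn{dU/dt = \alpha(t) - \beta U, \qquad dS/dt = \beta U - \gamma S,}
#' where \eqn{U} is unspliced and \eqn{S} spliced mRNA abundance,
#' \eqn{\alpha} the transcription rate, \eqn{\beta} the splicing rate and
#' \eqn{\gamma} the degradation rate. Transcription switches off
#' (\eqn{\alpha \to 0}) at \code{t_switch}, starting the repression phase.
#'
#' @param alpha transcription rate (molecules per unit time, >= 0).
#' @param beta splicing rate (> 0).
#' @param gamma degradation rate (> 0).
#' @param t_switch time at which transcription switches off (>= 0; \code{Inf}
#'   for pure induction).
#' @param u0,s0 initial molecule counts (>= 0).
#' @return an object of class \code{"kinetic_params"}.
#' @export
kinetic_params <- function(alpha, beta, gamma, t_switch = Inf, u0 = 0, s0 = 0) {
  if (!is.finite(beta) || beta <= 0) stopf("beta must be > 0, got %s", format(beta))
  if (!is.finite(gamma) || gamma <= 0) stopf("gamma must be > 0, got %s", format(gamma))
  if (alpha < 0) stopf("alpha must be >= 0, got %s", format(alpha))
  if (t_switch < 0) stopf("t_switch must be >= 0, got %s", format(t_switch))
  if (u0 < 0 || s0 < 0) stopf("initial counts u0, s0 must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 t_switch = t_switch, u0 = u0, s0 = s0),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic_params: alpha=%.4g beta=%.4g gamma=%.4g t_switch=%.4g u0=%.4g s0=%.4g\n",
              x$alpha, x$beta, x$gamma, x$t_switch, x$u0, x$s0))
  invisible(x)
}

# One-phase closed form at constant alpha from initial state (u0, s0).
# For beta == gamma the analytic limit is used (the t*exp(-beta t) term),
# never a perturbation of gamma.
.kinetics_phase <- function(t, alpha, beta, gamma, u0, s0) {
  eu <- exp(-beta * t)
  u <- alpha / beta + (u0 - alpha / beta) * eu
  if (abs(beta - gamma) > 1e-12 * max(beta, gamma)) {
    es <- exp(-gamma * t)
    cc <- beta * (u0 - alpha / beta) / (gamma - beta)
    s <- alpha / gamma + (s0 - alpha / gamma - cc) * es + cc * eu
  } else {
    es <- exp(-gamma * t)
    s <- alpha / gamma + (s0 - alpha / gamma) * es + beta * (u0 - alpha / beta) * t * eu
  }
  list(u = u, s = s)
}

#' Closed-form solution of the splicing kinetics
#'
#' Solves the linear ODE system \eqn{dU/dt=\alpha-\beta U},
#' \eqn{dS/dt=\beta U-\gamma S} exactly, piecewise around \code{t_switch}
#' (after which \eqn{\alpha = 0}), continuous at the switch. The degenerate
#' case \eqn{\beta=\gamma} uses the analytic limit containing a
#' \eqn{t e^{-\beta t}} term.
#'
#' @param params a [kinetic_params()] object.
#' @param times numeric vector of time points, >= 0, sorted ascending.
#' @return a data.frame with columns \code{t}, \code{u}, \code{s}.
#' @examples
#' p <- kinetic_params(alpha = 2, beta = 1, gamma = 0.5)
#' solve_kinetics(p, c(0, 1, 50)) # approaches (alpha/beta, alpha/gamma)
#' @export
solve_kinetics <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(times < 0)) stopf("times must be >= 0")
  if (is.unsorted(times)) stopf("times must be sorted ascending")
  a <- params$alpha; b <- params$beta; g <- params$gamma; ts <- params$t_switch
  u <- numeric(length(times)); s <- numeric(length(times))
  ind <- times <= ts
  if (any(ind)) {
    ph <- .kinetics_phase(times[ind], a, b, g, params$u0, params$s0)
    u[ind] <- ph$u; s[ind] <- ph$s
  }
  if (any(!ind)) {
    sw <- .kinetics_phase(ts, a, b, g, params$u0, params$s0)
    ph <- .kinetics_phase(times[!ind] - ts, 0, b, g, sw$u, sw$s)
    u[!ind] <- ph$u; s[!ind] <- ph$s
  }
  data.frame(t = times, u = u, s = s)
}
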
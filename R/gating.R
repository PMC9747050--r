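#' Gate kinetics descriptor
#'
#' Bundles the five constants of one Hodgkin-Huxley-type gating variable:
#' the half-point voltage `theta`, the two slope factors `sigma1`/`sigma2`
#' and the two rate scales `k1`/`k2`, together with the gate's `role`.
#'
#' Activation gates (m, n, a) use
#' \deqn{\alpha(V) = k_1 (\theta - V)/(e^{(\theta - V)/\sigma_1} - 1), \quad
#'       \beta(V) = k_2 e^{V/\sigma_2}}
#' and evolve as \eqn{dx/dt = \alpha (1 - x) - \beta x}.
#'
#' The inactivation gate (h) uses the original Hodgkin-Huxley h-gate
#' functional forms with the same constants: the recovery (opening) rate is
#' the exponential \eqn{\alpha(V) = k_1 e^{V/\sigma_1}} (large at
#' hyperpolarized voltages since \eqn{\sigma_1 < 0}) and the closing rate is
#' \eqn{\beta(V) = k_2 (\theta - V)/(e^{(\theta - V)/\sigma_2} - 1)}, which
#' grows with depolarization. This places the steady-state inactivation
#' midpoint near `theta` and is the only role assignment of the tabulated
#' constants that yields a stable, spiking fast-spiking-interneuron model
#' (see the methods vignette).
#'
#' @param theta half-point voltage (mV)
#' @param sigma1,sigma2 slope factors (mV), non-zero
#' @param k1,k2 rate scales (1/ms), positive
#' @param role `"activation"` or `"inactivation"`
#' @return an object of class `gate_kinetics`
#' @seealso [gate_rates()], [default_kinetics()]
#' @export
gate_kinetics <- function(theta, sigma1, sigma2, k1, k2,
                          role = c("activation", "inactivation")) {
  role <- match.arg(role)
  stopifnot(is.finite(theta), sigma1 != 0, sigma2 != 0, k1 > 0, k2 > 0)
  structure(list(theta = theta, sigma1 = sigma1, sigma2 = sigma2,
                 k1 = k1, k2 = k2, role = role),
            class = "gate_kinetics")
}

#' @export
print.gate_kinetics <- function(x, ...) {
  cat(sprintf("<gate_kinetics: %s> theta=%g mV, sigma1=%g, sigma2=%g, k1=%g, k2=%g /ms\n",
              x$role, x$theta, x$sigma1, x$sigma2, x$k1, x$k2))
  invisible(x)
}

# F1 rate form with its removable singularity evaluated analytically at V = theta
rate_f1 <- function(V, theta, sigma, k) {
  z <- (theta - V) / sigma
  out <- ifelse(abs(z) < 1e-9, k * sigma, k * (theta - V) / expm1(z))
  out
}

#' Voltage-dependent opening and closing rates of a gate
#'
#' @param V membrane potential (mV); vectorized
#' @param kin a [gate_kinetics()] object
#' @return list with components `alpha` (opening) and `beta` (closing), 1/ms
#' @examples
#' mkin <- default_kinetics()$m
#' gate_rates(-53, mkin)$alpha  # 0.25 * 4 = 1 at the singular point
#' @export
gate_rates <- function(V, kin) {
  stopifnot(inherits(kin, "gate_kinetics"))
  if (any(!is.finite(V))) stop("non-finite membrane potential")
  if (kin$role == "activation") {
    list(alpha = rate_f1(V, kin$theta, kin$sigma1, kin$k1),
         beta  = kin$k2 * exp(V / kin$sigma2))
  } else {
    list(alpha = kin$k1 * exp(V / kin$sigma1),
         beta  = rate_f1(V, kin$theta, kin$sigma2, kin$k2))
  }
}

#' Steady-state activation and time constant of a gate
#'
#' @inheritParams gate_rates
#' @return list with `x_inf` and `tau` (ms)
#' @export
gate_steady_state <- function(V, kin) {
  r <- gate_rates(V, kin)
  list(x_inf = r$alpha / (r$alpha + r$beta), tau = 1 / (r$alpha + r$beta))
}

#' Reference gating-kinetics table for mEC fast-spiking interneurons
#'
#' The tabulated constants of the four gating variables: Nav activation `m`
#' and inactivation `h`, Kv3 activation `n` (high-threshold delayed
#' rectifier setting the maximum firing rate) and Kv1 activation `a`
#' (low-threshold current setting the cutoff frequency). The `theta` values
#' are those of the representative homogeneous-network neuron; across a
#' heterogeneous population the four `theta`s vary while the other constants
#' are fixed.
#'
#' @return named list of four [gate_kinetics()] objects (`m`, `h`, `n`, `a`)
#' @export
default_kinetics <- function() {
  list(m = gate_kinetics(-53.0,   4,  -13,  0.25,  0.1,   "activation"),
       h = gate_kinetics(-55.71, -20,  3.5, 0.012, 0.2,   "inactivation"),
       n = gate_kinetics(5.9,     12, -8.5, 1,     0.001, "activation"),
       a = gate_kinetics(51.36,   12, -80,  1,     0.02,  "activation"))
}

# 4x5 kinetics matrix + role vector for the C++ engine (rows m, h, n, a)
kin_matrix <- function(kinetics) {
  m <- t(vapply(kinetics[c("m", "h", "n", "a")], function(k)
    c(k$theta, k$sigma1, k$sigma2, k$k1, k$k2), numeric(5)))
  dimnames(m) <- list(c("m", "h", "n", "a"),
                      c("theta", "sigma1", "sigma2", "k1", "k2"))
  m
}

kin_roles <- function(kinetics) {
  vapply(kinetics[c("m", "h", "n", "a")],
         function(k) as.integer(k$role == "inactivation"), integer(1))
}
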
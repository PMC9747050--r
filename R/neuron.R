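#' Single-compartment fast-spiking interneuron model
#'
#' Constructs the parameter set of one model cell. The membrane equation is
#' \deqn{C_M dV/dt = I_{app} + g_{Na} m^3 h (E_{Na} - V)
#'   + g_{Kv1} a^4 (E_K - V) + g_{Kv3} n^4 (E_K - V) + g_L (E_L - V)
#'   + I_{syn} + I_{gap} + I_{ChR}}
#' with \eqn{E_{Na} = 50} mV and \eqn{E_K = -90} mV; every conductance
#' drives V toward its own reversal potential. Units throughout: mV, ms, nS,
#' pA, pF (nS*mV = pA, pA/pF = mV/ms).
#'
#' @param C_M membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param E_L leak reversal potential (mV)
#' @param g_Na,g_Kv1,g_Kv3 peak conductances (nS)
#' @param kinetics named list of four [gate_kinetics()] (`m`, `h`, `n`, `a`);
#'   defaults to [default_kinetics()]
#' @param theta optional named numeric vector overriding the gate half-points,
#'   e.g. `c(m = -50.7, h = -53.07, n = 8.79, a = 49.46)`
#' @return object of class `fs_neuron`
#' @seealso [reference_neuron()], [simulate_neuron()]
#' @export
fs_neuron <- function(C_M, g_L, E_L, g_Na, g_Kv1, g_Kv3,
                      kinetics = default_kinetics(), theta = NULL) {
  stopifnot(C_M > 0, g_L >= 0, g_Na >= 0, g_Kv1 >= 0, g_Kv3 >= 0,
            is.finite(E_L))
  if (!is.null(theta)) {
    for (g in names(theta)) kinetics[[g]]$theta <- unname(theta[g])
  }
  structure(list(C_M = C_M, g_L = g_L, E_L = E_L,
                 g_Na = g_Na, g_Kv1 = g_Kv1, g_Kv3 = g_Kv3,
                 E_Na = 50, E_K = -90, kinetics = kinetics),
            class = "fs_neuron")
}

#' Representative model neuron of the homogeneous network
#'
#' The single cell (f-I curve near the middle of the heterogeneous range)
#' that is cloned 100 times for the homogeneous-network and phase-response
#' analyses: g_Na 16805 nS, g_Kv1 59 nS, g_Kv3 631.7 nS, E_L -72 mV,
#' C_M 76.8 pF, g_L 14.7 nS (input resistance 68 MOhm), with the reference
#' gating table.
#'
#' @return an `fs_neuron`
#' @export
reference_neuron <- function() {
  fs_neuron(C_M = 76.8, g_L = 14.7, E_L = -72,
            g_Na = 16805, g_Kv1 = 59, g_Kv3 = 631.7)
}

#' @export
print.fs_neuron <- function(x, ...) {
  cat("<fs_neuron>\n")
  cat(sprintf("  C_M %.4g pF | g_L %.4g nS | E_L %.4g mV | R_input %.3g MOhm | tau_m %.3g ms\n",
              x$C_M, x$g_L, x$E_L, 1000 / x$g_L, x$C_M / x$g_L))
  cat(sprintf("  g_Na %.6g | g_Kv1 %.4g | g_Kv3 %.5g nS (Kv3/Na %.4f)\n",
              x$g_Na, x$g_Kv1, x$g_Kv3, x$g_Kv3 / x$g_Na))
  th <- vapply(x$kinetics, `[[`, numeric(1), "theta")
  cat(sprintf("  theta (mV): m %.4g, h %.4g, n %.4g, a %.4g\n",
              th["m"], th["h"], th["n"], th["a"]))
  invisible(x)
}

par_vector <- function(neuron) {
  c(neuron$C_M, neuron$g_L, neuron$E_L, neuron$g_Na, neuron$g_Kv1, neuron$g_Kv3)
}

#' Gating steady state of a neuron at a voltage
#'
#' @param neuron an `fs_neuron`
#' @param V membrane potential (mV)
#' @return numeric state vector `c(V, m, h, n, a)`
#' @export
steady_state <- function(neuron, V) {
  x <- vapply(neuron$kinetics[c("m", "h", "n", "a")],
              function(k) gate_steady_state(V, k)$x_inf, numeric(1))
  c(V = V, x)
}

#' Time derivatives of the neuron state
#'
#' Evaluates the right-hand side of the five model ODEs at a given state.
#' `I_extra` is the total non-intrinsic current (pA) in the convention
#' "positive depolarizes" (applied current plus synaptic, gap-junctional and
#' optogenetic terms evaluated by the caller).
#'
#' @param state numeric `c(V, m, h, n, a)`
#' @param neuron an `fs_neuron`
#' @param I_extra total non-intrinsic current (pA)
#' @return numeric derivative vector, same layout as `state`
#' @export
state_derivatives <- function(state, neuron, I_extra = 0) {
  if (any(!is.finite(state))) stop("non-finite state")
  V <- state[1]; m <- state[2]; h <- state[3]; n <- state[4]; a <- state[5]
  I <- neuron$g_Na * m^3 * h * (neuron$E_Na - V) +
    neuron$g_Kv1 * a^4 * (neuron$E_K - V) +
    neuron$g_Kv3 * n^4 * (neuron$E_K - V) +
    neuron$g_L * (neuron$E_L - V) + I_extra
  r <- lapply(neuron$kinetics[c("m", "h", "n", "a")], function(k) gate_rates(V, k))
  x <- state[2:5]
  dx <- vapply(seq_along(x), function(i)
    r[[i]]$alpha * (1 - x[i]) - r[[i]]$beta * x[i], numeric(1))
  out <- c(I / neuron$C_M, dx)
  names(out) <- c("V", "m", "h", "n", "a")
  out
}

#' Resting membrane potential of an isolated neuron
#'
#' Solves the steady-state current balance (all gates at their
#' voltage-dependent steady state, no synaptic or optogenetic input) by
#' bisection to 0.01 mV.
#'
#' @param neuron an `fs_neuron`
#' @param interval search interval (mV)
#' @return resting potential (mV)
#' @export
resting_potential <- function(neuron, interval = c(-95, -40)) {
  f <- function(V) {
    s <- steady_state(neuron, V)
    state_derivatives(s, neuron, 0)[1]
  }
  # below E_K all currents depolarize, so f > 0 at the lower end; the rest
  # is the lowest downward zero crossing (high-g_Na cells can have further
  # depolarized fixed points)
  grid <- seq(interval[1], interval[2], by = 0.5)
  fg <- vapply(grid, f, numeric(1))
  k <- which(fg[-length(fg)] > 0 & fg[-1] <= 0)
  if (!length(k))  # e.g. leak-compensated cells whose quiescence is marginal
    k <- which(sign(fg[-length(fg)]) * sign(fg[-1]) <= 0)
  if (!length(k)) return(grid[which.min(abs(fg))])
  uniroot(f, grid[c(k[1], k[1] + 1)], tol = 1e-4)$root
}

#' Simulate a single model neuron
#'
#' Integrates the five model ODEs with a fixed step (forward Euler by
#' default, classical Runge-Kutta optionally) and logs spikes at upward
#' crossings of the -30 mV threshold (interpolated crossing time, 1 ms
#' lockout).
#'
#' @param neuron an `fs_neuron`
#' @param drive a drive descriptor from [drive_constant()], [drive_theta()]
#'   or [drive_current()]
#' @param duration simulated time (ms)
#' @param dt integration step (ms), default 0.01
#' @param method `"euler"` or `"rk4"`
#' @param record `"v"` to keep the voltage trace, `"state"` for all five
#'   state variables, `"spikes"` for spike times only
#' @param init optional initial state `c(V, m, h, n, a)`; defaults to the
#'   gating steady state at `E_L`
#' @param perturbation optional biexponential conductance perturbation,
#'   `list(t_on =, g_peak =, tau1 = 2, tau2 = 0.3, E_syn = -75)` (peak
#'   conductance `g_peak` nS at `t_on + t_peak`)
#' @param blowup `"error"` to stop with a diagnostic naming the step when
#'   |V| exceeds 200 mV, `"flag"` to return with `blown = TRUE`
#' @return object of class `neuron_sim`: list with `spikes` (ms), `t`, `V`
#'   (if recorded), `states` (if recorded), `final_state`, `blown`, and the
#'   call parameters
#' @examples
#' sim <- simulate_neuron(reference_neuron(), drive_constant(7), 100)
#' length(sim$spikes)
#' @export
simulate_neuron <- function(neuron, drive, duration, dt = 0.01,
                            method = c("euler", "rk4"),
                            record = c("v", "state", "spikes"),
                            init = NULL, perturbation = NULL,
                            blowup = c("error", "flag")) {
  method <- match.arg(method)
  record <- match.arg(record)
  blowup <- match.arg(blowup)
  stopifnot(dt > 0, duration > dt)
  pert <- numeric(0)
  if (!is.null(perturbation)) {
    p <- perturbation
    pert <- c(p$t_on, p$g_peak,
              if (is.null(p$tau1)) 2.0 else p$tau1,
              if (is.null(p$tau2)) 0.3 else p$tau2,
              if (is.null(p$E_syn)) -75 else p$E_syn)
  }
  res <- cpp_simulate_neuron(par_vector(neuron), kin_matrix(neuron$kinetics),
                             kin_roles(neuron$kinetics),
                             duration, dt, as.integer(method == "rk4"),
                             drive$I_app, drive$g_const,
                             drive$theta_gmax, drive$theta_freq,
                             pert, if (is.null(init)) numeric(0) else init,
                             record != "spikes", record == "state",
                             -30, 1.0, blowup == "error")
  n <- round(duration / dt)
  out <- structure(list(spikes = res$spikes,
                        t = if (record != "spikes") seq_len(n) * dt else NULL,
                        V = if (record != "spikes") res$V else NULL,
                        states = if (record == "state") {
                          colnames(res$states) <- c("V", "m", "h", "n", "a")
                          res$states
                        } else NULL,
                        final_state = res$final_state,
                        blown = res$blown, blow_step = res$blow_step,
                        duration = duration, dt = dt, method = method,
                        drive = drive, neuron = neuron),
                   class = "neuron_sim")
  out
}

#' @export
print.neuron_sim <- function(x, ...) {
  cat(sprintf("<neuron_sim> %g ms at dt %g ms (%s): %d spikes",
              x$duration, x$dt, x$method, length(x$spikes)))
  if (length(x$spikes) > 3) {
    isi <- diff(x$spikes)
    cat(sprintf(", steady rate %.1f Hz", 1000 / mean(tail(isi, 10))))
  }
  if (x$blown) cat(sprintf("  [DIVERGED at step %d]", x$blow_step))
  cat("\n")
  invisible(x)
}

#' @export
plot.neuron_sim <- function(x, xlim = NULL, ...) {
  if (is.null(x$V)) stop("voltage trace was not recorded")
  plot(x$t, x$V, type = "l", xlab = "time (ms)", ylab = "V (mV)",
       xlim = xlim, ...)
  abline(h = -30, lty = 3, col = "grey50")
  invisible(x)
}

#' Drive descriptors
#'
#' `drive_constant()` applies a constant channelrhodopsin-like conductance
#' with reversal 0 mV; `drive_theta()` the theta-modulated optogenetic
#' drive, a raised cosine `g(t) = g_max/2 (1 - cos(2 pi f t / 1000))`
#' spanning 0 to `g_max` with minimum at t = 0 and peak at the half-cycle;
#' `drive_current()` a constant applied current (electrode current step).
#'
#' @param g_const constant conductance (nS)
#' @param g_max peak theta conductance (nS), default 14
#' @param freq theta frequency (Hz), default 8
#' @param I_app applied current (pA)
#' @return a `drive` descriptor list
#' @export
drive_constant <- function(g_const) {
  structure(list(mode = "constant", g_const = g_const, theta_gmax = 0,
                 theta_freq = 0, I_app = 0), class = "drive")
}

#' @rdname drive_constant
#' @export
drive_theta <- function(g_max = 14, freq = 8) {
  stopifnot(g_max > 0, freq > 0)
  structure(list(mode = "theta", g_const = 0, theta_gmax = g_max,
                 theta_freq = freq, I_app = 0), class = "drive")
}

#' @rdname drive_constant
#' @export
drive_current <- function(I_app) {
  structure(list(mode = "current", g_const = 0, theta_gmax = 0,
                 theta_freq = 0, I_app = I_app), class = "drive")
}
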
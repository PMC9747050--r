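#' Free-running period at a constant drive
#'
#' Mean of the last 10 inter-spike intervals after a settling run.
#'
#' @param neuron an `fs_neuron`
#' @param g_const constant channelrhodopsin-like conductance (nS)
#' @param settle settling time (ms), default 200
#' @param n_isi number of final intervals to average, default 10
#' @param dt integration step (ms)
#' @return period (ms)
#' @export
free_running_period <- function(neuron, g_const, settle = 200, n_isi = 10,
                                dt = 0.01) {
  dur <- settle + 40 * 8   # room for >= n_isi slow cycles
  sim <- simulate_neuron(neuron, drive_constant(g_const), dur, dt = dt,
                         record = "spikes")
  sp <- sim$spikes[sim$spikes > settle]
  if (length(sp) < n_isi + 1)
    stop("neuron does not fire repetitively at this constant drive")
  mean(tail(diff(sp), n_isi))
}

#' First- and second-order phase response curve
#'
#' On separate trials, a compound inhibitory biexponential conductance
#' (default 36 unitary synapses of 1.65 nS, i.e. the synchronous input one
#' neuron receives during global network synchrony) is applied at each of
#' `n_phases` equally spaced phases of the free-running cycle, with phase 0
#' at the -30 mV threshold crossing. The first-order resetting
#' `f1(theta) = (P_perturbed - P_i)/P_i` is the normalized change of the
#' cycle containing the perturbation onset (delays positive, advances
#' negative); `f2(theta)` is the same for the following cycle.
#'
#' @param neuron an `fs_neuron`
#' @param g_const constant drive during the PRC protocol (nS), default 7
#'   (the midpoint of the theta modulation)
#' @param g_peak compound perturbation peak conductance (nS), default
#'   `36 * 1.65`
#' @param E_syn perturbation reversal (mV): -75 hyperpolarizing, -55 shunting
#' @param n_phases number of sampled phases, default 100
#' @param tau1,tau2 biexponential time constants (ms)
#' @param settle settling time before the reference crossing (ms)
#' @param dt integration step (ms)
#' @return object of class `prc`: data.frame (`phase`, `f1`, `f2`) with
#'   attributes `period` (P_i, ms), `E_syn`, `g_peak`, `trough_phase` (phase
#'   of the action-potential trough) and `undefined` (phases where the
#'   perturbation abolished spiking, if any)
#' @export
compute_prc <- function(neuron, g_const = 7, g_peak = 36 * 1.65, E_syn = -75,
                        n_phases = 100, tau1 = 2.0, tau2 = 0.3,
                        settle = 300, dt = 0.01) {
  sim <- simulate_neuron(neuron, drive_constant(g_const), settle + 60,
                         dt = dt, record = "state")
  sp <- sim$spikes[sim$spikes > settle]
  if (length(sp) < 3) stop("neuron does not fire repetitively at g_const")
  # state snapshot at the first step after a threshold crossing = phase 0
  i0 <- ceiling(sp[1] / dt)
  snap <- sim$states[i0, ]
  P <- sp[2] - sp[1]
  i1 <- ceiling(sp[2] / dt) - 1L
  cyc_V <- sim$states[i0:i1, 1]
  trough_phase <- (which.min(cyc_V) - 1) * dt / P
  phases <- (seq_len(n_phases) - 1) / n_phases
  f1 <- f2 <- rep(NA_real_, n_phases)
  for (k in seq_len(n_phases)) {
    trial <- simulate_neuron(neuron, drive_constant(g_const), 5 * P, dt = dt,
                             record = "spikes", init = snap,
                             perturbation = list(t_on = phases[k] * P,
                                                 g_peak = g_peak,
                                                 tau1 = tau1, tau2 = tau2,
                                                 E_syn = E_syn))
    cr <- trial$spikes
    if (length(cr) >= 2) {
      f1[k] <- (cr[1] - P) / P
      f2[k] <- (cr[2] - cr[1] - P) / P
    }
  }
  undefined <- phases[is.na(f1)]
  structure(data.frame(phase = phases, f1 = f1, f2 = f2),
            class = c("prc", "data.frame"),
            period = P, E_syn = E_syn, g_peak = g_peak, g_const = g_const,
            trough_phase = trough_phase, undefined = undefined)
}

#' @export
print.prc <- function(x, ...) {
  cat(sprintf("<prc> %d phases | P_i %.3f ms | E_syn %g mV | g_peak %.2f nS\n",
              nrow(x), attr(x, "period"), attr(x, "E_syn"), attr(x, "g_peak")))
  cat(sprintf("  f1 range [%.3f, %.3f] | AP trough at phase %.3f\n",
              min(x$f1, na.rm = TRUE), max(x$f1, na.rm = TRUE),
              attr(x, "trough_phase")))
  invisible(x)
}

#' @export
plot.prc <- function(x, ...) {
  plot(x$phase, x$f1, type = "l", xlab = "phase", ylab = "normalized resetting",
       ...)
  lines(x$phase, x$f2, lty = 2)
  abline(h = 0, col = "grey60")
  legend("topleft", legend = c("f1 (perturbed cycle)", "f2 (next cycle)"),
         lty = c(1, 2), bty = "n")
  invisible(x)
}

prc_interp <- function(prc, what, theta) {
  ok <- !is.na(prc[[what]])
  if (any(!ok) && any(abs(prc$phase[!ok] - theta) < 1.5 / nrow(prc)))
    stop("locking phase falls on an undefined PRC sample")
  approx(prc$phase[ok], prc[[what]][ok], xout = theta, rule = 2)$y
}

#' Predicted network frequency from a PRC
#'
#' In global synchrony with conduction delay `delta`, each neuron receives
#' the compound input at the locking phase `theta = delta / P_i`. The locked
#' period is `P_i (1 + f1(theta))` (first order), optionally plus
#' `f2(theta)` (order `"1+2"`), interpolated on the PRC grid.
#'
#' @param prc a `prc` object
#' @param delta conduction delay (ms), must be below the period
#' @param order `"1"` or `"1+2"`
#' @return predicted frequency (Hz), with the locking phase as attribute
#' @export
predict_network_frequency <- function(prc, delta, order = c("1", "1+2")) {
  order <- match.arg(order)
  P <- attr(prc, "period")
  if (delta >= P) stop("conduction delay must be smaller than the period")
  theta <- delta / P
  f <- prc_interp(prc, "f1", theta)
  if (order == "1+2") f <- f + prc_interp(prc, "f2", theta)
  out <- 1000 / (P * (1 + f))
  attr(out, "locking_phase") <- theta
  out
}

#' Synchrony stability multiplier from the PRC slope
#'
#' A perturbation of a single neuron from global synchrony scales per cycle
#' by `1 - f1'(theta)` at the locking phase: |multiplier| below one is
#' stable, above one unstable; a slope of exactly one is maximally
#' stabilizing (multiplier 0). The slope comes from centered finite differences on the
#' PRC grid (one-sided at the edges, with a warning). Nearby PRC
#' discontinuities (adjacent-sample jumps exceeding 5x the median jump) are
#' flagged, since sampling them destabilizes synchrony.
#'
#' @param prc a `prc` object
#' @param theta locking phase in [0, 1)
#' @return list: `multiplier`, `slope`, `classification`
#'   (stable/unstable/marginal), `near_discontinuity`
#' @export
stability_multiplier <- function(prc, theta) {
  ph <- prc$phase; f1 <- prc$f1
  np <- length(ph)
  k <- which.min(abs(ph - theta))
  if (k == 1 || k == np) {
    warning("locking phase at the PRC grid edge; using a one-sided difference")
    slope <- if (k == 1) (f1[2] - f1[1]) / (ph[2] - ph[1])
             else (f1[np] - f1[np - 1]) / (ph[np] - ph[np - 1])
  } else {
    slope <- (f1[k + 1] - f1[k - 1]) / (ph[k + 1] - ph[k - 1])
  }
  jumps <- abs(diff(f1))
  near <- any(jumps[max(1, k - 2):min(np - 1, k + 1)] >
                5 * median(jumps, na.rm = TRUE), na.rm = TRUE)
  mult <- 1 - slope
  cls <- if (abs(abs(mult) - 1) < 1e-9) "marginal"
         else if (abs(mult) < 1) "stable" else "unstable"
  list(multiplier = mult, slope = slope, classification = cls,
       near_discontinuity = near)
}

#' Zero crossing and slope reversal of the first-order PRC
#'
#' `prc_sign_change()` locates the first zero crossing of f1 by linear
#' interpolation between the bracketing samples. `prc_slope_reversal()`
#' locates the first sign change of the f1 slope (the PRC extremum), which
#' for shunting inhibition sits very near the action-potential trough.
#'
#' @param prc a `prc` object
#' @param from search start phase (default 0)
#' @return phase of the crossing (NA if none)
#' @export
prc_sign_change <- function(prc, from = 0) {
  ok <- !is.na(prc$f1) & prc$phase >= from
  ph <- prc$phase[ok]; f1 <- prc$f1[ok]
  s <- which(diff(sign(f1)) != 0)
  if (!length(s)) return(NA_real_)
  i <- s[1]
  ph[i] - f1[i] * (ph[i + 1] - ph[i]) / (f1[i + 1] - f1[i])
}

#' @rdname prc_sign_change
#' @export
prc_slope_reversal <- function(prc, from = 0) {
  ok <- !is.na(prc$f1) & prc$phase >= from
  ph <- prc$phase[ok]; f1 <- prc$f1[ok]
  d <- diff(f1)
  s <- which(diff(sign(d)) != 0)
  if (!length(s)) return(NA_real_)
  ph[s[1] + 1]
}

#' Perturbation experiment on a homogeneous network
#'
#' Runs the network from a chosen initialization and reports when (if ever)
#' it reaches global synchrony, defined as a population spike containing at
#' least `sync_count` neurons within 1 ms.
#'
#' @param spec a homogeneous `network_spec` with constant drive
#' @param init `"random"` (random limit-cycle phases) or `"offset_one"`
#'   (all neurons at threshold, one offset by `offset` cycle fractions)
#' @param offset phase offset of the perturbed neuron (cycle fraction)
#' @param duration run length (ms)
#' @param sync_count coincident neurons required (default `n - 1`)
#' @param seed RNG seed for random init
#' @param dt integration step (ms)
#' @return list: `raster`, `sync_times`, `synchronized`, `first_sync` (ms),
#'   `cycles_to_sync` (population spikes preceding the first synchronous
#'   one; 0 if the very first population spike is synchronous),
#'   `frequency` (Hz after synchrony, NA if never synchronized)
#' @export
perturbation_experiment <- function(spec, init = c("random", "offset_one", "rest"),
                                    offset = 0.1, duration = 400,
                                    sync_count = nrow(spec$population) - 1,
                                    seed = 1, dt = 0.01) {
  init <- match.arg(init)
  n <- nrow(spec$population)
  states <- if (init == "offset_one") {
    init_states(spec, "on_cycle", offsets = c(offset, rep(0, n - 1)), dt = dt)
  } else {
    init_states(spec, init, seed = seed, dt = dt)
  }
  raster <- run_network(spec, duration, dt = dt, init = states)
  ps_all <- population_spikes(raster, min_count = n / 2, transient = 0)
  ps_sync <- population_spikes(raster, min_count = sync_count, transient = 0)
  synchronized <- length(ps_sync$times) > 0
  first <- if (synchronized) ps_sync$times[1] else NA_real_
  cycles <- if (synchronized) sum(ps_all$times < first - 1) else NA_integer_
  freq <- if (synchronized && length(ps_sync$times) > 3)
    1000 / median(diff(ps_sync$times[ps_sync$times > 50])) else NA_real_
  list(raster = raster, sync_times = ps_sync$times, synchronized = synchronized,
       first_sync = first, cycles_to_sync = cycles, frequency = freq)
}
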
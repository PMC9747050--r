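#' Peak time and normalization of the biexponential synaptic waveform
#'
#' The unitary conductance is
#' `g(t) = F (exp(-t/tau1) - exp(-t/tau2))` with decay `tau1` and rise
#' `tau2`; `F` scales the peak to one so that the synaptic weight is the
#' peak conductance. The peak occurs at the closed-form time
#' `t_peak = tau1 tau2 / (tau1 - tau2) * log(tau1/tau2)`.
#'
#' @param tau1 decay time constant (ms), default 2.0
#' @param tau2 rise time constant (ms), default 0.3; must satisfy
#'   `tau1 > tau2 > 0`
#' @return `biexp_normalization()`: the factor F; `biexp_peak_time()`: t_peak (ms)
#' @export
biexp_normalization <- function(tau1 = 2.0, tau2 = 0.3) {
  tpk <- biexp_peak_time(tau1, tau2)
  1 / (exp(-tpk / tau1) - exp(-tpk / tau2))
}

#' @rdname biexp_normalization
#' @export
biexp_peak_time <- function(tau1 = 2.0, tau2 = 0.3) {
  if (!(tau1 > tau2 && tau2 > 0)) stop("need tau1 > tau2 > 0")
  tau1 * tau2 / (tau1 - tau2) * log(tau1 / tau2)
}

#' Short-term depression: depletion-variable updates
#'
#' The available transmitter fraction x recovers between spikes as
#' `x(t) = 1 - (1 - x0) exp(-t/tau_r)` and is depleted by each spike,
#' `x <- x (1 - U_SE)`, after its pre-spike value has scaled the
#' transmitted conductance. `std_elapse()` and `std_spike()` implement the
#' two updates; `std_fixed_point()` gives the closed-form steady-state
#' pre-spike value under periodic firing at period T:
#' `x* = (1 - e^(-T/tau_r)) / (1 - (1 - U_SE) e^(-T/tau_r))`.
#'
#' @param x depletion state in `[0, 1]`
#' @param dt elapsed time (ms)
#' @param tau_r recovery time constant (ms), default 100
#' @param U_SE release fraction per spike, default 0.3
#' @param T inter-spike period (ms)
#' @return updated x (or the fixed point)
#' @export
std_elapse <- function(x, dt, tau_r = 100) {
  stopifnot(all(x >= 0 & x <= 1), dt >= 0)
  1 - (1 - x) * exp(-dt / tau_r)
}

#' @rdname std_elapse
#' @export
std_spike <- function(x, U_SE = 0.3) {
  stopifnot(all(x >= 0 & x <= 1))
  x * (1 - U_SE)
}

#' @rdname std_elapse
#' @export
std_fixed_point <- function(T, tau_r = 100, U_SE = 0.3) {
  e <- exp(-T / tau_r)
  (1 - e) / (1 - (1 - U_SE) * e)
}

#' Chemical-synapse connectivity
#'
#' Homogeneous mode: every neuron receives exactly `in_degree` synapses
#' (default 36) of identical strength (default 1.65 nS) and identical
#' conduction delay (default 0.8 ms), with presynaptic partners drawn
#' uniformly without self-connections. Heterogeneous mode: each ordered
#' pair is connected independently with probability `p` (default 0.36, no
#' self-edges), peak conductances are lognormal with median 1 nS and
#' log-scale sigma 1, and delays are uniform on `delay_range`
#' (0.6-1.0 ms). `autapse_fraction > 0` reroutes that fraction of each
#' neuron's inhibitory in-degree to a self-synapse of equal total
#' conductance (robustness check; default off).
#'
#' @param n network size
#' @param mode `"homogeneous"` or `"heterogeneous"`
#' @param seed RNG seed
#' @param in_degree exact in-degree in homogeneous mode
#' @param g_syn homogeneous peak conductance (nS)
#' @param delay homogeneous conduction delay (ms)
#' @param p connection probability per direction (heterogeneous)
#' @param sigma_log lognormal sigma (heterogeneous weights)
#' @param median_nS lognormal median (nS)
#' @param delay_range heterogeneous delay range (ms)
#' @param autapse_fraction fraction of in-degree rerouted to an autapse
#' @return data.frame of class `synapse_list`: `pre`, `post`, `g_syn`, `delay`
#' @export
build_chemical_connectivity <- function(n = 100,
                                        mode = c("homogeneous", "heterogeneous"),
                                        seed = 1, in_degree = 36, g_syn = 1.65,
                                        delay = 0.8, p = 0.36, sigma_log = 1,
                                        median_nS = 1,
                                        delay_range = c(0.6, 1.0),
                                        autapse_fraction = 0) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "homogeneous") {
    if (n <= in_degree)
      stop(sprintf("need n > in_degree (%d) for exact in-degree sampling", in_degree))
    pre <- unlist(lapply(seq_len(n), function(j)
      sample(setdiff(seq_len(n), j), in_degree)))
    edges <- data.frame(pre = pre, post = rep(seq_len(n), each = in_degree),
                        g_syn = g_syn, delay = delay)
  } else {
    pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
    pairs <- pairs[pairs$pre != pairs$post, ]
    on <- runif(nrow(pairs)) < p
    edges <- pairs[on, , drop = FALSE]
    k <- nrow(edges)
    edges$g_syn <- median_nS * exp(rnorm(k, 0, sigma_log))
    edges$delay <- runif(k, delay_range[1], delay_range[2])
    rownames(edges) <- NULL
  }
  if (autapse_fraction > 0) {
    for (j in seq_len(n)) {
      inc <- which(edges$post == j & edges$pre != j)
      n_move <- round(autapse_fraction * length(inc))
      if (n_move > 0) {
        mv <- sample(inc, n_move)
        g_total <- sum(edges$g_syn[mv])
        edges <- edges[-mv, , drop = FALSE]
        edges <- rbind(edges, data.frame(pre = j, post = j, g_syn = g_total,
                                         delay = mean(edges$delay)))
      }
    }
    rownames(edges) <- NULL
  }
  structure(edges, class = c("synapse_list", "data.frame"),
            mode = mode, seed = seed)
}

#' Gap-junction connectivity
#'
#' Candidate-partner procedure (default): every neuron draws 27 candidate
#' partners at random; a junction forms for each drawn pair not already
#' present. Each junction is bidirectional with a single conductance: with
#' probability 0.25 the strong mode (point mass at 1.2 nS), otherwise the
#' weak mode, the positive half of a zero-mean Gaussian with sd 0.4 nS.
#' `method = "bernoulli"` instead connects each unordered pair independently
#' with probability 0.27. The returned list is later pruned by
#' [apply_gap_compensation()]'s leak floor.
#'
#' @param n network size
#' @param seed RNG seed
#' @param n_candidates candidate partners per neuron (default 27)
#' @param p_pair pairwise probability for `method = "bernoulli"` (default 0.27)
#' @param p_strong probability of the strong mode (default 0.25)
#' @param g_strong strong-mode conductance (nS), default 1.2
#' @param sd_weak weak-mode half-Gaussian sd (nS), default 0.4
#' @param method `"partner"` or `"bernoulli"`
#' @return data.frame of class `gap_list`: `i`, `j` (i < j), `g_gap`
#' @export
build_gap_connectivity <- function(n = 100, seed = 1, n_candidates = 27,
                                   p_pair = 0.27, p_strong = 0.25,
                                   g_strong = 1.2, sd_weak = 0.4,
                                   method = c("partner", "bernoulli")) {
  method <- match.arg(method)
  set.seed(seed)
  if (method == "partner") {
    seen <- new.env(hash = TRUE)
    ii <- integer(0); jj <- integer(0)
    for (i in seq_len(n)) {
      partners <- sample(setdiff(seq_len(n), i), min(n_candidates, n - 1))
      for (j in partners) {
        key <- paste(min(i, j), max(i, j))
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          ii <- c(ii, min(i, j)); jj <- c(jj, max(i, j))
        }
      }
    }
    edges <- data.frame(i = ii, j = jj)
  } else {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < p_pair
    edges <- data.frame(i = pairs[on, 1], j = pairs[on, 2])
  }
  k <- nrow(edges)
  strong <- runif(k) < p_strong
  g <- ifelse(strong, g_strong, abs(rnorm(k, 0, sd_weak)))
  edges$g_gap <- g
  rownames(edges) <- NULL
  structure(edges, class = c("gap_list", "data.frame"),
            method = method, seed = seed)
}

#' Theta-drive conductance and phase
#'
#' The simulated channelrhodopsin drive is a raised cosine
#' `g(t) = g_max/2 (1 - cos(2 pi f t / 1000))`: continuous, spanning 0 to
#' `g_max`, with its minimum at the cycle start and its peak (the theta
#' peak) at the half-cycle. The theta phase of a time point is defined
#' analytically from this waveform, with phase 0 at the conductance peak,
#' in `(-pi, pi]`.
#'
#' @param t time (ms), vectorized
#' @param drive a [drive_theta()] descriptor (or `g_max`/`freq` given directly)
#' @param g_max,freq used if `drive` is missing
#' @return conductance (nS) / phase (rad)
#' @export
theta_conductance <- function(t, drive = NULL, g_max = 14, freq = 8) {
  stopifnot(all(t >= 0))
  if (!is.null(drive)) { g_max <- drive$theta_gmax; freq <- drive$theta_freq }
  0.5 * g_max * (1 - cos(2 * pi * freq * t / 1000))
}

#' @rdname theta_conductance
#' @export
theta_phase <- function(t, drive = NULL, freq = 8) {
  if (!is.null(drive)) freq <- drive$theta_freq
  ph <- 2 * pi * freq * t / 1000 - pi   # 0 at the conductance peak
  wrapped <- ((ph + pi) %% (2 * pi)) - pi
  ifelse(wrapped == -pi, pi, wrapped)
}
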
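#' Action-potential features of a simulated trace
#'
#' For every detected spike: amplitude above the -30 mV detection threshold
#' (peak minus -30), half-width (time spent above the midpoint between -30
#' and the peak) and after-hyperpolarization depth. The AHP is measured the
#' way an electrophysiologist would: from the spike-onset voltage (where the
#' upstroke dV/dt first exceeds `dvdt_onset`) down to the post-spike trough
#' before the next spike. Referencing the AHP to the fixed -30 mV line would
#' overstate it by the onset-to-threshold gap (~20 mV in these cells).
#'
#' @param sim a `neuron_sim` with a recorded voltage trace
#' @param dvdt_onset upstroke rate criterion for spike onset (mV/ms)
#' @return data.frame with one row per analyzable spike: `time`, `peak_mV`,
#'   `amplitude_mV`, `half_width_ms`, `ahp_depth_mV`, `onset_mV`; zero rows
#'   if the trace has no spikes
#' @export
spike_features <- function(sim, dvdt_onset = 20) {
  stopifnot(inherits(sim, "neuron_sim"))
  if (is.null(sim$V)) stop("voltage trace was not recorded")
  sp <- sim$spikes
  empty <- data.frame(time = numeric(0), peak_mV = numeric(0),
                      amplitude_mV = numeric(0), half_width_ms = numeric(0),
                      ahp_depth_mV = numeric(0), onset_mV = numeric(0))
  if (length(sp) == 0) return(empty)
  V <- sim$V; dt <- sim$dt; nT <- length(V)
  dV <- c(diff(V), 0) / dt
  rows <- vector("list", length(sp))
  for (k in seq_along(sp)) {
    i0 <- max(1L, floor(sp[k] / dt))
    i_end <- if (k < length(sp)) floor(sp[k + 1] / dt) else nT
    iwin <- i0:min(i0 + round(2 / dt), i_end, nT)
    ipk <- iwin[which.max(V[iwin])]
    peak <- V[ipk]
    # spike onset: walk back from the crossing until the upstroke slows
    j <- i0
    while (j > 1 && dV[j - 1] > dvdt_onset) j <- j - 1
    onset <- V[j]
    # half-width around the peak at the midpoint between -30 and peak
    mid <- (peak + (-30)) / 2
    lo <- ipk; while (lo > 1 && V[lo - 1] > mid) lo <- lo - 1
    hi <- ipk; while (hi < nT && V[hi + 1] > mid) hi <- hi + 1
    hw <- (hi - lo + 1) * dt
    trough <- min(V[ipk:min(i_end, nT)])
    rows[[k]] <- data.frame(time = sp[k], peak_mV = peak,
                            amplitude_mV = peak - (-30), half_width_ms = hw,
                            ahp_depth_mV = onset - trough, onset_mV = onset)
  }
  do.call(rbind, rows)
}

sustained_firing <- function(spikes, duration) {
  if (length(spikes) < 4) return(FALSE)
  isi <- diff(spikes)
  tail_isi <- mean(tail(isi, 3))
  spikes[length(spikes)] > duration - 2 * tail_isi - 5
}

steady_frequency <- function(spikes, duration) {
  # mean ISI over the last half of the step, after early adaptation
  sp <- spikes[spikes > duration / 2]
  if (length(sp) < 3) return(NA_real_)
  1000 / mean(diff(sp))
}

#' Frequency-current curve
#'
#' Applies depolarizing current steps on a regular grid (default 25 pA, the
#' experimental increment) and records the stabilized steady firing
#' frequency, taken as the mean inverse inter-spike interval over the last
#' half of each step. Only current levels that sustain repetitive firing to
#' the end of the step report a frequency. The rheobase is the smallest
#' sustaining current on the grid and the cutoff frequency is the frequency
#' at rheobase; for these type-2 cells it is strictly positive (firing
#' onset is abrupt).
#'
#' @param neuron an `fs_neuron`
#' @param I_min,I_max current range (pA)
#' @param step grid increment (pA), default 25
#' @param step_dur step duration (ms), default 500
#' @param dt integration step (ms)
#' @return object of class `fI_curve`: data.frame (`I_pA`, `freq_Hz`,
#'   `sustained`, `n_spikes`) plus attributes `rheobase` and `cutoff`
#'   (NA if the neuron never fires repetitively on the grid)
#' @export
fI_curve <- function(neuron, I_min = 0, I_max = 1000, step = 25,
                     step_dur = 500, dt = 0.01) {
  stopifnot(I_min < I_max, step > 0)
  grid <- seq(I_min, I_max, by = step)
  rows <- lapply(grid, function(I) {
    sim <- simulate_neuron(neuron, drive_current(I), step_dur, dt = dt,
                           record = "spikes", blowup = "flag")
    if (sim$blown)
      return(data.frame(I_pA = I, freq_Hz = NA_real_, sustained = FALSE,
                        n_spikes = NA_integer_))
    sus <- sustained_firing(sim$spikes, step_dur)
    data.frame(I_pA = I,
               freq_Hz = if (sus) steady_frequency(sim$spikes, step_dur) else NA_real_,
               sustained = sus, n_spikes = length(sim$spikes))
  })
  out <- do.call(rbind, rows)
  sus_I <- out$I_pA[out$sustained]
  rheo <- if (length(sus_I)) min(sus_I) else NA_real_
  cutoff <- if (!is.na(rheo)) out$freq_Hz[match(rheo, out$I_pA)] else NA_real_
  structure(out, class = c("fI_curve", "data.frame"),
            rheobase = rheo, cutoff = cutoff, neuron = neuron)
}

#' @export
print.fI_curve <- function(x, ...) {
  cat(sprintf("<fI_curve> %d current levels; rheobase %s pA, cutoff %s Hz\n",
              nrow(x), format(attr(x, "rheobase")),
              format(round(attr(x, "cutoff"), 1))))
  print.data.frame(head(x[x$sustained, ], 8))
  invisible(x)
}

#' @export
plot.fI_curve <- function(x, ...) {
  plot(x$I_pA, x$freq_Hz, type = "b", pch = 16,
       xlab = "I (pA)", ylab = "steady frequency (Hz)", ...)
  abline(v = attr(x, "rheobase"), lty = 3)
  invisible(x)
}

# Grid-exact rheobase by bracketing + binary search over the 25 pA grid
# (sustained firing is monotone in I for these type-2 cells).
rheobase_search <- function(neuron, step = 25, I_cap = 2400, step_dur = 500,
                            dt = 0.01) {
  sustains <- function(I) {
    sim <- simulate_neuron(neuron, drive_current(I), step_dur, dt = dt,
                           record = "spikes", blowup = "flag")
    if (sim$blown) return(NA)
    sustained_firing(sim$spikes, step_dur)
  }
  hi <- 200
  repeat {
    s <- sustains(hi)
    if (is.na(s)) return(list(rheobase = NA_real_, cutoff = NA_real_, blown = TRUE))
    if (s) break
    hi <- hi * 2
    if (hi > I_cap) return(list(rheobase = NA_real_, cutoff = NA_real_, blown = FALSE))
  }
  lo <- 0
  lo_i <- 0L; hi_i <- as.integer(hi / step)
  while (hi_i - lo_i > 1L) {
    mid <- as.integer((lo_i + hi_i) %/% 2)
    s <- sustains(mid * step)
    if (is.na(s)) return(list(rheobase = NA_real_, cutoff = NA_real_, blown = TRUE))
    if (s) hi_i <- mid else lo_i <- mid
  }
  rheo <- hi_i * step
  sim <- simulate_neuron(neuron, drive_current(rheo), step_dur, dt = dt,
                         record = "spikes", blowup = "flag")
  list(rheobase = rheo, cutoff = steady_frequency(sim$spikes, step_dur),
       blown = FALSE)
}
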
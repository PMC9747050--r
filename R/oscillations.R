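#' Instantaneous population firing rate
#'
#' Bins all spikes at `bin` ms (default 0.1), optionally smooths with a
#' flat sliding window, and normalizes to spikes/s per neuron. The integral
#' of the rate times `n * bin/1000` recovers the total spike count.
#'
#' @param raster a `spike_raster`
#' @param bin bin width (ms), default 0.1
#' @param smooth_width flat smoothing window width (ms); the default equals
#'   the bin width (no extra smoothing)
#' @return object of class `population_rate`: list with `t` (bin centers,
#'   ms), `rate` (spikes/s per neuron), `fs` (sampling rate, Hz), `n`, `bin`
#' @export
population_rate <- function(raster, bin = 0.1, smooth_width = bin) {
  edges <- seq(0, raster$duration, by = bin)
  if (edges[length(edges)] < raster$duration)
    edges <- c(edges, raster$duration)
  allsp <- unlist(raster$spikes)
  counts <- if (length(allsp))
    graphics::hist(allsp, breaks = edges, plot = FALSE)$counts
  else rep(0, length(edges) - 1)
  rate <- counts / raster$n / (bin / 1000)
  w <- max(1L, round(smooth_width / bin))
  if (w > 1) {
    kern <- rep(1 / w, w)
    rate <- as.numeric(stats::filter(rate, kern, sides = 2))
    rate[is.na(rate)] <- 0
  }
  structure(list(t = edges[-length(edges)] + bin / 2, rate = rate,
                 fs = 1000 / bin, n = raster$n, bin = bin,
                 drive = raster$drive),
            class = "population_rate")
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Morlet continuous-wavelet scalogram of a rate signal
#'
#' Continuous wavelet transform with a Morlet wavelet of order
#' `omega0 = 5`. The per-frequency width (in samples) is
#' `s = omega0 * fs / (2 pi f)`; the wavelet is
#' `pi^(-1/4) sqrt(1/s) exp(i omega0 x/s) exp(-x^2/(2 s^2))` on a support
#' of `min(10 s, n)` samples, and the transform is the convolution of the
#' signal with the conjugate-reversed wavelet (computed by FFT). Power is
#' the squared modulus of the coefficients; no normalization is applied
#' across scales. The default frequency grid is 50 to 449 Hz in steps of
#' 3 Hz.
#'
#' @param rate a `population_rate`, or a numeric signal (then give `fs`)
#' @param fs sampling rate (Hz) when `rate` is a bare numeric vector
#' @param omega0 wavelet order, default 5
#' @param freqs analysis frequencies (Hz)
#' @return object of class `scalogram`: list with `t` (ms), `freqs` (Hz),
#'   `power` (n_freq x n_time), `fs`, `omega0`, `support_ms` (the longest
#'   wavelet half-support, for edge guards)
#' @export
wavelet_power <- function(rate, fs = NULL, omega0 = 5,
                          freqs = seq(50, 449, by = 3)) {
  if (inherits(rate, "population_rate")) {
    x <- rate$rate; fs <- rate$fs; tms <- rate$t; drv <- rate$drive
  } else {
    stopifnot(!is.null(fs))
    x <- as.numeric(rate); tms <- (seq_along(x) - 0.5) / fs * 1000
    drv <- NULL
  }
  n <- length(x)
  widths <- omega0 * fs / (2 * pi * freqs)
  if (10 * max(widths) > 2 * n)
    stop("signal shorter than the longest wavelet support")
  nf <- length(freqs)
  pow <- matrix(0, nf, n)
  for (k in seq_len(nf)) {
    s <- widths[k]
    M <- ceiling(min(10 * s, n))
    xx <- ((0:(M - 1)) - (M - 1) / 2) / s
    psi <- pi^(-0.25) * sqrt(1 / s) * exp(1i * omega0 * xx) * exp(-0.5 * xx^2)
    # convolution with conj(rev(psi)); Morlet is Hermitian so this is psi
    N2 <- next_pow2(n + M - 1)
    W <- fft(fft(c(x, rep(0, N2 - n))) *
               fft(c(Conj(rev(psi)), rep(0, N2 - M))), inverse = TRUE) / N2
    start <- (M - 1) %/% 2
    pow[k, ] <- Mod(W[(start + 1):(start + n)])^2
  }
  structure(list(t = tms, freqs = freqs, power = pow, fs = fs,
                 omega0 = omega0,
                 support_ms = 5 * max(widths) / fs * 1000, drive = drv),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d freqs (%g-%g Hz) x %d times; peak power %.3g\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$t),
              max(x$power)))
  invisible(x)
}

#' @export
plot.scalogram <- function(x, ...) {
  image(x$t, x$freqs, t(x$power), col = hcl.colors(64, "inferno"),
        xlab = "time (ms)", ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Per-theta-cycle metrics of the nested fast oscillation
#'
#' Splits the scalogram into theta cycles (cycle k spans
#' `[k, k+1] / theta_freq`), discards the first `discard_first` cycles as
#' transients and any cycle whose wavelet support would cross the
#' simulation boundary (cone-of-influence guard), then reports per retained
#' cycle the maximum wavelet power, the dominant fast frequency at that
#' maximum, and the theta phases at which the power envelope crosses the
#' retention threshold from below (onset) and from above (offset).
#' The threshold is `threshold_frac` times the maximum power across the
#' run's analyzable cycles (or `threshold_power` if supplied, e.g. a shared
#' reference across conditions); cycles never exceeding it are flagged
#' `included = FALSE` and carry NA phases.
#'
#' @param scal a `scalogram` (of a theta-driven run)
#' @param theta_freq theta frequency (Hz); taken from the drive if present
#' @param threshold_frac retention threshold as a fraction of maximum power
#' @param discard_first cycles discarded at the start, default 4
#' @param threshold_power optional absolute threshold override
#' @return data.frame of class `cycle_metrics`: `cycle`, `t_start`,
#'   `dominant_freq`, `max_power`, `onset_phase`, `offset_phase`,
#'   `included`; attributes `threshold` and `theta_freq`
#' @export
cycle_metrics <- function(scal, theta_freq = NULL, threshold_frac = 0.3,
                          discard_first = 4, threshold_power = NULL) {
  stopifnot(inherits(scal, "scalogram"))
  if (is.null(theta_freq)) {
    if (is.null(scal$drive) || scal$drive$theta_freq <= 0)
      stop("theta_freq not given and not available from the drive")
    theta_freq <- scal$drive$theta_freq
  }
  T_cyc <- 1000 / theta_freq
  t_end <- max(scal$t)
  n_cyc <- floor(t_end / T_cyc)
  if (n_cyc < discard_first + 1)
    stop("simulation covers too few theta cycles")
  env <- apply(scal$power, 2, max)
  cand <- (discard_first:(n_cyc - 1))
  # cone-of-influence guard at both ends
  cand <- cand[cand * T_cyc >= scal$support_ms &
                 (cand + 1) * T_cyc + scal$support_ms <= t_end + 1e-9]
  if (!length(cand)) stop("no analyzable theta cycles after edge guards")
  rows <- lapply(cand, function(k) {
    sel <- scal$t >= k * T_cyc & scal$t < (k + 1) * T_cyc
    pw <- scal$power[, sel, drop = FALSE]
    imax <- arrayInd(which.max(pw), dim(pw))
    data.frame(cycle = k, t_start = k * T_cyc,
               dominant_freq = scal$freqs[imax[1]],
               max_power = max(pw))
  })
  out <- do.call(rbind, rows)
  thr <- if (is.null(threshold_power)) threshold_frac * max(out$max_power)
         else threshold_power
  out$included <- out$max_power > thr
  out$onset_phase <- out$offset_phase <- NA_real_
  for (r in seq_len(nrow(out))) {
    if (!out$included[r]) next
    k <- out$cycle[r]
    sel <- which(scal$t >= k * T_cyc & scal$t < (k + 1) * T_cyc)
    e <- env[sel]; tt <- scal$t[sel]
    above <- e > thr
    up <- which(diff(c(FALSE, above)) == 1)
    down <- which(diff(c(above, FALSE)) == -1)
    if (length(up) && length(down)) {
      out$onset_phase[r] <- theta_phase(tt[up[1]], freq = theta_freq)
      out$offset_phase[r] <- theta_phase(tt[down[length(down)]],
                                         freq = theta_freq)
    }
  }
  structure(out, class = c("cycle_metrics", "data.frame"),
            threshold = thr, theta_freq = theta_freq)
}

#' Circular mean and standard deviation
#'
#' The circular mean is the argument of the mean resultant vector; the
#' circular standard deviation is `sqrt(-2 log Rbar)` with `Rbar` the mean
#' resultant length. For a zero resultant (e.g. uniform phases) the mean is
#' undefined and NA is returned.
#'
#' @param phases angles (rad)
#' @return `circular_mean()`/`circular_sd()`: scalar;
#'   `circular_summary()`: list with `mean`, `sd`, `R`, `n`
#' @export
circular_mean <- function(phases) {
  stopifnot(length(phases) > 0)
  z <- mean(exp(1i * phases))
  if (Mod(z) < 1e-12) return(NA_real_)
  Arg(z)
}

#' @rdname circular_mean
#' @export
circular_sd <- function(phases) {
  stopifnot(length(phases) > 0)
  R <- Mod(mean(exp(1i * phases)))
  if (R < 1e-12) return(Inf)
  sqrt(-2 * log(R))
}

#' @rdname circular_mean
#' @export
circular_summary <- function(phases) {
  list(mean = circular_mean(phases), sd = circular_sd(phases),
       R = Mod(mean(exp(1i * phases))), n = length(phases))
}

#' Ensemble statistics over runs
#'
#' Pools the retained cycles of one or more [cycle_metrics()] tables and
#' reports dominant-frequency and maximum-power statistics per run and
#' across runs.
#'
#' @param runs a `cycle_metrics` data.frame or a list of them
#' @return list with `per_run` (data.frame) and `pooled` (list)
#' @export
ensemble_metrics <- function(runs) {
  if (inherits(runs, "cycle_metrics")) runs <- list(runs)
  per <- do.call(rbind, lapply(seq_along(runs), function(i) {
    cm <- runs[[i]]
    inc <- cm[cm$included, , drop = FALSE]
    data.frame(run = i, n_retained = nrow(inc),
               freq_mean = if (nrow(inc)) mean(inc$dominant_freq) else NA_real_,
               freq_sd = if (nrow(inc) > 1) sd(inc$dominant_freq) else 0,
               power_mean = if (nrow(inc)) mean(inc$max_power) else NA_real_,
               power_sd = if (nrow(inc) > 1) sd(inc$max_power) else 0)
  }))
  allinc <- do.call(rbind, lapply(runs, function(cm) cm[cm$included, , drop = FALSE]))
  pooled <- list(n_retained = if (is.null(allinc)) 0L else nrow(allinc),
                 freq_mean = if (!is.null(allinc) && nrow(allinc)) mean(allinc$dominant_freq) else NA_real_,
                 freq_sd = if (!is.null(allinc) && nrow(allinc) > 1) sd(allinc$dominant_freq) else NA_real_,
                 power_mean = if (!is.null(allinc) && nrow(allinc)) mean(allinc$max_power) else NA_real_)
  list(per_run = per, pooled = pooled)
}
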
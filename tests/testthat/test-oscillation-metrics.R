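make_raster <- function(spikes, n, duration, dt = 0.01) {
  structure(list(spikes = spikes, n = n, duration = duration, dt = dt,
                 traces = NULL, drive = drive_theta(14, 8)),
            class = "spike_raster")
}

test_that("population rate conserves the spike count and handles edge cases", {
  # empty raster -> identically zero
  r0 <- make_raster(rep(list(numeric(0)), 5), 5, 100)
  pr0 <- population_rate(r0)
  expect_true(all(pr0$rate == 0))
  # 100 neurons spiking once at t = 10 ms -> one bin at 10,000 spikes/s/neuron
  r1 <- make_raster(rep(list(10.0001), 100), 100, 50)
  pr1 <- population_rate(r1)
  expect_equal(max(pr1$rate), 100 / (100 * 1e-4))
  expect_equal(sum(pr1$rate > 0), 1)
  # integral conservation on a random raster
  set.seed(11)
  sp <- lapply(1:40, function(i) sort(runif(rpois(1, 30), 0, 200)))
  r2 <- make_raster(sp, 40, 200)
  pr2 <- population_rate(r2)
  expect_equal(sum(pr2$rate) * 40 * 1e-4, sum(lengths(sp)), tolerance = 1e-9)
  # conservation also under a wider smoothing window
  pr3 <- population_rate(r2, smooth_width = 0.5)
  expect_equal(sum(pr3$rate) * 40 * 1e-4, sum(lengths(sp)), tolerance = 1e-3)
})

test_that("Morlet scalogram localizes a 200 Hz component and rejects DC", {
  fs <- 10000
  tt <- (0:8191) / fs
  x200 <- 50 + 20 * sin(2 * pi * 200 * tt)
  sc <- wavelet_power(x200, fs = fs)
  expect_equal(sc$freqs, seq(50, 449, by = 3))
  mid <- 2000:6000   # away from edges
  peak_f <- sc$freqs[apply(sc$power[, mid], 2, which.max)]
  expect_true(all(abs(peak_f - 200) <= 3))
  peak_power <- max(sc$power[, mid])
  # constant signal: residual response below 1% of the oscillatory peak
  sc_dc <- wavelet_power(rep(50, 8192), fs = fs)
  expect_lt(max(sc_dc$power[, mid]), 0.01 * peak_power)
  # power is invariant to a DC offset within that tolerance
  sc_off <- wavelet_power(x200 + 200, fs = fs)
  expect_equal(max(sc_off$power[, mid]), peak_power, tolerance = 0.02)
  expect_error(wavelet_power(rep(1, 100), fs = fs), "support")
})

test_that("FFT-based wavelet coefficients equal a direct correlation", {
  set.seed(5)
  fs <- 10000
  x <- rnorm(3000) + sin(2 * pi * 150 * (1:3000) / fs)
  f0 <- 150
  sc <- wavelet_power(x, fs = fs, freqs = f0)
  s <- 5 * fs / (2 * pi * f0)
  M <- ceiling(min(10 * s, length(x)))
  xx <- ((0:(M - 1)) - (M - 1) / 2) / s
  psi <- pi^(-0.25) * sqrt(1 / s) * exp(1i * 5 * xx) * exp(-0.5 * xx^2)
  start <- (M - 1) %/% 2
  for (tc in c(700, 1500, 2300)) {
    # direct evaluation of the 'same'-mode convolution with conj(rev(psi))
    m <- seq_len(M)
    j <- tc + 1 + start - m + 1        # signal indices, 1-based
    keep <- j >= 1 & j <= length(x)
    w <- sum(x[j[keep]] * Conj(rev(psi))[m[keep]])
    expect_equal(sc$power[1, tc + 1], Mod(w)^2, tolerance = 1e-6)
  }
})

test_that("cycle metrics find onset before offset with a constructed power blob", {
  # synthetic rate: fast oscillation burst placed before each theta peak
  fs <- 10000; f_theta <- 8; T <- 1000 / f_theta
  tt <- seq(0, 1625 - 1e-4, by = 0.1)
  phase <- theta_phase(tt, freq = f_theta)
  envelope <- exp(-((phase + 1.5)^2) / (2 * 0.25^2))   # centered at -1.5 rad
  x <- 100 + 80 * envelope * sin(2 * pi * 180 * tt / 1000)
  pr <- structure(list(t = tt, rate = x, fs = fs, n = 100, bin = 0.1,
                       drive = drive_theta(14, f_theta)),
                  class = "population_rate")
  sc <- wavelet_power(pr)
  cm <- cycle_metrics(sc, f_theta)
  inc <- cm[cm$included, ]
  expect_gt(nrow(inc), 3)
  expect_true(all(abs(inc$dominant_freq - 180) <= 3))
  expect_true(all(inc$onset_phase < inc$offset_phase))
  expect_true(all(inc$onset_phase < -1.5 & inc$offset_phase > -1.5))
  expect_true(all(inc$offset_phase < 0))   # burst sits before the peak
  expect_true(all(inc$onset_phase > -pi & inc$onset_phase <= pi))
})

test_that("circular statistics wrap correctly and are rotation-equivariant", {
  expect_equal(circular_mean(rep(-1, 5)), -1)
  expect_equal(circular_sd(rep(-1, 5)), 0)
  m <- circular_mean(c(pi - 0.1, -pi + 0.1))
  expect_equal(abs(m), pi, tolerance = 1e-9)   # wraps to +-pi, not 0
  set.seed(8)
  ph <- rnorm(200, 1, 0.4)
  for (rot in c(0.5, 2, -3)) {
    wrapped <- ((ph + rot + pi) %% (2 * pi)) - pi
    dm <- circular_mean(wrapped) - circular_mean(ph)
    expect_equal(((dm - rot + pi) %% (2 * pi)) - pi, 0, tolerance = 1e-9)
    expect_equal(circular_sd(wrapped), circular_sd(ph), tolerance = 1e-9)
  }
  # circular SD is sqrt(-2 log R)
  R <- Mod(mean(exp(1i * ph)))
  expect_equal(circular_sd(ph), sqrt(-2 * log(R)))
  expect_true(is.na(circular_mean(c(0, pi))))
})

test_that("ensemble metrics degenerate correctly for a single retained cycle", {
  cm <- structure(data.frame(cycle = 4, t_start = 500, dominant_freq = 180,
                             max_power = 3, included = TRUE,
                             onset_phase = -2, offset_phase = -1),
                  class = c("cycle_metrics", "data.frame"))
  em <- ensemble_metrics(cm)
  expect_equal(em$per_run$freq_sd, 0)
  expect_equal(em$pooled$freq_mean, 180)
})
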
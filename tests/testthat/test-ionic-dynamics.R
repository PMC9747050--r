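test_that("gate rates match the printed forms, including singular limits", {
  kin <- default_kinetics()
  # removable singularity at V = theta: alpha = k1 * sigma1
  expect_equal(gate_rates(-53, kin$m)$alpha, 0.25 * 4)
  # exp(0) = 1
  expect_equal(gate_rates(0, kin$n)$beta, 0.001)
  # independent arithmetic evaluation away from the singularity
  expect_equal(gate_rates(-60, kin$m)$alpha, 0.25 * 7 / (exp(7 / 4) - 1),
               tolerance = 1e-12)
  expect_equal(gate_rates(-60, kin$m)$beta, 0.1 * exp(-60 / -13))
  # continuity across the singularity
  eps <- 1e-6
  expect_equal(gate_rates(-53 + eps, kin$m)$alpha,
               gate_rates(-53 - eps, kin$m)$alpha, tolerance = 1e-4)
  expect_error(gate_rates(NaN, kin$m), "non-finite")
})

test_that("h-gate rates give an inactivation gate: high at rest, low at peak", {
  kin <- default_kinetics()$h
  ss_rest <- gate_steady_state(-72, kin)
  ss_spike <- gate_steady_state(10, kin)
  expect_gt(ss_rest$x_inf, 0.85)
  expect_lt(ss_spike$x_inf, 0.05)
  # inactivation midpoint sits near theta_h (within a few mV)
  mid <- uniroot(function(v) gate_steady_state(v, kin)$x_inf - 0.5,
                 c(-75, -40))$root
  expect_lt(abs(mid - kin$theta), 7)
})

test_that("state derivatives vanish at rest and match a hand summation", {
  nrn <- reference_neuron()
  vr <- resting_potential(nrn)
  d <- state_derivatives(steady_state(nrn, vr), nrn, 0)
  expect_lt(max(abs(d)), 1e-3)
  # arbitrary fixed state: dV/dt equals the independently summed currents
  s <- c(-40, 0.3, 0.5, 0.2, 0.1)
  I_hand <- nrn$g_Na * 0.3^3 * 0.5 * (50 - -40) +
    nrn$g_Kv1 * 0.1^4 * (-90 - -40) +
    nrn$g_Kv3 * 0.2^4 * (-90 - -40) +
    nrn$g_L * (nrn$E_L - -40) + 120
  expect_equal(unname(state_derivatives(s, nrn, 120)[1]), I_hand / nrn$C_M,
               tolerance = 1e-12)
})

test_that("two gap-coupled identical neurons exchange exactly opposite currents", {
  nrn <- reference_neuron()
  V1 <- -60; V2 <- -45; g <- 1.2
  I12 <- g * (V2 - V1)   # current into neuron 1
  I21 <- g * (V1 - V2)
  expect_equal(I12 + I21, 0)
  d1 <- state_derivatives(steady_state(nrn, V1), nrn, I12)[1]
  d0 <- state_derivatives(steady_state(nrn, V1), nrn, 0)[1]
  expect_equal(unname(d1 - d0), I12 / nrn$C_M)
})

test_that("reference neuron fires near 168 Hz with a 5.97 ms period at 7 nS", {
  nrn <- reference_neuron()
  sim <- simulate_neuron(nrn, drive_constant(7), 300)
  rate <- sum(sim$spikes > 100) / 0.2
  expect_equal(rate, 168, tolerance = 0.02)
  expect_equal(free_running_period(nrn, 7), 5.97, tolerance = 0.02)
  # quiescent without drive
  sim0 <- simulate_neuron(nrn, drive_constant(0), 200)
  expect_length(sim0$spikes, 0)
  expect_equal(tail(sim0$V, 1), resting_potential(nrn), tolerance = 0.1)
})

test_that("gating variables stay in [0, 1] along a 1 s trace", {
  sim <- simulate_neuron(reference_neuron(), drive_constant(7), 1000,
                         record = "state")
  gates <- sim$states[, c("m", "h", "n", "a")]
  expect_gte(min(gates), 0)
  expect_lte(max(gates), 1)
})

test_that("Euler and RK4 agree, and halving dt moves the rate by < 1 Hz", {
  nrn <- reference_neuron()
  p_eu <- free_running_period(nrn, 7, dt = 0.01)
  p_rk <- free_running_period(nrn, 7, dt = 0.01)
  sim_rk <- simulate_neuron(nrn, drive_constant(7), 300, method = "rk4")
  p_rk <- mean(tail(diff(sim_rk$spikes), 10))
  expect_equal(p_eu, p_rk, tolerance = 0.01)
  r1 <- 1000 / free_running_period(nrn, 7, dt = 0.01)
  r2 <- 1000 / free_running_period(nrn, 7, dt = 0.005)
  expect_lt(abs(r1 - r2), 1)
})

test_that("numerical blow-up raises a diagnostic naming the step", {
  # an extreme non-inactivating sodium load destabilizes Euler at dt = 0.01
  bad <- fs_neuron(C_M = 76.8, g_L = 14.7, E_L = -72, g_Na = 60000,
                   g_Kv1 = 59, g_Kv3 = 100, theta = c(h = 50))
  expect_error(simulate_neuron(bad, drive_current(800), 100), "step")
  flagged <- simulate_neuron(bad, drive_current(800), 100, blowup = "flag")
  expect_true(flagged$blown)
})

test_that("spike features recover constructed and physiological values", {
  sim <- simulate_neuron(reference_neuron(), drive_current(400), 300)
  ft <- spike_features(sim)
  ft <- ft[ft$time > 150, ]
  expect_gt(nrow(ft), 10)
  expect_equal(median(ft$amplitude_mV), 40, tolerance = 0.25)
  expect_equal(median(ft$half_width_ms), 0.3, tolerance = 0.55)
  expect_equal(median(ft$ahp_depth_mV), 20, tolerance = 0.3)
  # flat trace: no spikes, empty result (not an error)
  quiet <- simulate_neuron(reference_neuron(), drive_constant(0), 50)
  expect_identical(nrow(spike_features(quiet)), 0L)
})

test_that("f-I curve shows type-2 excitability with a grid-consistent rheobase", {
  nrn <- reference_neuron()
  fi <- fI_curve(nrn, 0, 500, step = 25)
  expect_false(fi$sustained[fi$I_pA == 0])
  rheo <- attr(fi, "rheobase")
  cutoff <- attr(fi, "cutoff")
  expect_gt(cutoff, 0)            # abrupt onset, no arbitrarily slow firing
  expect_gt(cutoff, 40)
  # bisection-style refinement agrees with the grid rheobase
  rs <- ingsim:::rheobase_search(nrn, step = 25)
  expect_equal(rs$rheobase, rheo)
  expect_equal(rs$cutoff, cutoff, tolerance = 1e-6)
})
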
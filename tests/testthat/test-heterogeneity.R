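test_that("candidate sampling crosses 100 x 100 draws inside the stated ranges", {
  cand <- sample_candidates(seed = 1)
  expect_equal(nrow(cand), 10000)
  expect_true(all(cand$tau_m >= 3 & cand$tau_m <= 7))
  expect_true(all(cand$R_input >= 50 & cand$R_input <= 150))
  expect_true(all(cand$E_L >= -80 & cand$E_L <= -60))
  expect_true(all(cand$g_Na >= 6000 & cand$g_Na <= 35000))
  expect_true(all(cand$g_Kv1 >= 15 & cand$g_Kv1 <= 150))
  expect_true(all(cand$kv3_na_ratio >= 0.03 & cand$kv3_na_ratio <= 0.05))
  expect_true(all(cand$theta_h >= -60 & cand$theta_h <= -50))
  expect_equal(cand$g_Kv3, cand$kv3_na_ratio * cand$g_Na)
  expect_equal(cand$g_L, 1000 / cand$R_input)
  # worked example: tau 5.45 ms, R 83.55 MOhm -> C_M 65.2 pF
  expect_equal(5.45 / 83.55 * 1000, 65.2, tolerance = 0.001)
  # determinism
  expect_identical(sample_candidates(seed = 7), sample_candidates(seed = 7))
  expect_false(identical(sample_candidates(seed = 7)$g_Na[1],
                         sample_candidates(seed = 8)$g_Na[1]))
})

test_that("impossible criteria fail with a diagnostic histogram of causes", {
  cand <- sample_candidates(n_passive = 4, n_active = 4, seed = 2)
  crit <- selection_criteria(amplitude_band = c(0, 0))
  expect_error(select_population(cand, crit, n = 5, seed = 1),
               "0 of the screened candidates.*amplitude")
})

test_that("selected population is calibrated, in-range and seed-deterministic", {
  pop <- het_population()
  expect_equal(nrow(pop), 100)
  crit <- attr(pop, "criteria")
  expect_true(all(pop$amplitude >= crit$amplitude_band[1] &
                    pop$amplitude <= crit$amplitude_band[2]))
  expect_true(all(pop$half_width >= crit$half_width_band[1] &
                    pop$half_width <= crit$half_width_band[2]))
  expect_true(all(pop$ahp >= crit$ahp_band[1] & pop$ahp <= crit$ahp_band[2]))
  expect_true(all(pop$cutoff > 0))            # type-2 excitability throughout
  expect_true(all(pop$tau_m >= 3 & pop$tau_m <= 7))
  expect_true(all(pop$R_input >= 50 & pop$R_input <= 150))
  # re-measuring a selected neuron reproduces the stored screen values
  i <- 7
  rs <- ingsim:::rheobase_search(row_to_neuron(pop[i, , drop = FALSE]))
  expect_equal(rs$rheobase, pop$rheobase[i])
})

test_that("some sampled candidates spike once then fall silent below rheobase", {
  # large-g_Kv1 cells can emit spikes without sustaining repetitive firing
  cand <- sample_candidates(seed = 1)
  big <- cand[order(-cand$g_Kv1), ][1:120, ]
  found <- FALSE
  for (k in seq_len(nrow(big))) {
    nrn <- row_to_neuron(big[k, , drop = FALSE])
    rs <- ingsim:::rheobase_search(nrn, step_dur = 400)
    if (is.na(rs$rheobase)) next
    sim <- simulate_neuron(nrn, drive_current(rs$rheobase - 25), 400,
                           record = "spikes", blowup = "flag")
    if (!sim$blown && length(sim$spikes) >= 1 &&
        !ingsim:::sustained_firing(sim$spikes, 400)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("cloned populations are bit-identical and behave identically", {
  cl <- clone_population(reference_neuron(), 10)
  expect_equal(nrow(unique(cl)), 1)
  chem0 <- build_chemical_connectivity(10, "homogeneous", seed = 1,
                                       in_degree = 3, g_syn = 0)
  spec <- network_spec(cl, chem0, NULL, drive_constant(7), std = FALSE)
  ini <- init_states(spec, "rest")
  r <- run_network(spec, 100, init = ini)
  for (i in 2:10) expect_equal(r$spikes[[i]], r$spikes[[1]])
})

test_that("gap compensation preserves input resistance, rest and the leak floor", {
  pop <- het_population()
  gaps <- build_gap_connectivity(100, seed = 7)
  comp <- apply_gap_compensation(pop, gaps)
  expect_true(all(comp$population$g_L >= 1.5))
  gsum <- vapply(seq_len(100), function(i)
    sum(comp$gaps$g_gap[comp$gaps$i == i | comp$gaps$j == i]), numeric(1))
  # 1/(g_L' + sum g_gap) equals the pre-compensation R_input (5% stated bound)
  R_new <- 1000 / (comp$population$g_L + gsum)
  expect_true(all(abs(R_new - pop$R_input) / pop$R_input < 0.05))
  # resting potential preserved on the most heavily compensated neuron
  i <- which.max(pop$g_L - comp$population$g_L)
  v0 <- resting_potential(row_to_neuron(pop[i, , drop = FALSE]))
  v1 <- resting_potential(row_to_neuron(comp$population[i, , drop = FALSE]))
  expect_equal(v1, v0, tolerance = 0.01)
  expect_equal(comp$population$C_M, pop$C_M)
  # empty gap list is a no-op
  none <- apply_gap_compensation(pop, gaps[0, , drop = FALSE])
  expect_identical(none$population, pop)
})

test_that("f-I curves barely move when compensated gap junctions are added", {
  pop <- het_population()
  gaps <- build_gap_connectivity(100, seed = 7)
  comp <- apply_gap_compensation(pop, gaps)
  no_chem <- data.frame(pre = integer(0), post = integer(0),
                        g_syn = numeric(0), delay = numeric(0))
  spec <- network_spec(comp$population, no_chem, comp$gaps,
                       drive_constant(0), std = FALSE)
  # current steps injected into one neuron of the gap-coupled network,
  # compared with the same neuron before compensation in isolation
  for (i in c(3, 30)) {
    n0 <- row_to_neuron(pop[i, , drop = FALSE])
    for (I in pop$rheobase[i] + c(100, 300)) {
      s0 <- simulate_neuron(n0, drive_current(I), 400, record = "spikes")
      f0 <- ingsim:::steady_frequency(s0$spikes, 400)
      Ivec <- rep(0, 100); Ivec[i] <- I
      r1 <- run_network(spec, 400, init = "rest", I_app = Ivec)
      f1 <- ingsim:::steady_frequency(r1$spikes[[i]], 400)
      expect_lt(abs(f1 - f0) / f0, 0.10)
    }
  }
})
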
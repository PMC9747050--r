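# Expensive shared fixtures, built once per test session.
fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

# calibrated heterogeneous population (seed 1); ~1.5 min, reused across files
het_population <- function() {
  memo("pop", select_population(sample_candidates(seed = 1), seed = 1))
}

ref_prc <- function(E_syn) {
  memo(paste0("prc", E_syn),
       compute_prc(reference_neuron(), g_const = 7, E_syn = E_syn))
}

# one theta-driven heterogeneous condition at reduced scale
theta_condition <- function(E_syn, gap_mode, std, dt, seed = 1, n_cycles = 8) {
  key <- paste("cond", E_syn, gap_mode, std, dt, seed, n_cycles)
  memo(key, {
    pop <- het_population()
    chem <- build_chemical_connectivity(100, "heterogeneous", seed = seed)
    gaps <- NULL
    if (gap_mode == "calibrated") {
      g0 <- build_gap_connectivity(100, seed = seed + 500000L)
      cc <- apply_gap_compensation(pop, g0)
      pop <- cc$population; gaps <- cc$gaps
    } else if (gap_mode == "strong") {
      gaps <- build_gap_connectivity(100, seed = seed + 500000L)
      gaps$g_gap <- 2.0
    }
    spec <- network_spec(pop, chem, gaps, drive_theta(14, 8),
                         E_syn = E_syn, std = std)
    raster <- run_network(spec, (4 + n_cycles + 1) * 125, dt = dt,
                          init = "rest")
    wavelet_power(population_rate(raster))
  })
}
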
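#' Experiment configuration
#'
#' Declarative description of one simulation experiment, mirroring the
#' study's figure panels: homogeneous or heterogeneous populations, chemical
#' synapses with hyperpolarizing (-75 mV) or shunting (-55 mV) reversal,
#' gap-junction mode, short-term depression, delay mode and drive. Reduced
#' default scale (3 network instantiations x 8 retained theta cycles) keeps
#' desk runs short; production scale is 30 x 30.
#'
#' @param id experiment identifier, one of [experiment_ids()]
#' @param E_syn synaptic reversal (mV); per-id default
#' @param gap_mode `"none"`, `"calibrated"` (with leak compensation) or
#'   `"strong_2nS_uncompensated"`
#' @param std enable short-term depression
#' @param delay_mode `"uniform"` (0.6-1.0 ms) or a fixed numeric delay (ms)
#' @param drive a drive descriptor
#' @param n_networks network instantiations
#' @param n_cycles retained theta cycles per run (after the 4 discarded)
#' @param dt integration step (ms); per-id default (finer with gap junctions)
#' @param g_L_min leak floor (nS) for calibrated-gap compensation (the `s5`
#'   sensitivity sweep varies it)
#' @param seed RNG seed (mandatory)
#' @param compensate logical; requesting compensation of the strong 2 nS
#'   gap junctions is refused, since the leak cannot absorb them while
#'   keeping input resistance in the physiological range
#' @return list of class `experiment_config`
#' @export
experiment_config <- function(id, seed = 1, E_syn = NULL, gap_mode = NULL,
                              std = NULL, delay_mode = NULL, drive = NULL,
                              n_networks = 3, n_cycles = 8, dt = NULL,
                              g_L_min = 1.5, compensate = NULL) {
  id <- match.arg(id, experiment_ids())
  d <- experiment_defaults(id)
  cfg <- list(id = id, seed = seed,
              E_syn = if (is.null(E_syn)) d$E_syn else E_syn,
              gap_mode = if (is.null(gap_mode)) d$gap_mode else gap_mode,
              std = if (is.null(std)) d$std else std,
              delay_mode = if (is.null(delay_mode)) d$delay_mode else delay_mode,
              drive = if (is.null(drive)) d$drive else drive,
              population = d$population, init = d$init,
              n_networks = n_networks, n_cycles = n_cycles,
              g_L_min = g_L_min,
              dt = if (is.null(dt)) d$dt else dt)
  cfg$gap_mode <- match.arg(cfg$gap_mode,
                            c("none", "calibrated", "strong_2nS_uncompensated"))
  if (cfg$gap_mode == "strong_2nS_uncompensated" && isTRUE(compensate))
    stop(paste("cannot compensate 2 nS gap junctions: subtracting them from",
               "the leak would leave input resistances outside the",
               "experimentally constrained range"))
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @export
experiment_ids <- function() {
  c("fig3a1", "fig3b1", "fig3a2", "fig3b2", "fig3a3", "fig3b3",
    "fig4b", "fig5b", "fig5c",
    "fig6a1", "fig6b1", "fig6a2", "fig6b2", "fig6a3", "fig6b3",
    "fig7", "fig8", "fig9", "s2", "s3", "s4", "s5")
}

experiment_defaults <- function(id) {
  hyper <- -75; shunt <- -55
  base <- list(E_syn = hyper, gap_mode = "none", std = TRUE,
               delay_mode = "uniform", drive = drive_theta(14, 8),
               population = "heterogeneous", init = "rest", dt = 0.01)
  ov <- switch(id,
    fig3a1 = list(population = "homogeneous", delay_mode = 0.8),
    fig3b1 = list(population = "homogeneous", delay_mode = 0.8, E_syn = shunt),
    fig3a2 = list(population = "het_intrinsic", delay_mode = 0.8),
    fig3b2 = list(population = "het_intrinsic", delay_mode = 0.8, E_syn = shunt),
    fig3a3 = list(population = "homogeneous_hetsyn"),
    fig3b3 = list(population = "homogeneous_hetsyn", E_syn = shunt),
    fig4b = list(population = "homogeneous", delay_mode = 0.8, std = FALSE,
                 drive = drive_constant(7), init = "random"),
    fig5b = list(population = "homogeneous", delay_mode = 0.8, std = FALSE,
                 E_syn = shunt, drive = drive_constant(7), init = "offset_one"),
    fig5c = list(population = "homogeneous", delay_mode = 1.6, std = FALSE,
                 E_syn = shunt, drive = drive_constant(7), init = "random"),
    fig6a1 = list(), fig6b1 = list(E_syn = shunt),
    fig6a2 = list(gap_mode = "calibrated", dt = 2e-3),
    fig6b2 = list(gap_mode = "calibrated", dt = 2e-3, E_syn = shunt),
    fig6a3 = list(gap_mode = "strong_2nS_uncompensated", dt = 2e-3),
    fig6b3 = list(gap_mode = "strong_2nS_uncompensated", dt = 2e-3,
                  E_syn = shunt),
    fig7 = list(gap_mode = "calibrated", dt = 2e-3),
    fig8 = list(gap_mode = "calibrated", dt = 2e-3),
    fig9 = list(gap_mode = "calibrated", dt = 2e-3),
    s2 = list(gap_mode = "calibrated"),
    s3 = list(gap_mode = "calibrated", dt = 2e-3, delay_mode = 1.6),
    s4 = list(gap_mode = "strong_2nS_uncompensated", dt = 2e-3,
              E_syn = shunt),
    s5 = list(gap_mode = "calibrated", dt = 2e-3),
    stop("unknown experiment id"))
  base[names(ov)] <- ov
  base
}

resolve_population <- function(cfg, population) {
  n <- 100
  switch(cfg$population,
    homogeneous = , homogeneous_hetsyn = clone_population(reference_neuron(), n),
    het_intrinsic = , heterogeneous = {
      if (is.null(population))
        population <- select_population(sample_candidates(seed = cfg$seed),
                                        seed = cfg$seed)
      population
    })
}

build_coupling <- function(cfg, pop, net_seed) {
  n <- nrow(pop)
  chem_mode <- if (cfg$population %in% c("homogeneous", "het_intrinsic"))
    "homogeneous" else "heterogeneous"
  delay_fixed <- is.numeric(cfg$delay_mode)
  chem <- if (chem_mode == "homogeneous") {
    build_chemical_connectivity(n, "homogeneous", seed = net_seed,
                                delay = if (delay_fixed) cfg$delay_mode else 0.8)
  } else {
    ch <- build_chemical_connectivity(n, "heterogeneous", seed = net_seed)
    if (delay_fixed) ch$delay <- cfg$delay_mode
    ch
  }
  gaps <- NULL
  if (cfg$gap_mode == "calibrated") {
    g0 <- build_gap_connectivity(n, seed = net_seed + 500000L)
    comp <- apply_gap_compensation(pop, g0,
                                   g_L_min = if (is.null(cfg$g_L_min)) 1.5
                                             else cfg$g_L_min)
    pop <- comp$population; gaps <- comp$gaps
  } else if (cfg$gap_mode == "strong_2nS_uncompensated") {
    gaps <- build_gap_connectivity(n, seed = net_seed + 500000L)
    gaps$g_gap <- 2.0
  }
  if (cfg$id == "s4") chem$g_syn <- chem$g_syn * 5
  list(population = pop, chem = chem, gaps = gaps)
}

#' Run a configured experiment
#'
#' End-to-end driver: builds (or reuses) the population, instantiates the
#' coupling graphs per network, simulates, and analyzes. Theta-driven
#' experiments return per-network [cycle_metrics()] and pooled circular
#' statistics of onset/offset phases (with a power threshold shared across
#' the networks of the experiment, so that conditions can be compared);
#' constant-drive experiments return the synchrony verdict and population
#' frequency from [perturbation_experiment()]. `fig8` runs its condition
#' twice, with and without short-term depression.
#'
#' @param config an [experiment_config()]
#' @param population optional prebuilt heterogeneous `fs_population`
#'   (avoids rebuilding the calibrated population for every call)
#' @param keep_rasters keep the spike rasters in the result (memory)
#' @return list of class `experiment_result`
#' @export
run_experiment <- function(config, population = NULL, keep_rasters = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  if (cfg$id == "s2") {
    # f/I stability when calibrated gap junctions are added with compensation:
    # current steps into single neurons of the gap-coupled (otherwise silent)
    # network vs the uncompensated isolated cells
    pop <- resolve_population(cfg, population)
    cpl <- build_coupling(cfg, pop, net_seed = cfg$seed)
    no_chem <- data.frame(pre = integer(0), post = integer(0),
                          g_syn = numeric(0), delay = numeric(0))
    spec <- network_spec(cpl$population, no_chem, cpl$gaps,
                         drive_constant(0), std = FALSE)
    set.seed(cfg$seed)
    cells <- sort(sample.int(nrow(pop), min(5, nrow(pop))))
    rows <- list()
    for (i in cells) {
      for (dI in c(100, 300)) {
        I <- pop$rheobase[i] + dI
        f0 <- steady_frequency(simulate_neuron(
          row_to_neuron(pop[i, , drop = FALSE]), drive_current(I), 400,
          record = "spikes")$spikes, 400)
        Ivec <- rep(0, nrow(pop)); Ivec[i] <- I
        f1 <- steady_frequency(run_network(spec, 400, init = "rest",
                                           I_app = Ivec)$spikes[[i]], 400)
        rows[[length(rows) + 1]] <-
          data.frame(neuron = i, I_pA = I, freq_isolated = f0,
                     freq_with_gaps = f1,
                     rel_change = (f1 - f0) / f0)
      }
    }
    return(structure(list(config = cfg, fi_table = do.call(rbind, rows)),
                     class = "experiment_result"))
  }
  if (cfg$id == "fig9") {
    # summary battery: theta synchrony in the homogeneous network, loss under
    # full heterogeneity, rescue by calibrated gap junctions (hyperpolarizing),
    # and no rescue with shunting synapses
    sub <- function(id) run_experiment(
      experiment_config(id, seed = cfg$seed, n_networks = 1,
                        n_cycles = cfg$n_cycles),
      population = population)
    return(structure(list(config = cfg,
                          homogeneous = sub("fig3a1"),
                          heterogeneous = sub("fig6a1"),
                          gap_rescued = sub("fig6a2"),
                          shunting_gaps = sub("fig6b2")),
                     class = "experiment_result"))
  }
  if (cfg$id == "fig8") {
    on <- run_theta_condition(cfg, population, std = TRUE, keep_rasters)
    off <- run_theta_condition(cfg, population, std = FALSE, keep_rasters)
    return(structure(list(config = cfg, with_std = on, without_std = off),
                     class = "experiment_result"))
  }
  if (cfg$init %in% c("random", "offset_one") && cfg$drive$mode == "constant") {
    pop <- resolve_population(cfg, population)
    cpl <- build_coupling(cfg, pop, net_seed = cfg$seed)
    spec <- network_spec(cpl$population, cpl$chem, cpl$gaps, cfg$drive,
                         E_syn = cfg$E_syn, std = cfg$std)
    pe <- perturbation_experiment(spec, init = cfg$init, duration = 400,
                                  seed = cfg$seed, dt = cfg$dt)
    if (!keep_rasters) pe$raster <- NULL
    return(structure(list(config = cfg, verdict = pe), class = "experiment_result"))
  }
  structure(list(config = cfg,
                 condition = run_theta_condition(cfg, population, cfg$std,
                                                 keep_rasters)),
            class = "experiment_result")
}

run_theta_condition <- function(cfg, population, std, keep_rasters) {
  pop0 <- resolve_population(cfg, population)
  T_cyc <- 1000 / cfg$drive$theta_freq
  duration <- (4 + cfg$n_cycles + 1) * T_cyc
  runs <- vector("list", cfg$n_networks)
  for (k in seq_len(cfg$n_networks)) {
    net_seed <- cfg$seed + (k - 1L) * 1000L
    cpl <- build_coupling(cfg, pop0, net_seed)
    spec <- network_spec(cpl$population, cpl$chem, cpl$gaps, cfg$drive,
                         E_syn = cfg$E_syn, std = std)
    raster <- run_network(spec, duration, dt = cfg$dt, init = "rest")
    scal <- wavelet_power(population_rate(raster))
    runs[[k]] <- list(raster = if (keep_rasters) raster else NULL,
                      scalogram = scal)
  }
  # shared threshold across this condition's networks
  thr <- 0.3 * max(vapply(runs, function(r) max(r$scalogram$power), numeric(1)))
  metrics <- lapply(runs, function(r)
    cycle_metrics(r$scalogram, cfg$drive$theta_freq, threshold_power = thr))
  inc <- do.call(rbind, metrics)
  inc <- inc[inc$included & !is.na(inc$onset_phase), , drop = FALSE]
  list(runs = runs, metrics = metrics, threshold = thr,
       ensemble = ensemble_metrics(metrics),
       onset = if (nrow(inc)) circular_summary(inc$onset_phase) else NULL,
       offset = if (nrow(inc)) circular_summary(inc$offset_phase) else NULL)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s>\n", x$config$id))
  if (!is.null(x$verdict)) {
    v <- x$verdict
    cat(sprintf("  synchronized: %s | first sync %.1f ms | cycles to sync %s | freq %.1f Hz\n",
                v$synchronized, v$first_sync,
                format(v$cycles_to_sync), v$frequency))
  }
  if (!is.null(x$fi_table)) {
    cat(sprintf("  f/I with gaps intact: max |rel change| %.3f over %d probes\n",
                max(abs(x$fi_table$rel_change), na.rm = TRUE),
                nrow(x$fi_table)))
  }
  for (nm in intersect(c("homogeneous", "heterogeneous", "gap_rescued",
                         "shunting_gaps"), names(x))) {
    cc <- x[[nm]]$condition
    cat(sprintf("  [%s] retained %d | dominant %.1f Hz | power %.3g\n",
                nm, cc$ensemble$pooled$n_retained,
                cc$ensemble$pooled$freq_mean, cc$ensemble$pooled$power_mean))
  }
  for (nm in intersect(c("condition", "with_std", "without_std"), names(x))) {
    cc <- x[[nm]]
    cat(sprintf("  [%s] retained cycles %d | dominant freq %.1f Hz | max power %.3g\n",
                nm, cc$ensemble$pooled$n_retained,
                cc$ensemble$pooled$freq_mean, cc$ensemble$pooled$power_mean))
    if (!is.null(cc$onset))
      cat(sprintf("      onset %.2f+-%.2f rad | offset %.2f+-%.2f rad\n",
                  cc$onset$mean, cc$onset$sd, cc$offset$mean, cc$offset$sd))
  }
  invisible(x)
}

#' Miniature deterministic test networks
#'
#' Small (default 10-neuron) network specifications with known qualitative
#' outcomes, for fast checks: `sync` (clones with hyperpolarizing synapses
#' and a 0.8 ms delay; synchronizes), `hetero` (intrinsic heterogeneity;
#' fails the coincidence criterion), `rescued` (the heterogeneous network
#' plus strong gap junctions; synchrony restored). The compound inhibition
#' per neuron matches the full-size network's 36 x 1.65 nS.
#'
#' @param seed RNG seed
#' @param n network size (default 10)
#' @return named list of `network_spec` objects
#' @export
generate_fixtures <- function(seed = 1, n = 10) {
  ref <- reference_neuron()
  in_deg <- n %/% 2
  g_each <- 36 * 1.65 / in_deg
  clones <- clone_population(ref, n)
  chem <- build_chemical_connectivity(n, "homogeneous", seed = seed,
                                      in_degree = in_deg, g_syn = g_each,
                                      delay = 0.8)
  set.seed(seed + 1)
  het <- clones
  het$g_Na <- het$g_Na * runif(n, 0.8, 1.2)
  het$g_Kv3 <- het$kv3_na_ratio * het$g_Na
  het$E_L <- het$E_L + runif(n, -4, 4)
  het$theta_m <- het$theta_m + runif(n, -2, 2)
  gaps <- build_gap_connectivity(n, seed = seed + 2, n_candidates = 4)
  gaps$g_gap <- 2.0
  list(sync = network_spec(clones, chem, NULL, drive_constant(7),
                           E_syn = -75, std = FALSE),
       hetero = network_spec(het, chem, NULL, drive_constant(7),
                             E_syn = -75, std = FALSE),
       rescued = network_spec(het, chem, gaps, drive_constant(7),
                              E_syn = -75, std = FALSE))
}
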
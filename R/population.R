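#' Sample candidate parameter sets for the synthetic population
#'
#' Draws 100 passive parameter vectors (membrane time constant 3-7 ms, input
#' resistance 50-150 MOhm, leak reversal -80 to -60 mV, all uniform) and 100
#' active vectors (g_Na 6000-35000 nS, g_Kv1 15-150 nS, Kv3/Na ratio
#' 0.03-0.05, and the four gate half-points: theta_m -60..-45, theta_h
#' -60..-50, theta_n -15..25, theta_a 35..55 mV), then crosses every passive
#' set with every active set, giving 10,000 candidates. Derived quantities:
#' C_M = tau_m / R_input (ms/MOhm = nF, stored in pF), g_L = 1000 / R_input
#' nS, g_Kv3 = ratio * g_Na.
#'
#' @param n_passive,n_active numbers of passive and active draws (default 100
#'   each, i.e. 10,000 candidates)
#' @param seed RNG seed; the table is a pure function of it
#' @return data.frame of class `candidate_table`, one row per candidate
#' @export
sample_candidates <- function(n_passive = 100, n_active = 100, seed = 1) {
  set.seed(seed)
  passive <- data.frame(tau_m = runif(n_passive, 3, 7),
                        R_input = runif(n_passive, 50, 150),
                        E_L = runif(n_passive, -80, -60))
  active <- data.frame(g_Na = runif(n_active, 6000, 35000),
                       g_Kv1 = runif(n_active, 15, 150),
                       kv3_na_ratio = runif(n_active, 0.03, 0.05),
                       theta_m = runif(n_active, -60, -45),
                       theta_h = runif(n_active, -60, -50),
                       theta_n = runif(n_active, -15, 25),
                       theta_a = runif(n_active, 35, 55))
  idx <- expand.grid(p = seq_len(n_passive), a = seq_len(n_active))
  out <- cbind(passive[idx$p, , drop = FALSE], active[idx$a, , drop = FALSE])
  out$C_M <- out$tau_m / out$R_input * 1000   # pF
  out$g_L <- 1000 / out$R_input               # nS
  out$g_Kv3 <- out$kv3_na_ratio * out$g_Na
  rownames(out) <- NULL
  structure(out, class = c("candidate_table", "data.frame"), seed = seed)
}

#' Build an `fs_neuron` from one population-table row
#'
#' @param row a single row of a candidate or population table
#' @return an `fs_neuron`
#' @export
row_to_neuron <- function(row) {
  fs_neuron(C_M = row$C_M, g_L = row$g_L, E_L = row$E_L,
            g_Na = row$g_Na, g_Kv1 = row$g_Kv1, g_Kv3 = row$g_Kv3,
            theta = c(m = row$theta_m, h = row$theta_h,
                      n = row$theta_n, a = row$theta_a))
}

#' Physiological selection criteria
#'
#' Acceptance bands around the experimentally observed action-potential
#' features (amplitude ~40 mV above the -30 mV threshold, half-width
#' ~0.3 ms, AHP depth ~20 mV) and optional ranges for rheobase and cutoff
#' frequency.
#'
#' @param amplitude_band,half_width_band,ahp_band numeric length-2 bands
#' @param rheobase_range,cutoff_range optional length-2 ranges (pA, Hz)
#' @return list of class `selection_criteria`
#' @export
selection_criteria <- function(amplitude_band = c(30, 55),
                               half_width_band = c(0.15, 0.5),
                               ahp_band = c(10, 30),
                               rheobase_range = c(25, 2400),
                               cutoff_range = c(10, 250)) {
  stopifnot(diff(amplitude_band) >= 0, diff(half_width_band) >= 0,
            diff(ahp_band) >= 0)
  structure(list(amplitude_band = amplitude_band,
                 half_width_band = half_width_band, ahp_band = ahp_band,
                 rheobase_range = rheobase_range, cutoff_range = cutoff_range),
            class = "selection_criteria")
}

# Measure rheobase, cutoff and AP features of one candidate.
screen_candidate <- function(neuron, dt = 0.01, step_dur = 500) {
  rc <- rheobase_search(neuron, step_dur = step_dur, dt = dt)
  if (is.na(rc$rheobase))
    return(list(ok = FALSE, why = if (isTRUE(rc$blown)) "diverged" else "no_repetitive_firing"))
  sim <- simulate_neuron(neuron, drive_current(rc$rheobase + 100), 300,
                         dt = dt, record = "v", blowup = "flag")
  if (sim$blown) return(list(ok = FALSE, why = "diverged"))
  ft <- spike_features(sim)
  ft <- ft[ft$time > 150, , drop = FALSE]   # steady part of the step
  if (nrow(ft) < 2) return(list(ok = FALSE, why = "no_repetitive_firing"))
  list(ok = TRUE, rheobase = rc$rheobase, cutoff = rc$cutoff,
       amplitude = median(ft$amplitude_mV), half_width = median(ft$half_width_ms),
       ahp = median(ft$ahp_depth_mV))
}

passes_criteria <- function(sc, criteria) {
  in_band <- function(x, b) !is.na(x) && x >= b[1] && x <= b[2]
  if (!isTRUE(sc$ok)) return(sc$why)
  if (!in_band(sc$amplitude, criteria$amplitude_band)) return("amplitude")
  if (!in_band(sc$half_width, criteria$half_width_band)) return("half_width")
  if (!in_band(sc$ahp, criteria$ahp_band)) return("ahp")
  if (!in_band(sc$rheobase, criteria$rheobase_range)) return("rheobase")
  if (!in_band(sc$cutoff, criteria$cutoff_range)) return("cutoff")
  "pass"
}

#' Select a calibrated population from the candidate pool
#'
#' Screens candidates (in a seeded random order) against the physiological
#' acceptance bands, then picks `n` of the passing candidates by greedy
#' stratified sampling over a 10 x 10 grid of (cutoff frequency, rheobase)
#' bins, visiting non-empty bins round-robin. This maintains the approximate
#' spread of cutoff frequencies and rheobases across the selected set
#' without an unstated optimizer. Screening stops as soon as enough
#' candidates have passed (`n_pool` passers, default 1.5 n), so the whole
#' build is deterministic given the seed.
#'
#' @param candidates a `candidate_table` from [sample_candidates()]
#' @param criteria a [selection_criteria()] object
#' @param n population size (default 100)
#' @param seed RNG seed for the screening order and within-bin sampling
#' @param n_pool stop screening after this many passers (default `ceiling(1.5 n)`)
#' @param dt integration step for the screening simulations (ms)
#' @return data.frame of class `fs_population`: the selected parameter rows
#'   plus measured `rheobase`, `cutoff`, `amplitude`, `half_width`, `ahp`
#' @export
select_population <- function(candidates, criteria = selection_criteria(),
                              n = 100, seed = 1,
                              n_pool = ceiling(1.5 * n), dt = 0.01) {
  stopifnot(inherits(candidates, "data.frame"), n >= 1)
  set.seed(seed)
  order_idx <- sample.int(nrow(candidates))
  passers <- list()
  fail_count <- c(no_repetitive_firing = 0, diverged = 0, amplitude = 0,
                  half_width = 0, ahp = 0, rheobase = 0, cutoff = 0)
  for (ci in order_idx) {
    row <- candidates[ci, , drop = FALSE]
    sc <- screen_candidate(row_to_neuron(row), dt = dt)
    verdict <- passes_criteria(sc, criteria)
    if (verdict == "pass") {
      row$rheobase <- sc$rheobase; row$cutoff <- sc$cutoff
      row$amplitude <- sc$amplitude; row$half_width <- sc$half_width
      row$ahp <- sc$ahp
      passers[[length(passers) + 1]] <- row
      if (length(passers) >= n_pool) break
    } else {
      fail_count[verdict] <- fail_count[verdict] + 1
    }
  }
  if (length(passers) < n) {
    stop(sprintf(paste0("only %d of the screened candidates passed the ",
                        "selection criteria (need %d); failures: %s"),
                 length(passers), n,
                 paste(names(fail_count), fail_count, sep = "=", collapse = ", ")))
  }
  pool <- do.call(rbind, passers)
  # stratify over a 10x10 (cutoff, rheobase) grid
  bin10 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(rep(1L, length(x)))
    pmin(10L, 1L + as.integer(10 * (x - r[1]) / diff(r)))
  }
  bins <- paste(bin10(pool$cutoff), bin10(pool$rheobase))
  picked <- integer(0)
  remaining <- split(seq_len(nrow(pool)), bins)
  remaining <- lapply(remaining, sample)   # random order inside each bin
  while (length(picked) < n) {
    for (b in seq_along(remaining)) {
      if (length(remaining[[b]]) > 0 && length(picked) < n) {
        picked <- c(picked, remaining[[b]][1])
        remaining[[b]] <- remaining[[b]][-1]
      }
    }
  }
  out <- pool[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("fs_population", "data.frame"),
            seed = seed, criteria = criteria)
}

#' @export
print.fs_population <- function(x, ...) {
  cat(sprintf("<fs_population> %d neurons\n", nrow(x)))
  cat(sprintf("  rheobase %g-%g pA | cutoff %.0f-%.0f Hz | R_input %.0f-%.0f MOhm\n",
              min(x$rheobase), max(x$rheobase), min(x$cutoff), max(x$cutoff),
              min(x$R_input), max(x$R_input)))
  invisible(x)
}

#' Homogeneous population of clones
#'
#' @param neuron an `fs_neuron` to clone
#' @param n population size
#' @return an `fs_population` of `n` identical rows
#' @export
clone_population <- function(neuron, n = 100) {
  th <- vapply(neuron$kinetics, `[[`, numeric(1), "theta")
  row <- data.frame(tau_m = neuron$C_M / neuron$g_L,
                    R_input = 1000 / neuron$g_L, E_L = neuron$E_L,
                    g_Na = neuron$g_Na, g_Kv1 = neuron$g_Kv1,
                    kv3_na_ratio = neuron$g_Kv3 / neuron$g_Na,
                    theta_m = th[["m"]], theta_h = th[["h"]],
                    theta_n = th[["n"]], theta_a = th[["a"]],
                    C_M = neuron$C_M, g_L = neuron$g_L, g_Kv3 = neuron$g_Kv3)
  out <- row[rep(1, n), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("fs_population", "data.frame"))
}

#' Compensate the leak for added gap junctions
#'
#' Each accepted gap junction subtracts its conductance from the leak of
#' both endpoint neurons so that the measured input resistance,
#' approximately 1/(g_L + sum g_gap), stays in the experimentally
#' constrained range. Junctions whose addition would push either endpoint's
#' leak below the floor `g_L_min` are skipped and removed from the returned
#' junction list. The leak reversal of every touched neuron is then
#' re-adjusted so that its isolated resting potential (bisected to 0.01 mV)
#' is preserved: with the new leak `g_L'`, setting
#' `E_L' = V_rest + (g_L/g_L') (E_L - V_rest)` keeps the steady-state
#' current balance at `V_rest` exact. Capacitance is unchanged.
#'
#' @param population an `fs_population`
#' @param gaps gap-junction edge list from [build_gap_connectivity()]
#' @param g_L_min leak floor (nS), default 1.5
#' @return list with `population` (adjusted) and `gaps` (accepted junctions)
#' @export
apply_gap_compensation <- function(population, gaps, g_L_min = 1.5) {
  pop <- population
  if (nrow(gaps) == 0) return(list(population = pop, gaps = gaps))
  keep <- logical(nrow(gaps))
  gl <- pop$g_L
  for (k in seq_len(nrow(gaps))) {    # prune in draw order
    i <- gaps$i[k]; j <- gaps$j[k]; g <- gaps$g_gap[k]
    if (gl[i] - g >= g_L_min && gl[j] - g >= g_L_min) {
      gl[i] <- gl[i] - g; gl[j] <- gl[j] - g
      keep[k] <- TRUE
    }
  }
  touched <- which(gl != pop$g_L)
  for (i in touched) {
    vrest <- resting_potential(row_to_neuron(pop[i, , drop = FALSE]))
    new_EL <- vrest + (pop$g_L[i] / gl[i]) * (pop$E_L[i] - vrest)
    pop$g_L[i] <- gl[i]
    pop$E_L[i] <- new_EL
  }
  list(population = pop, gaps = gaps[keep, , drop = FALSE])
}
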
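#' Read and write pipeline artifacts as plain text
#'
#' Populations are one-neuron-per-row CSVs with unit-suffixed column names;
#' synapse and gap-junction lists are edge-list CSVs; spike rasters are
#' two-column CSVs (`neuron_id`, `t_ms`) with a JSON sidecar carrying run
#' metadata.
#'
#' @param population an `fs_population`
#' @param path file path
#' @name ingsim-io
NULL

pop_units <- c(tau_m = "ms", R_input = "MOhm", E_L = "mV", g_Na = "nS",
               g_Kv1 = "nS", kv3_na_ratio = "", theta_m = "mV",
               theta_h = "mV", theta_n = "mV", theta_a = "mV", C_M = "pF",
               g_L = "nS", g_Kv3 = "nS", rheobase = "pA", cutoff = "Hz",
               amplitude = "mV", half_width = "ms", ahp = "mV")

#' @rdname ingsim-io
#' @export
write_population <- function(population, path) {
  df <- as.data.frame(population)
  u <- pop_units[names(df)]
  names(df) <- ifelse(is.na(u) | u == "", names(df),
                      paste(names(df), u, sep = "_"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ingsim-io
#' @export
read_population <- function(path) {
  df <- read.csv(path)
  names(df) <- sub("_(ms|MOhm|mV|nS|pF|pA|Hz)$", "", names(df))
  structure(df, class = c("fs_population", "data.frame"))
}

#' @rdname ingsim-io
#' @param edges a `synapse_list` or `gap_list`
#' @export
write_edges <- function(edges, path) {
  df <- as.data.frame(edges)
  if (all(c("pre", "post") %in% names(df))) {
    out <- data.frame(pre = df$pre, post = df$post, g_nS = df$g_syn,
                      delay_ms = df$delay, kind = "chemical")
  } else {
    out <- data.frame(pre = df$i, post = df$j, g_nS = df$g_gap,
                      delay_ms = 0, kind = "gap")
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ingsim-io
#' @export
read_edges <- function(path) {
  df <- read.csv(path)
  if (all(df$kind == "gap")) {
    structure(data.frame(i = df$pre, j = df$post, g_gap = df$g_nS),
              class = c("gap_list", "data.frame"))
  } else {
    structure(data.frame(pre = df$pre, post = df$post, g_syn = df$g_nS,
                         delay = df$delay_ms),
              class = c("synapse_list", "data.frame"))
  }
}

#' @rdname ingsim-io
#' @param raster a `spike_raster`
#' @param metadata extra fields for the JSON sidecar
#' @export
write_raster <- function(raster, path, metadata = list()) {
  df <- data.frame(
    neuron_id = rep(seq_along(raster$spikes), lengths(raster$spikes)),
    t_ms = unlist(raster$spikes))
  write.csv(df, path, row.names = FALSE)
  meta <- c(list(n = raster$n, duration_ms = raster$duration,
                 dt_ms = raster$dt), metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname ingsim-io
#' @export
read_raster <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  spikes <- lapply(seq_len(meta$n), function(i)
    sort(df$t_ms[df$neuron_id == i]))
  structure(list(spikes = spikes, n = meta$n, duration = meta$duration_ms,
                 dt = meta$dt_ms, traces = NULL, drive = NULL),
            class = "spike_raster")
}

#' @rdname ingsim-io
#' @param prc a `prc` object
#' @export
write_prc <- function(prc, path) {
  write.csv(as.data.frame(prc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ingsim-io
#' @param metrics a `cycle_metrics` table
#' @export
write_cycle_metrics <- function(metrics, path) {
  df <- as.data.frame(metrics)
  df <- df[, c("cycle", "dominant_freq", "max_power", "onset_phase",
               "offset_phase", "included")]
  names(df) <- c("cycle_index", "dominant_freq_Hz", "max_power",
                 "onset_rad", "offset_rad", "included")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
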
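# Configuration and file I/O shared by all protocols.  Units in all files:
# time ms, voltage mV, current pA, conductance nS.  Neuron ids are 0-based
# externally (excitatory neurons are ids 0..0.8N-1).

config_defaults <- function() {
  list(
    params = unclass(adex_params())[c("C_m", "g_L", "E_L", "Delta_T", "V_T",
                                      "V_thres", "V_r", "tau_w", "tau_s",
                                      "a_range", "b", "V_rev_exc",
                                      "V_rev_inh", "g_exc", "g_inh",
                                      "exp_cap")],
    # "n_neurons" rather than a bare "N": YAML 1.1 parses the unquoted key
    # N as the boolean false
    topology = list(n_neurons = 1000L, p = 0.1, frac_exc = 0.8,
                    seed = NULL),
    stimulus = list(r = 2, scp_amplitude = 0, scp_duration = 0,
                    scp_onset = 0, scp_target_fraction = 1,
                    noise_sigma = 0, noise_dt_invariant = FALSE),
    simulation = list(dt = 0.05, duration = 20000, transient = 10000,
                      record_dt = 0, record_isyn = FALSE,
                      state_seed = NULL, noise_seed = NULL,
                      sample_dt = 1, sync_threshold = 0.9)
  )
}

config_ranges <- function() {
  list(c("topology", "p", 0, 1), c("topology", "frac_exc", 0, 1),
       c("topology", "n_neurons", 1, Inf),
       c("simulation", "dt", 1e-6, Inf),
       c("simulation", "duration", 0, Inf),
       c("stimulus", "noise_sigma", 0, Inf),
       c("stimulus", "scp_duration", 0, Inf),
       c("simulation", "sync_threshold", 0, 1))
}

#' Load and validate a structured configuration file
#'
#' Reads a YAML configuration with sections `params`, `topology`,
#' `stimulus` and `simulation`, fills every omitted field with the package
#' defaults (the standard AdEx constants, N=1000/p=0.1 network, 20 s run at
#' dt=0.05 ms), and rejects unknown keys and out-of-range values by name.
#' An empty file therefore yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return nested named list with the four sections fully populated; the
#'   `params` section converts with [as_adex_params()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defs <- config_defaults()
  bad <- setdiff(names(user), names(defs))
  if (length(bad)) stop("unknown config section: ", paste(bad, collapse = ", "))
  cfg <- defs
  for (sec in names(user)) {
    u <- user[[sec]]
    if (!is.list(u)) stop("config section '", sec, "' must be a mapping")
    unknown <- setdiff(names(u), names(defs[[sec]]))
    if (length(unknown))
      stop("unknown config key: ", sec, ".", paste(unknown, collapse = ", "))
    cfg[[sec]][names(u)] <- u
  }
  for (rng in config_ranges()) {
    v <- cfg[[rng[1]]][[rng[2]]]
    if (!is.null(v) && (!is.numeric(v) || v < as.numeric(rng[3]) ||
                        v > as.numeric(rng[4])))
      stop("config value out of range: ", rng[1], ".", rng[2],
           " must be in [", rng[3], ", ", rng[4], "]")
  }
  validate_adex_params(as_adex_params(cfg$params))
  cfg
}

#' Convert a config `params` section to an [adex_params()] object
#' @param x named list with any subset of the [adex_params()] arguments.
#' @return an `adex_params` object.
#' @export
as_adex_params <- function(x) {
  do.call(adex_params, x[intersect(names(x), names(formals(adex_params)))])
}

#' Write / read a spike raster as CSV
#'
#' Columns `neuron_id` (0-based) and `spike_time_ms`, one row per spike,
#' with a header; the window is kept in a `# window:` comment line.
#'
#' @param raster an [adex_raster()].
#' @param path output file.
#' @return `write_raster_csv`: the path, invisibly.  `read_raster_csv`: the
#'   raster (with `n_neurons` inferred from the file unless given).
#' @export
write_raster_csv <- function(raster, path) {
  n <- vapply(raster$spike_times, length, 1L)
  df <- data.frame(neuron_id = rep(seq_along(n) - 1L, n),
                   spike_time_ms = unlist(raster$spike_times, use.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window: %.17g %.17g ; n_neurons: %d",
                     raster$window[1], raster$window[2], length(n)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param n_neurons override the neuron count on read.
#' @export
read_raster_csv <- function(path, n_neurons = NULL) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "window: ([-0-9.eE+]+) ([-0-9.eE+]+) ; n_neurons: ([0-9]+)", hdr))[[1]]
  if (length(m) != 4) stop("malformed raster header in ", path)
  window <- as.numeric(m[2:3])
  if (is.null(n_neurons)) n_neurons <- as.integer(m[4])
  df <- utils::read.csv(path, skip = 1L)
  raster_from_events(df$spike_time_ms, df$neuron_id + 1L, n_neurons, window)
}

#' Write / read a network topology
#'
#' The edge list goes to CSV with 0-based columns `post_id`, `pre_id`
#' (`M[post, pre] = 1`); a JSON sidecar (`<path>.json`) stores `N`, `p`,
#' `seed` and the excitatory count.
#'
#' @param topology an [adex_topology()].
#' @param path CSV output file.
#' @return `write_topology`: the path, invisibly; `read_topology`: the
#'   topology.
#' @export
write_topology <- function(topology, path) {
  idx <- which(topology$M == 1L, arr.ind = TRUE)
  df <- data.frame(post_id = idx[, 1] - 1L, pre_id = idx[, 2] - 1L)
  df <- df[order(df$post_id, df$pre_id), ]
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(N = topology$N, p = topology$p, seed = topology$seed,
               n_excitatory = sum(topology$is_excitatory))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  M <- matrix(0L, side$N, side$N)
  M[cbind(df$post_id + 1L, df$pre_id + 1L)] <- 1L
  new_adex_topology(M, seq_len(side$N) <= side$n_excitatory,
                    p = if (is.null(side$p)) NA_real_ else side$p,
                    seed = side$seed)
}

#' Write recorded traces as CSV
#'
#' One file per recorded series: `times`, one column per recorded neuron
#' for `V`, `w`, `g` and the per-neuron synaptic input, plus the
#' population-mean synaptic input when recorded.
#'
#' @param traces trace list from [adex_simulate()].
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  if (is.null(traces)) stop("no traces recorded")
  df <- data.frame(time_ms = traces$times)
  add <- function(mat, prefix) {
    if (is.null(mat) || !length(mat)) return()
    for (k in seq_len(ncol(mat)))
      df[[sprintf("%s_n%d", prefix, traces$neurons[k])]] <<- mat[, k]
  }
  add(traces$V, "V"); add(traces$w, "w"); add(traces$g, "g")
  add(traces$I_isc, "Isc")
  if (!is.null(traces$I_syn) && length(traces$I_syn))
    df$I_syn_mean <- traces$I_syn
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a tidy sweep grid as CSV
#' @param sweep an `adex_sweep` or `adex_hysteresis` data.frame.
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records what produced a set of output files: a config snapshot and its
#' hash, all seeds, the package version, timestamps and per-stage status.
#'
#' @param config the configuration list used.
#' @param seeds named list of seeds.
#' @param outputs character vector of output files written.
#' @param status named character vector of per-stage status.
#' @param path JSON output file.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, seeds, outputs, status, path) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, null = "null",
                               digits = NA)
  man <- list(package = "adexnet",
              version = as.character(utils::packageVersion("adexnet")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = config,
              config_hash = config_hash(config),
              seeds = seeds, outputs = outputs, status = as.list(status))
  jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(man)
}

# stable content hash of a config: canonical JSON + polynomial rolling hash
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                     null = "null", digits = NA))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("poly-%010d", h)
}
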
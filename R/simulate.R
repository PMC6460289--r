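#' Instantaneous synaptic input of one neuron
#'
#' Evaluates the conductance-based synaptic current arriving at neuron `i`:
#' `sum_j (Vrev_j - V_i) M[i, j] g_j`, where the reversal potential is that
#' of the presynaptic neuron's class.  With conductances in nS and voltages
#' in mV the result is in pA.
#'
#' @param state an [adex_init_state()] state.
#' @param topology an [adex_topology()].
#' @param params an [adex_params()].
#' @param i 1-based neuron index (or vector of indices).
#' @return synaptic current (pA).
#' @export
synaptic_drive <- function(state, topology, params, i) {
  stopifnot(all(i >= 1), all(i <= topology$N))
  vapply(i, function(ii) {
    pre <- which(topology$M[ii, ] == 1L)
    if (!length(pre)) return(0)
    vrev <- ifelse(topology$is_excitatory[pre], params$V_rev_exc, params$V_rev_inh)
    sum((vrev - state$V[ii]) * state$g[pre])
  }, numeric(1))
}

drive_current <- function(stimulus, params, a) {
  stimulus$r * adex_rheobase(params, a)
}

run_core <- function(topology, params, stimulus, config, state, t0 = state$t) {
  csr <- topology_csr(topology)
  targets <- stimulus$scp_targets
  if (is.null(targets)) targets <- seq_len(topology$N)
  if (!is.null(config$noise_seed) && stimulus$noise_sigma > 0)
    set.seed(config$noise_seed)
  adex_integrate_cpp(
    csr$out_ptr, csr$out_idx, topology$is_excitatory,
    state$V, state$w, state$g, state$a,
    drive_current(stimulus, params, state$a),
    unclass(params)[c("C_m", "g_L", "E_L", "Delta_T", "V_T", "V_thres",
                      "V_r", "tau_w", "tau_s", "b", "V_rev_exc", "V_rev_inh",
                      "g_exc", "g_inh", "exp_cap")],
    stimulus$scp_amplitude, stimulus$scp_onset,
    stimulus$scp_onset + stimulus$scp_duration,
    as.integer(targets) - 1L,
    stimulus$noise_sigma, stimulus$noise_dt_invariant,
    t0, config$duration, config$dt,
    config$record_dt, as.integer(config$record_neurons) - 1L,
    config$record_isyn)
}

#' Advance the network by one integration step
#'
#' Applies one explicit-Euler step of the coupled AdEx equations, then the
#' reset rule: every neuron whose membrane potential exceeds `V_thres` is
#' recorded as spiking and reset (`V -> V_r`, `w -> w + b`, `g -> g + g_s`
#' with `g_s` the conductance increment of its own class).  The argument of
#' the exponential term is capped (see [adex_params()]) for overflow safety.
#'
#' @param state current [adex_init_state()] state.
#' @param topology an [adex_topology()].
#' @param params an [adex_params()].
#' @param stimulus an [adex_stimulus()].
#' @param dt step size (ms).
#' @return list with `state` (advanced by `dt`) and `spiked` (1-based
#'   indices of neurons that fired during the step).
#' @export
adex_step <- function(state, topology, params, stimulus, dt) {
  stopifnot(dt > 0)
  cfg <- adex_config(dt = dt, duration = dt)
  res <- run_core(topology, params, stimulus, cfg, state)
  list(state = structure(list(t = res$t_end, V = res$V, w = res$w,
                              g = res$g, a = state$a), class = "adex_state"),
       spiked = sort(unique(res$spike_i + 1L)))
}

#' Simulate an AdEx network
#'
#' Integrates the full network with explicit Euler at step `config$dt`,
#' applying the constant rheobase-relative drive, the square current pulse
#' and the noise described by `stimulus`.  Returns the spike raster, the
#' requested traces and the final state (which can seed a continued run, as
#' in hysteresis sweeps).
#'
#' @param topology an [adex_topology()].
#' @param params an [adex_params()].
#' @param stimulus an [adex_stimulus()] (default: constant drive at twice
#'   rheobase, no pulse, no noise).
#' @param config an [adex_config()].
#' @param init initial [adex_init_state()] state; drawn randomly when `NULL`
#'   (use `state_seed` for reproducibility).
#' @param state_seed seed used when `init` is `NULL`.
#' @return An object of class `adex_sim`: list with `raster`
#'   ([adex_raster()]), `traces` (`NULL` unless recording was requested; else
#'   list with `times`, matrices `V`/`w`/`g`/`I_isc` for the recorded
#'   neurons, and `I_syn`, the population-mean synaptic input series),
#'   `final_state`, and the inputs that produced it.
#' @examples
#' top <- adex_topology(50, p = 0.1, seed = 1)
#' par <- adex_params()
#' sim <- adex_simulate(top, par, adex_stimulus(r = 2),
#'                      adex_config(dt = 0.05, duration = 500), state_seed = 1)
#' sim
#' @export
adex_simulate <- function(topology, params, stimulus = adex_stimulus(),
                          config = adex_config(), init = NULL,
                          state_seed = NULL) {
  if (is.null(init))
    init <- adex_init_state(topology, params, seed = state_seed)
  stopifnot(length(init$V) == topology$N)
  t0 <- init$t
  if (config$duration == 0) {
    res <- list(spike_t = numeric(), spike_i = integer(), V = init$V,
                w = init$w, g = init$g, t_end = t0, n_steps = 0,
                traces = NULL)
  } else {
    res <- run_core(topology, params, stimulus, config, init)
  }
  final <- structure(list(t = res$t_end, V = res$V, w = res$w, g = res$g,
                          a = init$a), class = "adex_state")
  traces <- res$traces
  if (!is.null(traces)) traces$neurons <- traces$neurons + 1L
  structure(list(
    raster = raster_from_events(res$spike_t, res$spike_i + 1L, topology$N,
                                c(t0, res$t_end)),
    traces = traces,
    final_state = final,
    topology = topology, params = params, stimulus = stimulus,
    config = config), class = "adex_sim")
}

#' @export
print.adex_sim <- function(x, ...) {
  cat(sprintf("AdEx network simulation: N=%d, %g ms at dt=%g ms, %d spikes\n",
              x$topology$N, diff(x$raster$window), x$config$dt,
              n_spikes(x$raster)))
  invisible(x)
}

#' Summarise a simulation into its dynamical regime
#'
#' Computes the time-averaged order parameter, the mean inter-spike-interval
#' coefficient of variation and the mean firing rate over an analysis
#' window, and classifies the regime (see [classify_regime()]).
#'
#' @param object an `adex_sim`.
#' @param t_ini,t_fin analysis window (ms); defaults to the last half of the
#'   simulated window (the first half is treated as transient).
#' @param ... passed to [regime_summary()].
#' @return an `adex_regime` summary (see [regime_summary()]).
#' @export
summary.adex_sim <- function(object, t_ini = NULL, t_fin = NULL, ...) {
  w <- object$raster$window
  if (is.null(t_ini)) t_ini <- mean(w)
  if (is.null(t_fin)) t_fin <- w[2]
  regime_summary(object$raster, t_ini = t_ini, t_fin = t_fin, ...)
}

#' @export
plot.adex_sim <- function(x, ...) plot(x$raster, topology = x$topology, ...)
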
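#' Random initial network state
#'
#' Draws the standard random initial condition: membrane potentials uniform
#' in \[-70, -50\] mV, adaptation currents uniform in \[0, 70\] pA, synaptic
#' conductances zero.  The per-neuron subthreshold adaptation conductances
#' `a_i` (uniform in `params$a_range`) are drawn here too and carried in the
#' state, so a continued simulation (hysteresis sweeps) keeps the same
#' heterogeneity.
#'
#' @param topology an [adex_topology()] object.
#' @param params an [adex_params()] object.
#' @param seed optional RNG seed.
#' @param V_range,w_range sampling intervals for the initial membrane
#'   potential (mV) and adaptation current (pA).
#' @return An object of class `adex_state`: list with `t` (ms), `V`, `w`,
#'   `g`, `a` (each length N).
#' @export
adex_init_state <- function(topology, params, seed = NULL,
                            V_range = c(-70, -50), w_range = c(0, 70)) {
  N <- topology$N
  if (!is.null(seed)) set.seed(seed)
  st <- list(t = 0,
             V = stats::runif(N, V_range[1], V_range[2]),
             w = stats::runif(N, w_range[1], w_range[2]),
             g = numeric(N),
             a = if (length(params$a) == N) params$a
                 else stats::runif(N, params$a_range[1], params$a_range[2]))
  class(st) <- "adex_state"
  st
}

#' @export
print.adex_state <- function(x, ...) {
  cat(sprintf("AdEx network state at t=%g ms: N=%d, V in [%.2f, %.2f] mV, mean w=%.1f pA\n",
              x$t, length(x$V), min(x$V), max(x$V), mean(x$w)))
  invisible(x)
}

#' External stimulus specification
#'
#' Describes the external input of every neuron: a constant drive expressed
#' as a multiple `r` of each neuron's own rheobase (`I_i = r *
#' rheobase(a_i)`), an optional square current pulse (SCP) of amplitude
#' `scp_amplitude` applied for `scp_duration` starting at `scp_onset` to the
#' neurons in `scp_targets`, and optional Gaussian current noise drawn
#' independently per neuron per integration step.
#'
#' @param r relative rheobase multiplier (dimensionless).
#' @param scp_amplitude SCP amplitude (pA); may be negative.
#' @param scp_duration SCP duration (ms).
#' @param scp_onset SCP switch-on time (ms, absolute simulation time).
#' @param scp_targets integer vector of 1-based target neuron indices, or
#'   `NULL` for all neurons.
#' @param noise_sigma standard deviation of the Gaussian current noise (pA);
#'   0 disables noise.
#' @param noise_dt_invariant if `TRUE` the per-step noise standard deviation
#'   is scaled by `1/sqrt(dt)` so that the integrated noise variance is
#'   independent of the step size; the default (`FALSE`) draws amplitude
#'   `noise_sigma` at every step (pulse-like current noise).
#' @return an object of class `adex_stimulus`.
#' @export
adex_stimulus <- function(r = 2, scp_amplitude = 0, scp_duration = 0,
                          scp_onset = 0, scp_targets = NULL,
                          noise_sigma = 0, noise_dt_invariant = FALSE) {
  stopifnot(scp_duration >= 0, noise_sigma >= 0, r >= 0)
  structure(list(r = r, scp_amplitude = scp_amplitude,
                 scp_duration = scp_duration, scp_onset = scp_onset,
                 scp_targets = scp_targets, noise_sigma = noise_sigma,
                 noise_dt_invariant = noise_dt_invariant),
            class = "adex_stimulus")
}

#' Simulation configuration
#'
#' @param dt integration step (ms); explicit Euler.
#' @param duration simulated time (ms).
#' @param record_dt sampling interval for recorded traces (ms); `0` disables
#'   trace recording.
#' @param record_neurons 1-based indices of neurons whose V/w/g/synaptic
#'   input traces are recorded (empty by default).
#' @param record_isyn record the population-mean instantaneous synaptic
#'   input series.
#' @param noise_seed RNG seed for the stimulus noise stream.
#' @return an object of class `adex_config`.
#' @export
adex_config <- function(dt = 0.05, duration = 1000, record_dt = 0,
                        record_neurons = integer(), record_isyn = FALSE,
                        noise_seed = NULL) {
  stopifnot(dt > 0, duration >= 0, record_dt >= 0)
  structure(list(dt = dt, duration = duration, record_dt = record_dt,
                 record_neurons = as.integer(record_neurons),
                 record_isyn = isTRUE(record_isyn), noise_seed = noise_seed),
            class = "adex_config")
}
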
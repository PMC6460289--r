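# Phase-plane analysis: V-nullcline and trajectory classification in the
# (w, V) plane for a single neuron.

#' Membrane-potential nullcline
#'
#' The V-nullcline is the curve dV/dt = 0 in the (V, w) plane for a given
#' total constant input current `I` (drive plus synaptic input folded
#' together):
#' `w_null(V) = -g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T) + I`.
#' Points with `w > w_null(V)` have dV/dt < 0.  The curve has a single
#' interior minimum, at `V = V_T`, of height `-g_L (V_T - E_L) + g_L
#' Delta_T + I`; trajectories of bursting neurons dwell in the region
#' enclosed above it, spiking trajectories do not.
#'
#' @param params an [adex_params()].
#' @param I total constant input current (pA).
#' @param V_grid voltages at which to evaluate the curve (mV).
#' @return An object of class `adex_nullcline`: data.frame with `V` and
#'   `w_null`; attributes `I`, `V_min` and `w_min` (the interior minimum).
#' @examples
#' nc <- nullcline_curve(adex_params(), I = 0)
#' attr(nc, "w_min")   # -216 pA at V = V_T
#' @export
nullcline_curve <- function(params, I = 0, V_grid = seq(-80, params$V_thres,
                                                        by = 0.25)) {
  w <- w_nullcline(V_grid, params, I)
  structure(data.frame(V = V_grid, w_null = w),
            class = c("adex_nullcline", "data.frame"),
            I = I, V_min = params$V_T,
            w_min = w_nullcline(params$V_T, params, I))
}

w_nullcline <- function(V, params, I) {
  -params$g_L * (V - params$E_L) +
    params$g_L * params$Delta_T * exp((V - params$V_T) / params$Delta_T) + I
}

#' Phase-plane trajectory of one recorded neuron
#'
#' Extracts the (w, V) trajectory of a recorded neuron from simulation
#' traces and compares it with the V-nullcline at a reference input
#' current (by default the neuron's mean total input over the trace:
#' constant drive plus time-averaged synaptic input).  For each sample the
#' function tests whether the point lies in the region enclosed by the
#' nullcline -- `w > w_null(V)` with `V` on the subthreshold side -- where
#' dV/dt < 0 and the membrane potential falls.  Burst trajectories dwell in
#' that region between intra-burst spikes (the adaptation built up during
#' the burst silences the neuron); tonic-spike trajectories stay below the
#' nullcline.
#'
#' @param sim an `adex_sim` whose config recorded traces for the neuron
#'   (see [adex_config()]'s `record_neurons`), or a trace list.
#' @param neuron 1-based neuron index (must be among the recorded ones).
#' @param params an [adex_params()]; taken from `sim` when available.
#' @param drive constant drive current of the neuron (pA); taken from the
#'   simulation inputs when available.
#' @param I_ref reference input current for the nullcline; default
#'   `drive + mean(recorded synaptic input)`.
#' @param dwell_threshold fraction of samples inside the enclosed region
#'   above which the trajectory is classified as bursting (default 0.02).
#' @param margin adaptation-current margin (pA) a sample must clear above
#'   the nullcline to count as inside (default 5).  A resting neuron sits
#'   exactly on its nullcline (that is what an equilibrium is), so a strict
#'   inequality would classify numerical jitter as dwelling.
#' @return An object of class `adex_phase_plane`: list with `V`, `w`,
#'   `times`, `nullcline`, `inside` (logical per sample), `dwell_fraction`,
#'   `n_crossings` and `classification` (`"burst"`/`"spike"`).
#' @export
phase_plane_trace <- function(sim, neuron, params = NULL, drive = NULL,
                              I_ref = NULL, dwell_threshold = 0.02,
                              margin = 5) {
  if (inherits(sim, "adex_sim")) {
    traces <- sim$traces
    if (is.null(params)) params <- sim$params
    if (is.null(drive))
      drive <- drive_current(sim$stimulus, params,
                             sim$final_state$a)[neuron]
  } else traces <- sim
  if (is.null(traces)) stop("phase-plane analysis requires recorded traces")
  k <- match(neuron, traces$neurons)
  if (is.na(k)) stop("neuron ", neuron, " was not recorded; see record_neurons")
  V <- traces$V[, k]; w <- traces$w[, k]
  if (is.null(I_ref)) {
    if (is.null(drive)) stop("supply 'drive' or 'I_ref'")
    I_ref <- drive + mean(traces$I_isc[, k])
  }
  wn <- w_nullcline(pmin(V, params$V_thres), params, I_ref)
  inside <- w > wn + margin & V < params$V_thres
  dwell <- mean(inside)
  crossings <- sum(diff(inside) != 0)
  structure(list(V = V, w = w, times = traces$times,
                 nullcline = nullcline_curve(params, I_ref),
                 I_ref = I_ref, inside = inside, dwell_fraction = dwell,
                 n_crossings = crossings,
                 classification = if (dwell > dwell_threshold) "burst"
                                  else "spike"),
            class = "adex_phase_plane")
}

#' @export
print.adex_phase_plane <- function(x, ...) {
  cat(sprintf("Phase-plane trajectory: %d samples, dwell fraction %.3f inside the V-nullcline region, %d boundary crossings -> %s signature\n",
              length(x$V), x$dwell_fraction, x$n_crossings,
              x$classification))
  invisible(x)
}

#' @export
plot.adex_phase_plane <- function(x, ...) {
  graphics::plot(x$w, x$V, type = "l", xlab = "w (pA)", ylab = "V (mV)",
                 col = if (x$classification == "burst") "firebrick" else "navy",
                 ...)
  graphics::lines(x$nullcline$w_null, x$nullcline$V, col = "black", lwd = 2)
  invisible(x)
}
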
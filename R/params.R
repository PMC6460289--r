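#' AdEx neuron and synapse parameters
#'
#' Builds the parameter set of the adaptive exponential integrate-and-fire
#' (AdEx) neuron with conductance-based synapses.  Defaults are the standard
#' cortical-neuron values used throughout the package: a leaky membrane with
#' an exponential spike-initiation term, a slow subthreshold/spike-triggered
#' adaptation current, and exponentially decaying synaptic conductances with
#' excitatory (0 mV) and inhibitory (-80 mV) reversal potentials.
#'
#' Units follow the electrophysiology convention used everywhere in this
#' package: capacitance pF, conductance nS, voltage mV, current pA, time ms
#' (so nS * mV = pA and pA / pF = mV/ms).
#'
#' @param C_m membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L resting (leak reversal) potential (mV).
#' @param Delta_T slope factor of the exponential term (mV).
#' @param V_T threshold potential of the exponential term (mV).
#' @param V_thres numerical spike-detection cutoff (mV).  Beyond
#'   `V_T +` a few `Delta_T` the exponential blow-up makes the precise value
#'   immaterial to spike timing at the default step; the default is
#'   `V_T + 5 * Delta_T = -40` mV.
#' @param V_r reset potential after a spike (mV).
#' @param tau_w adaptation time constant (ms).
#' @param tau_s synaptic decay time constant (ms).
#' @param a subthreshold adaptation conductance (nS): either a scalar or a
#'   per-neuron vector (heterogeneous networks draw one value per neuron, see
#'   [draw_adaptation()]).
#' @param a_range interval from which per-neuron `a` values are drawn when a
#'   heterogeneous vector is requested.
#' @param b spike-triggered adaptation increment (pA).
#' @param V_rev_exc,V_rev_inh excitatory / inhibitory synaptic reversal
#'   potentials (mV).
#' @param g_exc,g_inh synaptic conductance increment (nS) added to the
#'   presynaptic neuron's conductance when it fires, by its class.  The
#'   relative inhibitory strength is `g = g_inh / g_exc`.
#' @param exp_cap cap on the argument of the exponential term, for overflow
#'   safety; it can only bind at suprathreshold voltages where the reset
#'   fires in the same step.
#'
#' @return An object of class `adex_params` (a named list).
#' @examples
#' p <- adex_params()
#' adex_rheobase(p, a = 0)    # 216 pA for the default membrane
#' @export
adex_params <- function(C_m = 200, g_L = 12, E_L = -70, Delta_T = 2,
                        V_T = -50, V_thres = -40, V_r = -58,
                        tau_w = 300, tau_s = 2.728,
                        a = 0.2, a_range = c(0.19, 0.21), b = 70,
                        V_rev_exc = 0, V_rev_inh = -80,
                        g_exc = 0.4, g_inh = 1.2, exp_cap = 30) {
  p <- list(C_m = C_m, g_L = g_L, E_L = E_L, Delta_T = Delta_T, V_T = V_T,
            V_thres = V_thres, V_r = V_r, tau_w = tau_w, tau_s = tau_s,
            a = a, a_range = a_range, b = b,
            V_rev_exc = V_rev_exc, V_rev_inh = V_rev_inh,
            g_exc = g_exc, g_inh = g_inh, exp_cap = exp_cap)
  validate_adex_params(p)
  class(p) <- "adex_params"
  p
}

validate_adex_params <- function(p) {
  scal <- c("C_m", "g_L", "E_L", "Delta_T", "V_T", "V_thres", "V_r",
            "tau_w", "tau_s", "b", "V_rev_exc", "V_rev_inh",
            "g_exc", "g_inh", "exp_cap")
  for (nm in scal) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (!is.numeric(p$a) || any(!is.finite(p$a)) || any(p$a < 0))
    stop("parameter 'a' must be non-negative and finite", call. = FALSE)
  if (p$C_m <= 0 || p$g_L <= 0 || p$tau_w <= 0 || p$tau_s <= 0 || p$Delta_T <= 0)
    stop("C_m, g_L, tau_w, tau_s and Delta_T must be positive", call. = FALSE)
  if (!(p$V_r < p$V_T && p$V_T < p$V_thres))
    stop("require V_r < V_T < V_thres", call. = FALSE)
  if (length(p$a_range) != 2L || p$a_range[1] > p$a_range[2] || p$a_range[1] < 0)
    stop("a_range must be an ordered non-negative interval", call. = FALSE)
  invisible(p)
}

#' @export
print.adex_params <- function(x, ...) {
  cat("AdEx neuron parameters\n")
  cat(sprintf("  membrane : C_m=%g pF, g_L=%g nS, E_L=%g mV, Delta_T=%g mV, V_T=%g mV\n",
              x$C_m, x$g_L, x$E_L, x$Delta_T, x$V_T))
  cat(sprintf("  reset    : V_thres=%g mV -> V_r=%g mV, b=%g pA\n",
              x$V_thres, x$V_r, x$b))
  a <- if (length(x$a) == 1L) sprintf("a=%g nS", x$a)
       else sprintf("a: %d per-neuron values in [%g, %g] nS",
                    length(x$a), min(x$a), max(x$a))
  cat(sprintf("  adaptation: tau_w=%g ms, %s\n", x$tau_w, a))
  cat(sprintf("  synapses : tau_s=%g ms, g_exc=%g nS, g_inh=%g nS (g=%.3g), Vrev %g/%g mV\n",
              x$tau_s, x$g_exc, x$g_inh, x$g_inh / x$g_exc,
              x$V_rev_exc, x$V_rev_inh))
  invisible(x)
}

#' Heterogeneous subthreshold adaptation values
#'
#' Draws one subthreshold adaptation conductance per neuron, uniformly from
#' `a_range` (default 0.19-0.21 nS), giving each neuron a slightly different
#' rheobase and firing frequency.
#'
#' @param n number of neurons.
#' @param a_range sampling interval (nS).
#' @param seed optional RNG seed for reproducibility.
#' @return numeric vector of length `n`.
#' @export
draw_adaptation <- function(n, a_range = c(0.19, 0.21), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, a_range[1], a_range[2])
}

#' Rheobase current of an AdEx neuron
#'
#' The rheobase is the smallest constant input current for which the
#' subthreshold dynamics lose their stable fixed point, so the neuron fires.
#' Setting dV/dt = 0 and dw/dt = 0 gives the steady-state current demand
#' `I(V) = (g_L + a)(V - E_L) - g_L Delta_T exp((V - V_T)/Delta_T)`;
#' the rheobase is its maximum over V, attained at
#' `V* = V_T + Delta_T log(1 + a/g_L)`.
#'
#' @param params an [adex_params()] object.
#' @param a subthreshold adaptation conductance (nS); scalar or vector.
#'   Defaults to `params$a`.
#' @return rheobase current (pA), vectorised over `a`.
#' @examples
#' p <- adex_params()
#' adex_rheobase(p, a = 0)      # g_L * (V_T - E_L - Delta_T) = 216 pA
#' adex_rheobase(p, a = 0.2)    # ~220 pA
#' @export
adex_rheobase <- function(params, a = params$a) {
  if (any(!is.finite(a)) || any(a < 0)) stop("invalid adaptation conductance")
  gL <- params$g_L
  Vstar <- params$V_T + params$Delta_T * log1p(a / gL)
  (gL + a) * (Vstar - params$E_L) -
    gL * params$Delta_T * exp((Vstar - params$V_T) / params$Delta_T)
}
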
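# Square-current-pulse (SCP) stimulation protocols at a bistable point:
# triggering synchronized bursting from the desynchronized branch, and
# suppressing it from the synchronized branch.

#' Settle the network on one branch of a bistable point
#'
#' Prepares an initial condition on the desynchronized-spike or the
#' synchronized-burst branch at the given parameters.  The desynchronized
#' branch is reached by settling from a random initial condition (inside
#' the bistable region this is the high-probability outcome); the
#' synchronized branch by settling at a higher excitatory conductance
#' (`g_exc_high`, where only the synchronized state exists) and then
#' continuing at the target `g_exc` -- the backward-continuation route of
#' the hysteresis loop.
#'
#' @param branch `"desynchronized"` or `"synchronized"`.
#' @param g_exc,g,r bistable-point parameters (defaults 0.4 nS, 3, 2).
#' @param N,p network size and connection probability.
#' @param settle settling time per stage (ms).
#' @param g_exc_high conductance used to reach the synchronized state;
#'   must lie beyond the bistable band, where that state is the unique
#'   attractor (default: 0.15 nS above the target).
#' @param topology_seed,state_seed seeds.
#' @param dt integration step (ms).
#' @param verify_R optional order-parameter level separating the two
#'   branches.  When given, the settled state is checked against it
#'   (desynchronized branch: `R_bar < verify_R`; synchronized branch:
#'   `R_bar >= verify_R`) and the settling is retried from fresh random
#'   initial conditions if the check fails — inside a bistable region a
#'   random initial condition occasionally lands on the other branch.
#' @param max_tries settling attempts before giving up (with a warning).
#' @return list with `topology`, `params`, `stimulus`, `state` (settled),
#'   `summary` (regime over the last settling half) and `verified`.
#' @export
settle_branch <- function(branch = c("desynchronized", "synchronized"),
                          g_exc = 0.4, g = 3, r = 2, N = 1000, p = 0.1,
                          settle = 10000, g_exc_high = g_exc + 0.15,
                          topology_seed = NULL, state_seed = NULL,
                          dt = 0.05, verify_R = NULL, max_tries = 3) {
  branch <- match.arg(branch)
  top <- adex_topology(N, p, seed = topology_seed)
  par <- adex_params(g_exc = g_exc, g_inh = g * g_exc)
  stim <- adex_stimulus(r = r)
  par_hi <- adex_params(g_exc = g_exc_high, g_inh = g * g_exc_high)
  out <- NULL
  for (try in seq_len(max_tries)) {
    seed <- if (is.null(state_seed)) NULL else state_seed + 7919L * (try - 1L)
    if (branch == "desynchronized") {
      sim <- adex_simulate(top, par, stim,
                           adex_config(dt = dt, duration = settle),
                           state_seed = seed)
    } else {
      pre <- adex_simulate(top, par_hi, stim,
                           adex_config(dt = dt, duration = settle),
                           state_seed = seed)
      sim <- adex_simulate(top, par, stim,
                           adex_config(dt = dt, duration = settle),
                           init = pre$final_state)
    }
    w <- sim$raster$window
    s <- summary(sim, t_ini = mean(w), t_fin = w[2])
    ok <- is.null(verify_R) ||
      (branch == "desynchronized" && s$R_bar < verify_R) ||
      (branch == "synchronized" && s$R_bar >= verify_R)
    out <- list(topology = top, params = par, stimulus = stim,
                state = sim$final_state, summary = s, verified = ok)
    if (ok) break
  }
  if (!out$verified)
    warning("could not settle on the ", branch, " branch after ",
            max_tries, " attempts (last R_bar = ",
            format(out$summary$R_bar, digits = 3), ")")
  out
}

#' Sliding-window regime detection
#'
#' Classifies overlapping windows of a raster as synchronized bursting or
#' not: a window counts as synchronized bursting when its time-averaged
#' order parameter reaches `sync_threshold` and its mean ISI coefficient of
#' variation is at least 0.5.  The order-parameter series R(t) is computed
#' once over the whole observation range (one phase trajectory per neuron)
#' and averaged within each window.  Windows where either statistic is
#' undefined (too few spikes) are classified not-bursting.
#'
#' @param raster an [adex_raster()].
#' @param t_start,t_end observation range (ms).
#' @param window window length (ms), default 1000.
#' @param step window step (ms), default 500.
#' @param sync_threshold order-parameter threshold, default 0.9.
#' @return data.frame with `t0`, `t1`, `R_bar`, `CV_bar`, `sync_burst`.
#' @export
sliding_window_regimes <- function(raster, t_start = raster$window[1],
                                   t_end = raster$window[2], window = 1000,
                                   step = 500, sync_threshold = 0.9) {
  starts <- seq(t_start, t_end - window, by = step)
  os <- order_series(raster, t_start, t_end, sample_dt = 1)
  rows <- lapply(starts, function(t0) {
    t1 <- t0 + window
    sel <- os$times >= t0 & os$times <= t1 & !is.na(os$R)
    R <- if (sum(sel) >= 2L) trapz_mean(os$times[sel], os$R[sel]) else NA_real_
    CV <- tryCatch(isi_cv(raster, t_ini = t0, t_fin = t1)$cv_bar,
                   error = function(e) NA_real_)
    data.frame(t0 = t0, t1 = t1, R_bar = R, CV_bar = CV)
  })
  out <- do.call(rbind, rows)
  out$sync_burst <- !is.na(out$R_bar) & !is.na(out$CV_bar) &
    out$R_bar >= sync_threshold & out$CV_bar >= 0.5
  out
}

# persistence (ms) of the synchronized-burst state from the start of the
# observation range: length of the initial contiguous run of sync-burst
# windows, measured until the first window that fails the criterion.
burst_persistence <- function(windows, observe) {
  if (!nrow(windows) || !windows$sync_burst[1]) return(0)
  fail <- which(!windows$sync_burst)
  if (!length(fail)) return(observe)
  windows$t0[fail[1]] - windows$t0[1]
}

run_scp <- function(prep, A_I, T_I, targets, observe, window, step,
                    sync_threshold, dt = 0.05) {
  onset <- prep$state$t
  stim <- adex_stimulus(r = prep$stimulus$r, scp_amplitude = A_I,
                        scp_duration = T_I, scp_onset = onset,
                        scp_targets = targets)
  sim <- adex_simulate(prep$topology, prep$params, stim,
                       adex_config(dt = dt, duration = T_I + observe),
                       init = prep$state)
  off <- onset + T_I
  win <- sliding_window_regimes(sim$raster, t_start = off,
                                t_end = off + observe, window = window,
                                step = step, sync_threshold = sync_threshold)
  persist <- burst_persistence(win, observe)
  final <- summary(sim, t_ini = off + observe / 2, t_fin = off + observe)
  list(sim = sim, windows = win, persistence = persist, final = final)
}

scp_outcome <- function(A_I, T_I, target_fraction, res, observe) {
  structure(list(A_I = A_I, T_I = T_I, target_fraction = target_fraction,
                 persistence = res$persistence, observe = observe,
                 final_label = res$final$label, final = res$final,
                 windows = res$windows),
            class = "adex_scp")
}

#' @export
print.adex_scp <- function(x, ...) {
  cat(sprintf("SCP outcome: A_I=%g pA, T_I=%g ms, targets=%.0f%%\n",
              x$A_I, x$T_I, 100 * x$target_fraction))
  cat(sprintf("  synchronized-burst persistence: %g of %g ms; final regime %s\n",
              x$persistence, x$observe, x$final_label))
  invisible(x)
}

#' Trigger synchronization with a square current pulse
#'
#' At a bistable point, settles the network on the desynchronized branch,
#' applies a square current pulse of amplitude `A_I` for `T_I` ms to all
#' neurons, and measures how long the network stays in the
#' synchronized-burst state after switch-off (sliding-window detector).
#' Sufficiently strong or long pulses flip the network onto the
#' synchronized branch permanently.
#'
#' @param A_I pulse amplitude (pA).
#' @param T_I pulse duration (ms).
#' @param g_exc,g,r bistable-point parameters.
#' @param N,p network size and connection probability.
#' @param settle settling time on the branch before the pulse (ms).
#' @param observe post-pulse observation window (ms).
#' @param window,step sliding-window detector settings (ms).
#' @param sync_threshold order-parameter threshold.
#' @param topology_seed,state_seed seeds.
#' @param prep optional pre-settled preparation from [settle_branch()] (on
#'   the matching branch); when given, the settling stage is skipped, so
#'   one preparation can serve several pulse conditions.
#' @return an `adex_scp` outcome: pulse parameters, synchronized-burst
#'   `persistence` (ms) after switch-off, and the final regime.
#' @export
scp_trigger <- function(A_I, T_I, g_exc = 0.4, g = 3, r = 2, N = 1000,
                        p = 0.1, settle = 10000, observe = 20000,
                        window = 1000, step = 500, sync_threshold = 0.9,
                        topology_seed = NULL, state_seed = NULL,
                        prep = NULL) {
  if (is.null(prep))
    prep <- settle_branch("desynchronized", g_exc = g_exc, g = g, r = r,
                          N = N, p = p, settle = settle,
                          topology_seed = topology_seed,
                          state_seed = state_seed, verify_R = sync_threshold)
  res <- run_scp(prep, A_I, T_I, targets = NULL, observe = observe,
                 window = window, step = step,
                 sync_threshold = sync_threshold)
  scp_outcome(A_I, T_I, 1, res, observe)
}

#' Suppress synchronized bursting with a square current pulse
#'
#' At a bistable point, settles the network on the synchronized-burst
#' branch (via backward continuation from a higher excitatory conductance),
#' applies a square current pulse to a random subset of the neurons, and
#' measures how long synchronized bursting persists after switch-off.
#' Persistence 0 means the pulse succeeded in desynchronizing the network.
#'
#' @param A_I pulse amplitude (pA); may be negative.
#' @param T_I pulse duration (ms).
#' @param target_fraction fraction of neurons stimulated (uniformly random
#'   subset, seeded by `target_seed`).
#' @param observe,window,step,sync_threshold detector settings, see
#'   [scp_trigger()].
#' @param g_exc,g,r,N,p,settle,topology_seed,state_seed,prep as in
#'   [scp_trigger()].
#' @param target_seed seed for the target subset.
#' @return an `adex_scp` outcome.
#' @export
scp_suppress <- function(A_I, T_I, target_fraction, g_exc = 0.4, g = 3,
                         r = 2, N = 1000, p = 0.1, settle = 10000,
                         observe = 20000, window = 1000, step = 500,
                         sync_threshold = 0.9, topology_seed = NULL,
                         state_seed = NULL, target_seed = NULL,
                         prep = NULL) {
  stopifnot(target_fraction >= 0, target_fraction <= 1)
  if (is.null(prep))
    prep <- settle_branch("synchronized", g_exc = g_exc, g = g, r = r,
                          N = N, p = p, settle = settle,
                          topology_seed = topology_seed,
                          state_seed = state_seed, verify_R = sync_threshold)
  N <- prep$topology$N
  if (!is.null(target_seed)) set.seed(target_seed)
  n_tg <- round(target_fraction * N)
  targets <- if (n_tg > 0) sample.int(N, n_tg) else integer()
  res <- run_scp(prep, if (n_tg > 0) A_I else 0, T_I, targets = targets,
                 observe = observe, window = window, step = step,
                 sync_threshold = sync_threshold)
  scp_outcome(A_I, T_I, target_fraction, res, observe)
}
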
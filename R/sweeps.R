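# Experiment protocols: parameter sweeps, hysteresis continuation,
# inhibitory removal, synchronization probability, noise sensitivity.

make_seeds <- function(seed, n) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max, n))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Base study conditions for the protocols
#'
#' Bundles the shared network and run settings used by the sweep protocols:
#' an N=1000, p=0.1 random network with 80% excitatory neurons,
#' g_exc=0.4 nS, per-neuron constant drive `r` times each neuron's
#' rheobase, and a 20 s run whose first half is discarded as transient.
#'
#' @param N,p,frac_exc network size, connection probability, excitatory
#'   fraction.
#' @param g_exc excitatory conductance increment (nS).
#' @param g relative inhibitory conductance `g_inh/g_exc`.
#' @param r relative rheobase drive.
#' @param duration simulated time (ms).
#' @param transient discarded initial time (ms).
#' @param dt integration step (ms).
#' @return named list of study conditions.
#' @export
network_args <- function(N = 1000, p = 0.1, frac_exc = 0.8, g_exc = 0.4,
                         g = 3, r = 2, duration = 20000,
                         transient = duration / 2, dt = 0.05) {
  list(N = N, p = p, frac_exc = frac_exc, g_exc = g_exc, g = g, r = r,
       duration = duration, transient = transient, dt = dt)
}

run_cell <- function(args, topology_seed, state_seed, fraction_removed = 0,
                     removal_seed = NULL, record_isyn = FALSE,
                     noise_sigma = 0, noise_seed = NULL) {
  top <- adex_topology(args$N, args$p, args$frac_exc, seed = topology_seed)
  if (fraction_removed > 0)
    top <- remove_inhibitory(top, fraction_removed, seed = removal_seed)
  par <- adex_params(g_exc = args$g_exc, g_inh = args$g * args$g_exc)
  stim <- adex_stimulus(r = args$r, noise_sigma = noise_sigma)
  cfg <- adex_config(dt = args$dt, duration = args$duration,
                     record_dt = if (record_isyn) 1 else 0,
                     record_isyn = record_isyn, noise_seed = noise_seed)
  sim <- adex_simulate(top, par, stim, cfg, state_seed = state_seed)
  list(sim = sim,
       summary = summary(sim, t_ini = args$transient, t_fin = args$duration))
}

#' Sweep the (g, r) or (g, g_exc) parameter space
#'
#' Runs one seeded simulation per grid cell and trial, discards the
#' transient, and records the regime summary.  The relative inhibitory
#' conductance `g = g_inh/g_exc` is applied as `g_inh = g * g_exc`.
#'
#' @param axes named list of one or two numeric axes; names among `g`, `r`,
#'   `g_exc` (e.g. `list(g = c(2.5, 4), r = c(1.5, 2))`).
#' @param base base study conditions, see the arguments of
#'   [adex_topology()] and [adex_stimulus()]; defaults are the standard
#'   N=1000, p=0.1, g_exc=0.4 nS network with a 20 s run, first 10 s
#'   transient.
#' @param trials simulations per cell (fresh seeds each).
#' @param seed base seed from which all per-cell seeds derive.
#' @return An object of class `adex_sweep`: data.frame with one row per
#'   cell and trial (parameters, seeds, `R_bar`, `CV_bar`, `F_bar`,
#'   `label`; failed cells carry `NA` and the error message).
#' @export
sweep_parameter_space <- function(axes, base = network_args(), trials = 1,
                                  seed = NULL) {
  stopifnot(length(axes) >= 1, all(names(axes) %in% c("g", "r", "g_exc")))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = trials), , drop = FALSE]
  grid$trial <- rep(seq_len(trials), length.out = nrow(grid))
  seeds <- matrix(make_seeds(seed, 2 * nrow(grid)), ncol = 2)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    args <- base
    for (nm in setdiff(names(grid), "trial")) args[[nm]] <- grid[[nm]][k]
    out <- tryCatch(run_cell(args, seeds[k, 1], seeds[k, 2]),
                    error = function(e) e)
    row <- data.frame(g = args$g, r = args$r, g_exc = args$g_exc,
                      trial = grid$trial[k], topology_seed = seeds[k, 1],
                      state_seed = seeds[k, 2], R_bar = NA_real_,
                      CV_bar = NA_real_, F_bar = NA_real_,
                      label = NA_character_, error = NA_character_)
    if (inherits(out, "error")) {
      row$error <- conditionMessage(out)
    } else {
      s <- out$summary
      row$R_bar <- s$R_bar; row$CV_bar <- s$CV_bar; row$F_bar <- s$F_bar
      row$label <- s$label
    }
    row
  })
  structure(do.call(rbind, rows), class = c("adex_sweep", "data.frame"))
}

#' Hysteresis continuation sweep over the excitatory conductance
#'
#' Sweeps `g_exc` across a range in both directions, carrying the final
#' network state from each step into the next (parameter continuation).
#' The forward pass ascends from a fresh random initial condition; the
#' backward pass descends from an independently settled state at the top of
#' the range.  On the bistable interval the backward (synchronized) branch
#' keeps a high order parameter where the forward (desynchronized) branch
#' does not; a grid point is flagged bistable when
#' `R_bar_backward - R_bar_forward > gap_threshold` (default 0.4).
#'
#' @param g_exc_range range of `g_exc` (nS), default `c(0.35, 0.45)`.
#' @param step grid step (nS), default 0.01.
#' @param g relative inhibitory conductance `g_inh/g_exc`.
#' @param r relative rheobase drive.
#' @param settle per-step settling time before measuring (ms).
#' @param measure measuring window per step (ms).
#' @param trials independent forward/backward pairs averaged per grid point.
#' @param N,p network size and connection probability.
#' @param noise_sigma Gaussian current noise level (pA).
#' @param gap_threshold bistability criterion on the branch gap.
#' @param backward_overshoot how far above the top of the range (nS) the
#'   backward pass first settles.  The synchronized state must be the
#'   unique attractor at the starting point of the descending pass, which
#'   holds beyond the bistable band but not necessarily at its upper edge;
#'   the pass then steps down into the swept range carrying that state.
#' @param seed base seed.
#' @return An object of class `adex_hysteresis`: data.frame with `g_exc`,
#'   `R_forward`, `R_backward` (trial means), `gap`, `bistable`; attribute
#'   `trials` holds the per-trial matrices.
#' @export
hysteresis_sweep <- function(g_exc_range = c(0.35, 0.45), step = 0.01,
                             g = 3, r = 2, settle = 5000, measure = 5000,
                             trials = 2, N = 1000, p = 0.1,
                             noise_sigma = 0, gap_threshold = 0.4,
                             backward_overshoot = 0.1, seed = NULL) {
  stopifnot(step > 0, g_exc_range[2] >= g_exc_range[1])
  gx <- seq(g_exc_range[1], g_exc_range[2], by = step)
  # descending pass enters the range from above the bistable band
  over <- rev(seq(g_exc_range[2] + backward_overshoot, g_exc_range[2] + step,
                  by = -max(step, backward_overshoot / 3)))
  seeds <- matrix(make_seeds(seed, 4 * trials), ncol = 4)
  Rf <- matrix(NA_real_, trials, length(gx))
  Rb <- matrix(NA_real_, trials, length(gx))
  for (tr in seq_len(trials)) {
    top <- adex_topology(N, p, seed = seeds[tr, 1])
    Rf[tr, ] <- continuation_pass(top, gx, g, r, settle, measure,
                                  state_seed = seeds[tr, 2],
                                  noise_sigma = noise_sigma,
                                  noise_seed = seeds[tr, 4])
    bwd <- continuation_pass(top, c(rev(over), rev(gx)), g, r, settle,
                             measure, state_seed = seeds[tr, 3],
                             pre_settle = settle,
                             noise_sigma = noise_sigma,
                             noise_seed = seeds[tr, 4] + 1L)
    Rb[tr, ] <- rev(bwd[-seq_along(over)])
  }
  res <- data.frame(g_exc = gx, R_forward = colMeans(Rf),
                    R_backward = colMeans(Rb))
  res$gap <- res$R_backward - res$R_forward
  res$bistable <- res$gap > gap_threshold
  structure(res, class = c("adex_hysteresis", "data.frame"),
            trials = list(forward = Rf, backward = Rb),
            g = g, r = r, noise_sigma = noise_sigma,
            gap_threshold = gap_threshold)
}

# one continuation pass along gx (in given order); returns R_bar per step
continuation_pass <- function(top, gx, g, r, settle, measure, state_seed,
                              pre_settle = 0, noise_sigma = 0,
                              noise_seed = NULL, dt = 0.05) {
  par0 <- adex_params(g_exc = gx[1], g_inh = g * gx[1])
  state <- adex_init_state(top, par0, seed = state_seed)
  stim <- adex_stimulus(r = r, noise_sigma = noise_sigma)
  if (pre_settle > 0) {
    sim <- adex_simulate(top, par0, stim,
                         adex_config(dt = dt, duration = pre_settle,
                                     noise_seed = noise_seed),
                         init = state)
    state <- sim$final_state
  }
  out <- numeric(length(gx))
  for (k in seq_along(gx)) {
    par <- adex_params(g_exc = gx[k], g_inh = g * gx[k])
    ns <- if (is.null(noise_seed)) NULL else noise_seed + 2L * k
    sim <- adex_simulate(top, par, stim,
                         adex_config(dt = dt, duration = settle + measure,
                                     noise_seed = ns),
                         init = state)
    state <- sim$final_state
    t0 <- sim$raster$window[1]
    out[k] <- summary(sim, t_ini = t0 + settle,
                      t_fin = t0 + settle + measure)$R_bar
  }
  out
}

#' Locate the bistable operating point of a hysteresis sweep
#'
#' Picks the grid point with the largest branch gap and derives the
#' quantities the stimulation protocols need: the operating `g_exc`, the
#' order-parameter levels of the two branches there, and a
#' branch-separating threshold (their midpoint).  The exact location and
#' branch levels of the bistable band are emergent properties of the
#' simulated network, so protocols that require "a detected bistable cell"
#' should take their operating point from this function rather than assume
#' one.
#'
#' @param hyst an [hysteresis_sweep()] result.
#' @param min_R_high when positive, only grid points whose backward branch
#'   actually stayed synchronized (`R_backward >= min_R_high`) are
#'   considered, falling back to the whole grid if none qualifies.  A large
#'   gap at a point whose backward value is itself intermediate reflects a
#'   transiently decaying state rather than a standing synchronized branch,
#'   which stimulation protocols cannot operate on.
#' @return list with `g_exc`, `gap`, `R_low` (forward branch), `R_high`
#'   (backward branch), `threshold` (midpoint of the branches), `bistable`
#'   (whether the gap exceeds the sweep's criterion) and `candidates` (the
#'   considered grid points, ordered by decreasing gap).
#' @export
find_bistable_point <- function(hyst, min_R_high = 0) {
  d <- as.data.frame(hyst)
  cand <- d[d$R_backward >= min_R_high, , drop = FALSE]
  if (!nrow(cand)) cand <- d
  cand <- cand[order(-cand$gap), , drop = FALSE]
  list(g_exc = cand$g_exc[1], gap = cand$gap[1],
       R_low = cand$R_forward[1], R_high = cand$R_backward[1],
       threshold = (cand$R_forward[1] + cand$R_backward[1]) / 2,
       bistable = isTRUE(cand$bistable[1]),
       candidates = cand)
}

#' @export
print.adex_hysteresis <- function(x, ...) {
  cat(sprintf("Hysteresis sweep (g=%g, r=%g, sigma_noise=%g pA): %d grid points, %d bistable (max gap %.3f)\n",
              attr(x, "g"), attr(x, "r"), attr(x, "noise_sigma"),
              nrow(x), sum(x$bistable), max(x$gap)))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Sweep over inhibitory-neuron removal
#'
#' Grid of regime summaries over the relative inhibitory conductance `g`
#' and the fraction of inhibitory neurons removed; also records the maximum
#' of the instantaneous firing rate, which rises sharply when removal tips
#' the network into synchronized bursting.
#'
#' @param g_values values of `g = g_inh/g_exc`.
#' @param fractions fractions of the inhibitory population removed.
#' @param base study conditions, see [network_args()].
#' @param trials trials per cell.
#' @param seed base seed.
#' @return An `adex_sweep` data.frame with columns as in
#'   [sweep_parameter_space()] plus `fraction_removed` and `F_max`.
#' @export
removal_sweep <- function(g_values, fractions, base = network_args(),
                          trials = 1, seed = NULL) {
  grid <- expand.grid(g = g_values, fraction = fractions,
                      trial = seq_len(trials), KEEP.OUT.ATTRS = FALSE)
  seeds <- matrix(make_seeds(seed, 3 * nrow(grid)), ncol = 3)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    args <- base; args$g <- grid$g[k]
    out <- tryCatch(
      run_cell(args, seeds[k, 1], seeds[k, 2],
               fraction_removed = grid$fraction[k], removal_seed = seeds[k, 3]),
      error = function(e) e)
    row <- data.frame(g = args$g, r = args$r, g_exc = args$g_exc,
                      fraction_removed = grid$fraction[k],
                      trial = grid$trial[k],
                      topology_seed = seeds[k, 1], state_seed = seeds[k, 2],
                      R_bar = NA_real_, CV_bar = NA_real_, F_bar = NA_real_,
                      F_max = NA_real_, label = NA_character_,
                      error = NA_character_)
    if (inherits(out, "error")) {
      row$error <- conditionMessage(out)
    } else {
      s <- out$summary
      Ft <- instantaneous_rate(out$sim$raster, bin = 1,
                               t_ini = args$transient, t_fin = args$duration)
      row$R_bar <- s$R_bar; row$CV_bar <- s$CV_bar; row$F_bar <- s$F_bar
      row$F_max <- max(Ft$F); row$label <- s$label
    }
    row
  })
  structure(do.call(rbind, rows), class = c("adex_sweep", "data.frame"))
}

#' Probability of settling on the synchronized branch
#'
#' At fixed parameters, repeats the simulation from independent random
#' initial conditions and reports the fraction that end up synchronized
#' (`R_bar >= sync_threshold`).  Inside the bistable regime this probability
#' is strictly between 0 and 1.
#'
#' @param base study conditions, see [network_args()].
#' @param n_trials number of independent initial conditions.
#' @param sync_threshold order-parameter threshold.
#' @param seed base seed.
#' @return list with `probability`, binomial 95% confidence interval
#'   `conf_int`, `n_sync`, `n_trials` and the per-trial `R_bar` values.
#' @export
sync_probability <- function(base = network_args(g = 3), n_trials = 20,
                             sync_threshold = 0.9, seed = NULL) {
  stopifnot(n_trials >= 1)
  seeds <- matrix(make_seeds(seed, 2 * n_trials), ncol = 2)
  R <- vapply(seq_len(n_trials), function(k)
    run_cell(base, seeds[k, 1], seeds[k, 2])$summary$R_bar, numeric(1))
  n_sync <- sum(R >= sync_threshold)
  ci <- stats::binom.test(n_sync, n_trials)$conf.int
  list(probability = n_sync / n_trials, conf_int = as.numeric(ci),
       n_sync = n_sync, n_trials = n_trials, R_bar = R)
}

#' Noise sensitivity of the bistable interval
#'
#' Repeats the hysteresis sweep under increasing Gaussian current noise and
#' reports the width of the bistable interval per noise level; noise
#' shrinks the interval by kicking the network off the metastable branch.
#'
#' @param sigmas noise standard deviations (pA).
#' @param ... passed to [hysteresis_sweep()].
#' @param seed base seed (one derived seed per noise level).
#' @return An object of class `adex_noise_sweep`: list of
#'   [hysteresis_sweep()] results per sigma plus a `width` data.frame
#'   (`sigma`, `bistable_width` in nS, `n_bistable`).
#' @export
noise_sweep <- function(sigmas, ..., seed = NULL) {
  stopifnot(all(sigmas >= 0))
  seeds <- make_seeds(seed, length(sigmas))
  res <- lapply(seq_along(sigmas), function(k)
    hysteresis_sweep(..., noise_sigma = sigmas[k], seed = seeds[k]))
  names(res) <- paste0("sigma_", sigmas)
  step <- if (nrow(res[[1]]) > 1) diff(res[[1]]$g_exc[1:2]) else NA_real_
  width <- data.frame(sigma = sigmas,
                      n_bistable = vapply(res, function(h) sum(h$bistable), 1L))
  width$bistable_width <- width$n_bistable * step
  structure(list(sweeps = res, width = width), class = "adex_noise_sweep")
}

#' @export
print.adex_noise_sweep <- function(x, ...) {
  cat("Hysteresis under current noise:\n")
  print.data.frame(x$width, digits = 3)
  invisible(x)
}
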
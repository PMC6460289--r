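#' Brute-force reference integrator for micro-networks
#'
#' A deliberately plain R implementation of the coupled AdEx equations,
#' integrated with explicit Euler at a very small step (default 0.001 ms).
#' It recomputes the full synaptic sum from the adjacency matrix at every
#' step and serves as the ground-truth oracle for the compiled integrator in
#' convergence tests.  Restricted to micro-networks (N <= 3) and short
#' durations, where the tiny step is affordable.
#'
#' @param topology an [adex_topology()] with `N <= 3`.
#' @param params an [adex_params()].
#' @param stimulus an [adex_stimulus()] (noise unsupported here).
#' @param init initial [adex_init_state()] state.
#' @param duration simulated time (ms), at most 2000.
#' @param dt reference step (ms), default 0.001.
#' @param record_dt trace sampling interval (ms); 0 disables traces.
#' @return list with `raster` ([adex_raster()]), `final_state`, and `traces`
#'   (list with `times`, `V`, `w`, `g` matrices) when recording was on.
#' @export
reference_integrate <- function(topology, params, stimulus, init,
                                duration, dt = 0.001, record_dt = 0) {
  N <- topology$N
  stopifnot(N <= 3, duration <= 2000, dt > 0)
  if (stimulus$noise_sigma > 0) stop("reference integrator is noise-free")
  M <- topology$M
  vrev <- ifelse(topology$is_excitatory, params$V_rev_exc, params$V_rev_inh)
  gs_own <- ifelse(topology$is_excitatory, params$g_exc, params$g_inh)
  I0 <- drive_current(stimulus, params, init$a)
  scp_on <- stimulus$scp_onset
  scp_off <- stimulus$scp_onset + stimulus$scp_duration
  scp <- rep(0, N)
  if (stimulus$scp_amplitude != 0) {
    tg <- stimulus$scp_targets
    if (is.null(tg)) tg <- seq_len(N)
    scp[tg] <- stimulus$scp_amplitude
  }
  V <- init$V; w <- init$w; g <- init$g; a <- init$a
  t0 <- init$t
  nsteps <- floor(duration / dt + 1e-9)
  decay <- 1 - dt / params$tau_s
  cV <- dt / params$C_m; cw <- dt / params$tau_w

  if (N == 1L && record_dt == 0)
    return(reference_integrate_scalar(params, I0[1], scp[1], scp_on, scp_off,
                                      V, w, g, a, gs_own[1], t0, nsteps, dt,
                                      decay, cV, cw))
  spikes <- vector("list", N)
  for (j in seq_len(N)) spikes[[j]] <- numeric()

  rec <- record_dt > 0
  if (rec) {
    stride <- max(1L, round(record_dt / dt))
    ns <- nsteps %/% stride + 1L
    trt <- numeric(ns); trV <- matrix(0, ns, N)
    trw <- matrix(0, ns, N); trg <- matrix(0, ns, N)
    trt[1] <- t0; trV[1, ] <- V; trw[1, ] <- w; trg[1, ] <- g
    is <- 1L
  }

  for (step in seq_len(nsteps)) {
    t <- t0 + (step - 1) * dt
    # full synaptic sum: sum_j (vrev_j - V_i) M[i, j] g_j
    Isyn <- as.numeric(M %*% (vrev * g)) - V * as.numeric(M %*% g)
    Iext <- I0
    if (t >= scp_on && t < scp_off) Iext <- Iext + scp
    arg <- pmin((V - params$V_T) / params$Delta_T, params$exp_cap)
    dV <- -params$g_L * (V - params$E_L) +
      params$g_L * params$Delta_T * exp(arg) + Iext - w + Isyn
    Vn <- V + cV * dV
    w <- w + cw * (a * (V - params$E_L) - w)
    V <- Vn
    g <- g * decay
    fired <- which(V > params$V_thres)
    if (length(fired)) {
      for (j in fired) spikes[[j]] <- c(spikes[[j]], t + dt)
      V[fired] <- params$V_r
      w[fired] <- w[fired] + params$b
      g[fired] <- g[fired] + gs_own[fired]
    }
    if (!all(is.finite(V))) stop("reference integrator blow-up at t = ", t + dt)
    if (rec && step %% stride == 0L) {
      is <- is + 1L
      trt[is] <- t + dt; trV[is, ] <- V; trw[is, ] <- w; trg[is, ] <- g
    }
  }
  out <- list(
    raster = adex_raster(spikes, c(t0, t0 + nsteps * dt)),
    final_state = structure(list(t = t0 + nsteps * dt, V = V, w = w, g = g,
                                 a = a), class = "adex_state"))
  if (rec) out$traces <- list(times = trt[seq_len(is)],
                              V = trV[seq_len(is), , drop = FALSE],
                              w = trw[seq_len(is), , drop = FALSE],
                              g = trg[seq_len(is), , drop = FALSE])
  out
}

# single-neuron branch of the reference integrator: identical arithmetic,
# scalar loop (a tight R loop at dt = 0.001 ms is otherwise dominated by
# small-vector dispatch overhead)
reference_integrate_scalar <- function(params, I0, scp, scp_on, scp_off,
                                       V, w, g, a, gs_own, t0, nsteps, dt,
                                       decay, cV, cw) {
  gL <- params$g_L; EL <- params$E_L; DT <- params$Delta_T
  VT <- params$V_T; Vth <- params$V_thres; Vr <- params$V_r
  b <- params$b; cap <- params$exp_cap
  has_scp <- scp != 0 && scp_off > scp_on
  spikes <- numeric()
  for (step in seq_len(nsteps)) {
    t <- t0 + (step - 1) * dt
    arg <- (V - VT) / DT
    if (arg > cap) arg <- cap
    Iext <- I0
    if (has_scp && t >= scp_on && t < scp_off) Iext <- Iext + scp
    Vn <- V + cV * (-gL * (V - EL) + gL * DT * exp(arg) + Iext - w)
    w <- w + cw * (a * (V - EL) - w)
    V <- Vn
    g <- g * decay
    if (V > Vth) {
      spikes[length(spikes) + 1L] <- t0 + step * dt
      V <- Vr
      w <- w + b
      g <- g + gs_own
    }
    if (!is.finite(V)) stop("reference integrator blow-up at t = ", t + dt)
  }
  list(raster = adex_raster(list(spikes), c(t0, t0 + nsteps * dt)),
       final_state = structure(list(t = t0 + nsteps * dt, V = V, w = w,
                                    g = g, a = a), class = "adex_state"))
}

#' Deterministic micro-network fixtures
#'
#' Small fully specified networks used as oracles for the integrator.
#' Available ids:
#' \describe{
#'   \item{`single_rest`}{one neuron at rest, no drive: never fires.}
#'   \item{`single_tonic`}{one neuron at twice rheobase: tonic spiking.}
#'   \item{`pair_excitatory`}{two mutually coupled excitatory neurons with a
#'     strong synapse; one driven, one just below threshold.}
#'   \item{`triplet_ei`}{two excitatory neurons and one inhibitory neuron in
#'     a loop.}
#' }
#'
#' @param id fixture identifier.
#' @return list with `topology`, `params`, `stimulus`, `init` and
#'   `description`.
#' @export
micro_fixture <- function(id = c("single_rest", "single_tonic",
                                 "pair_excitatory", "triplet_ei")) {
  id <- match.arg(id)
  par <- adex_params()
  rest <- function(n, a = rep(0.2, n))
    structure(list(t = 0, V = rep(par$E_L, n), w = rep(0, n),
                   g = rep(0, n), a = a), class = "adex_state")
  switch(id,
    single_rest = list(
      topology = new_adex_topology(matrix(0L, 1, 1), TRUE),
      params = par, stimulus = adex_stimulus(r = 0), init = rest(1),
      description = "uncoupled neuron at rest; no spikes"),
    single_tonic = list(
      topology = new_adex_topology(matrix(0L, 1, 1), TRUE),
      params = par, stimulus = adex_stimulus(r = 2), init = rest(1),
      description = "uncoupled neuron at twice rheobase; tonic spiking"),
    pair_excitatory = {
      M <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
      st <- rest(2)
      st$V[2] <- -52       # this neuron fires first
      p2 <- adex_params(g_exc = 5)    # strong synapse (vs 0.4 nS at scale)
      list(topology = new_adex_topology(M, c(TRUE, TRUE)), params = p2,
           stimulus = adex_stimulus(r = 2), init = st,
           description = "mutually coupled excitatory pair, strong coupling")
    },
    triplet_ei = {
      # 1 -> 2 -> 3 -> 1, neuron 3 inhibitory
      M <- matrix(0L, 3, 3)
      M[2, 1] <- 1L; M[3, 2] <- 1L; M[1, 3] <- 1L
      list(topology = new_adex_topology(M, c(TRUE, TRUE, FALSE)),
           params = adex_params(g_exc = 5, g_inh = 15),
           stimulus = adex_stimulus(r = 2),
           init = rest(3, a = c(0.19, 0.2, 0.21)),
           description = "excitatory-excitatory-inhibitory ring")
    })
}

#' Synthetic spike rasters with known structure
#'
#' Generates rasters whose synchrony and firing-pattern statistics are known
#' by construction, for testing the measures independently of any network
#' simulation.
#'
#' Kinds:
#' \describe{
#'   \item{`periodic_synchronous`}{all neurons share identical periodic
#'     spike trains: order parameter 1, CV 0.}
#'   \item{`periodic_staggered`}{periodic trains with onsets evenly
#'     staggered across one period: phases are spread uniformly on the
#'     circle, order parameter ~ 0, CV 0.}
#'   \item{`poisson`}{independent homogeneous Poisson trains of the given
#'     `rate` (spikes/s): CV ~ 1, low order parameter.}
#'   \item{`burst_train`}{synchronized bursts: `spikes_per_burst` spikes at
#'     `intra_isi` ms spacing, bursts repeating every `burst_period` ms:
#'     CV well above 0.5, order parameter 1.}
#' }
#'
#' @param kind generator kind (see above).
#' @param N number of neurons.
#' @param window observation window (ms), length-2.
#' @param period spike period (ms) for the periodic kinds.
#' @param rate Poisson rate (spikes/s).
#' @param spikes_per_burst,intra_isi,burst_period burst-train shape.
#' @param seed RNG seed (Poisson only).
#' @return an [adex_raster()].
#' @export
synth_raster <- function(kind = c("periodic_synchronous", "periodic_staggered",
                                  "poisson", "burst_train"),
                         N = 100, window = c(0, 10000), period = 100,
                         rate = 10, spikes_per_burst = 5, intra_isi = 8,
                         burst_period = 500, seed = NULL) {
  kind <- match.arg(kind)
  t0 <- window[1]; t1 <- window[2]
  spikes <- switch(kind,
    periodic_synchronous = {
      s <- seq(t0 + period, t1, by = period)
      replicate(N, s, simplify = FALSE)
    },
    periodic_staggered = {
      offs <- (seq_len(N) - 1) / N * period
      lapply(offs, function(o) {
        s <- seq(t0 + o, t1, by = period)
        s[s > t0]
      })
    },
    poisson = {
      if (!is.null(seed)) set.seed(seed)
      lapply(seq_len(N), function(j) {
        n <- stats::rpois(1, rate * (t1 - t0) / 1000)
        sort(stats::runif(n, t0, t1))
      })
    },
    burst_train = {
      onsets <- seq(t0, t1 - (spikes_per_burst - 1) * intra_isi,
                    by = burst_period)
      s <- as.numeric(outer(seq_len(spikes_per_burst) - 1, onsets,
                            function(k, o) o + k * intra_isi))
      s <- sort(s[s >= t0 & s <= t1])
      replicate(N, s, simplify = FALSE)
    })
  adex_raster(spikes, window)
}

#' Regression bank of frozen simulation summaries
#'
#' A small library of seeded simulations and synthetic rasters whose summary
#' statistics were computed once and frozen.  Re-running any entry must
#' reproduce its raster bit-for-bit and its (R_bar, CV_bar, F_bar) to within
#' 1e-9; a drift signals an unintended change in the integrator or the
#' measures.  The four regime labels are all represented.
#'
#' @param entries optional character vector of entry names (default: all).
#' @return named list; each element has `summary` (current recomputation),
#'   `frozen` (stored values, `NULL` on first generation) and `raster`.
#' @export
regression_bank <- function(entries = NULL) {
  defs <- regression_bank_defs()
  if (!is.null(entries)) defs <- defs[entries]
  frozen <- regression_bank_frozen()
  lapply(stats::setNames(nm = names(defs)), function(nm) {
    r <- defs[[nm]]()
    list(summary = r$summary, raster = r$raster, frozen = frozen[[nm]])
  })
}

regression_bank_defs <- function() {
  net_entry <- function(g_inh, r, seed) function() {
    top <- adex_topology(200, p = 0.1, seed = seed)
    par <- adex_params(g_exc = 0.4, g_inh = g_inh)
    sim <- adex_simulate(top, par, adex_stimulus(r = r),
                         adex_config(dt = 0.05, duration = 4000),
                         state_seed = seed + 1)
    list(raster = sim$raster, summary = summary(sim, t_ini = 2000, t_fin = 4000))
  }
  synth_entry <- function(...) {
    args <- list(...)
    function() {
      ra <- do.call(synth_raster, args)
      list(raster = ra, summary = regime_summary(ra))
    }
  }
  list(
    net_weak_inhibition = net_entry(g_inh = 1.0, r = 2, seed = 101),
    net_strong_inhibition = net_entry(g_inh = 2.6, r = 2, seed = 102),
    synth_sync_spikes   = synth_entry(kind = "periodic_synchronous", N = 50,
                                      window = c(0, 5000), period = 100),
    synth_desync_spikes = synth_entry(kind = "periodic_staggered", N = 50,
                                      window = c(0, 5000), period = 100),
    synth_sync_bursts   = synth_entry(kind = "burst_train", N = 50,
                                      window = c(0, 5000)),
    synth_desync_bursts = synth_entry(kind = "poisson", N = 50,
                                      window = c(0, 20000), rate = 3,
                                      seed = 7)
  )
}

regression_bank_frozen <- function() {
  path <- system.file("extdata", "regression_bank.json", package = "adexnet")
  if (path == "") return(list())
  jsonlite::read_json(path, simplifyVector = TRUE)
}
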
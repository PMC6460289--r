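# Shared builders for small deterministic test objects.

small_net <- function(N = 40, p = 0.15, seed = 3, frac_exc = 0.8) {
  adex_topology(N, p, frac_exc = frac_exc, seed = seed)
}

# a raster built directly from spike-time vectors
raster_of <- function(..., window) {
  adex_raster(list(...), window)
}

# single uncoupled neuron as a 1-node topology
one_neuron <- function() adexnet:::new_adex_topology(matrix(0L, 1, 1), TRUE)

rest_state <- function(n, params = adex_params(), a = rep(0.2, n)) {
  structure(list(t = 0, V = rep(params$E_L, n), w = rep(0, n),
                 g = rep(0, n), a = a), class = "adex_state")
}

# dense-matrix explicit-Euler network integrator, written independently of
# the package core (recomputes the full synaptic sum every step); used as a
# cross-check oracle on small networks
dense_euler_sim <- function(top, par, stim, init, duration, dt) {
  N <- top$N; M <- top$M
  vrev <- ifelse(top$is_excitatory, par$V_rev_exc, par$V_rev_inh)
  gs_own <- ifelse(top$is_excitatory, par$g_exc, par$g_inh)
  I0 <- stim$r * adex_rheobase(par, init$a)
  V <- init$V; w <- init$w; g <- init$g
  decay <- 1 - dt / par$tau_s
  ev_t <- numeric(); ev_i <- integer()
  for (step in seq_len(round(duration / dt))) {
    Isyn <- as.numeric(M %*% (vrev * g)) - V * as.numeric(M %*% g)
    arg <- pmin((V - par$V_T) / par$Delta_T, par$exp_cap)
    dV <- -par$g_L * (V - par$E_L) + par$g_L * par$Delta_T * exp(arg) +
      I0 - w + Isyn
    Vn <- V + dt / par$C_m * dV
    w <- w + dt / par$tau_w * (init$a * (V - par$E_L) - w)
    V <- Vn
    g <- g * decay
    f <- which(V > par$V_thres)
    if (length(f)) {
      V[f] <- par$V_r; w[f] <- w[f] + par$b; g[f] <- g[f] + gs_own[f]
      ev_t <- c(ev_t, rep(step * dt, length(f))); ev_i <- c(ev_i, f)
    }
  }
  list(t = ev_t, i = ev_i, V = V, w = w, g = g)
}

spike_events <- function(raster) {
  n <- vapply(raster$spike_times, length, 1L)
  data.frame(t = unlist(raster$spike_times, use.names = FALSE),
             i = rep(seq_along(n), n))
}
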
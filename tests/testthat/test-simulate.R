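test_that("a neuron at rest with no input stays at rest", {
  par <- adex_params()
  st <- rest_state(1, par, a = 0)
  out <- adex_step(st, one_neuron(), par, adex_stimulus(r = 0), dt = 0.05)
  # E_L is not an exact fixed point (the exponential term contributes
  # ~ g_L*Delta_T*exp(-10)), but the drift over one step is sub-nanovolt
  expect_lt(abs(out$state$V - par$E_L), 1e-6)
  expect_length(out$spiked, 0)
  sim <- adex_simulate(one_neuron(), par, adex_stimulus(r = 0),
                       adex_config(dt = 0.05, duration = 1000), init = st)
  expect_equal(n_spikes(sim$raster), 0)
  expect_lt(abs(sim$final_state$V - par$E_L), 1e-3)
})

test_that("synaptic conductance decays with time constant tau_s", {
  par <- adex_params()
  st <- rest_state(1, par, a = 0)
  st$g <- 1
  out <- adex_step(st, one_neuron(), par, adex_stimulus(r = 0), dt = 0.05)
  expect_equal(out$state$g, 1 - 0.05 / par$tau_s)
  # over one tau_s of stepping, g ~ 1/e
  sim <- adex_simulate(one_neuron(), par, adex_stimulus(r = 0),
                       adex_config(dt = 0.01, duration = par$tau_s),
                       init = st)
  expect_equal(sim$final_state$g, exp(-1), tolerance = 2e-3)
})

test_that("synaptic drive evaluates the conductance-based sum", {
  top <- adexnet:::new_adex_topology(
    matrix(c(0L, 0L, 1L, 0L), 2, 2), c(TRUE, TRUE))  # neuron 2 presynaptic to 1
  par <- adex_params()
  st <- rest_state(2, par)
  expect_equal(synaptic_drive(st, top, par, 1), 0)
  st$g[2] <- 0.4
  # excitatory source, target at -70 mV: (0 - (-70)) * 0.4 = 28 pA
  expect_equal(synaptic_drive(st, top, par, 1), 28)
  expect_equal(synaptic_drive(st, top, par, 2), 0)  # no presynaptic input
  top$is_excitatory[2] <- FALSE
  st$g[2] <- 1.2
  # inhibitory source: (-80 + 70) * 1.2 = -12 pA
  expect_equal(synaptic_drive(st, top, par, 1), -12)
})

test_that("event-driven compiled core equals a dense-sum Euler oracle", {
  top <- small_net()
  par <- adex_params(g_exc = 2, g_inh = 6)
  st <- adex_init_state(top, par, seed = 4)
  stim <- adex_stimulus(r = 2)
  ref <- dense_euler_sim(top, par, stim, st, duration = 500, dt = 0.05)
  sim <- adex_simulate(top, par, stim,
                       adex_config(dt = 0.05, duration = 500), init = st)
  ev <- spike_events(sim$raster)
  o1 <- order(ref$t, ref$i); o2 <- order(ev$t, ev$i)
  expect_equal(length(ref$t), nrow(ev))
  expect_equal(ref$t[o1], ev$t[o2])
  expect_equal(ref$i[o1], ev$i[o2])
  expect_equal(ref$V, sim$final_state$V, tolerance = 1e-12)
  expect_equal(ref$w, sim$final_state$w, tolerance = 1e-12)
  expect_equal(ref$g, sim$final_state$g, tolerance = 1e-12)
})

test_that("simulation is deterministic and respects the raster contract", {
  top <- small_net()
  par <- adex_params(g_exc = 1, g_inh = 3)
  cfg <- adex_config(dt = 0.05, duration = 800)
  s1 <- adex_simulate(top, par, adex_stimulus(r = 2), cfg, state_seed = 6)
  s2 <- adex_simulate(top, par, adex_stimulus(r = 2), cfg, state_seed = 6)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$final_state, s2$final_state)
  # spikes strictly increasing per neuron, separated by > 2 dt, inside window
  for (s in s1$raster$spike_times) {
    if (length(s) > 1) expect_true(all(diff(s) > 2 * 0.05))
    if (length(s)) {
      expect_gte(min(s), s1$raster$window[1])
      expect_lte(max(s), s1$raster$window[2])
    }
  }
  # zero-duration run: empty raster, state unchanged
  st <- adex_init_state(top, par, seed = 1)
  s0 <- adex_simulate(top, par, adex_stimulus(r = 2),
                      adex_config(dt = 0.05, duration = 0), init = st)
  expect_equal(n_spikes(s0$raster), 0)
  expect_identical(s0$final_state$V, st$V)
})

test_that("uncoupled neurons at twice rheobase spike tonically", {
  top <- adex_topology(30, p = 0, seed = 2)   # M = 0
  par <- adex_params()
  sim <- adex_simulate(top, par, adex_stimulus(r = 2),
                       adex_config(dt = 0.05, duration = 3000),
                       state_seed = 3)
  cv <- isi_cv(sim$raster, t_ini = 1000)
  expect_true(all(cv$cv[!is.na(cv$cv)] < 0.5))
  expect_equal(cv$n_defined, 30)
})

test_that("halving dt moves single-neuron spike times by less than 1 ms", {
  par <- adex_params()
  st <- rest_state(1, par)
  run <- function(dt) adex_simulate(one_neuron(), par, adex_stimulus(r = 2),
                                    adex_config(dt = dt, duration = 1000),
                                    init = st)$raster$spike_times[[1]]
  a <- run(0.05); b <- run(0.025)
  n <- min(length(a), length(b))
  expect_lte(abs(length(a) - length(b)), 1)
  expect_true(all(abs(a[seq_len(n)] - b[seq_len(n)]) < 1))
})

test_that("micro-networks match the dt=0.001 ms reference integrator", {
  for (id in c("single_rest", "single_tonic", "pair_excitatory",
               "triplet_ei")) {
    fx <- micro_fixture(id)
    ref <- reference_integrate(fx$topology, fx$params, fx$stimulus, fx$init,
                               duration = 1000, dt = 0.001)
    sim <- adex_simulate(fx$topology, fx$params, fx$stimulus,
                         adex_config(dt = 0.05, duration = 1000),
                         init = fx$init)
    nref <- vapply(ref$raster$spike_times, length, 1L)
    nsim <- vapply(sim$raster$spike_times, length, 1L)
    expect_true(all(abs(nref - nsim) <= 1),
                label = sprintf("%s spike counts (ref %s vs sim %s)", id,
                                toString(nref), toString(nsim)))
  }
  # the rest fixture is silent, the tonic one is not
  expect_equal(n_spikes(adex_simulate(
    micro_fixture("single_rest")$topology, adex_params(),
    adex_stimulus(r = 0), adex_config(dt = 0.05, duration = 1000),
    init = rest_state(1))$raster), 0)
})

test_that("excitatory coupling propagates a spike to the partner neuron", {
  fx <- micro_fixture("pair_excitatory")
  ref <- reference_integrate(fx$topology, fx$params, fx$stimulus, fx$init,
                             duration = 500, dt = 0.001)
  t1 <- ref$raster$spike_times[[1]][1]
  t2 <- ref$raster$spike_times[[2]][1]
  expect_false(is.na(t1) || is.na(t2))
  expect_lt(abs(t1 - t2), 10)  # follower fires within 10 ms of the leader
})

test_that("a step exceeding the synaptic time constant is rejected", {
  par <- adex_params()
  st <- rest_state(1, par)
  expect_error(
    adex_simulate(one_neuron(), par, adex_stimulus(r = 5),
                  adex_config(dt = 4, duration = 100), init = st),
    "dt too large")
})

test_that("the square pulse and its window are honoured", {
  par <- adex_params()
  st <- rest_state(1, par)
  # sub-rheobase drive, strong pulse between 100 and 150 ms
  stim <- adex_stimulus(r = 0.5, scp_amplitude = 400, scp_duration = 50,
                        scp_onset = 100)
  sim <- adex_simulate(one_neuron(), par, stim,
                       adex_config(dt = 0.05, duration = 400), init = st)
  sp <- sim$raster$spike_times[[1]]
  expect_gt(length(sp), 0)
  expect_true(all(sp >= 100 & sp <= 160))  # few ms of lag after switch-off
  # amplitude 0 pulse changes nothing
  s0 <- adex_simulate(one_neuron(), par, adex_stimulus(r = 0.5),
                      adex_config(dt = 0.05, duration = 400), init = st)
  expect_equal(n_spikes(s0$raster), 0)
})
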
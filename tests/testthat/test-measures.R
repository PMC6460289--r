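test_that("spike phases interpolate linearly between spikes", {
  r <- raster_of(c(100, 200, 400), window = c(0, 500))
  ph <- spike_phases(r, sample_dt = 50)
  t <- ph$times
  # at a spike time, phase = 2*pi*m exactly
  expect_equal(ph$psi[1, t == 100], 0)
  expect_equal(ph$psi[1, t == 200], 2 * pi)
  # midway between spikes m and m+1: 2*pi*m + pi
  expect_equal(ph$psi[1, t == 150], pi)
  expect_equal(ph$psi[1, t == 300], 2 * pi + pi)
  # outside [first, last) the phase is masked
  expect_false(any(ph$valid[1, t < 100 | t >= 400]))
  expect_true(all(ph$valid[1, t >= 100 & t < 400]))
  # a neuron with < 2 spikes is entirely masked, without error
  r2 <- adex_raster(list(c(100, 200), 250), c(0, 500))
  ph2 <- spike_phases(r2, sample_dt = 50)
  expect_false(any(ph2$valid[2, ]))
})

test_that("periodic trains have constant unwrapped phase slope 2*pi/T", {
  r <- raster_of(seq(100, 900, by = 100), window = c(0, 1000))
  ph <- spike_phases(r, sample_dt = 10)
  ok <- ph$valid[1, ]
  slopes <- diff(ph$psi[1, ok]) / 10
  expect_equal(slopes, rep(2 * pi / 100, sum(ok) - 1))
})

test_that("order parameter obeys the classical identities", {
  # identical phases across neurons: R = 1
  r <- synth_raster("periodic_synchronous", N = 20, window = c(0, 2000),
                    period = 100)
  op <- order_parameter(spike_phases(r))
  expect_true(all(abs(op$R[!is.na(op$R)] - 1) < 1e-12))
  # phases uniformly spread on the circle: R = 0 (roots of unity)
  rs <- synth_raster("periodic_staggered", N = 20, window = c(0, 2000),
                     period = 100)
  ops <- order_parameter(spike_phases(rs))
  full <- ops$n_valid == 20
  expect_true(any(full))
  expect_true(all(ops$R[full] < 1e-12))
  # two neurons in antiphase: R = 0
  r2 <- adex_raster(list(seq(100, 900, 100), seq(150, 950, 100)), c(0, 1000))
  op2 <- order_parameter(spike_phases(r2, sample_dt = 10))
  both <- op2$n_valid == 2
  expect_true(all(op2$R[both] < 1e-9))
})

test_that("time averaging of R is trapezoidal and validates its window", {
  s <- structure(list(times = seq(0, 1000, 10), R = rep(0.42, 101),
                      Phi = numeric(101), n_valid = rep(5L, 101)),
                 class = "adex_order_parameter")
  expect_equal(time_average_R(s, 0, 1000), 0.42)
  s$R <- s$times / 1000          # R(t) = t on [0, 1]: average 1/2
  expect_equal(time_average_R(s, 0, 1000), 0.5)
  expect_error(time_average_R(s, 800, 200), "t_fin")
})

test_that("ISI coefficient of variation matches hand-computed values", {
  # perfectly periodic: CV = 0
  r <- raster_of(seq(100, 2000, 100), window = c(0, 2000))
  expect_equal(isi_cv(r)$cv_bar, 0)
  # alternating 1/3 ms intervals: mean 2, population sd 1, CV = 0.5
  alt <- raster_of(cumsum(c(10, rep(c(1, 3), 10))), window = c(0, 100))
  expect_equal(isi_cv(alt)$cv_bar, 0.5)
  # fewer than 3 spikes: excluded; all excluded is an error
  r2 <- adex_raster(list(seq(100, 2000, 100), c(100, 200)), c(0, 2000))
  cv <- isi_cv(r2)
  expect_true(is.na(cv$cv[2]))
  expect_equal(cv$n_defined, 1)
  expect_error(isi_cv(adex_raster(list(c(1, 2)), c(0, 10))), "undefined")
})

test_that("CV is invariant under time rescaling", {
  set.seed(31)
  s <- cumsum(rexp(50, 0.1))
  r1 <- adex_raster(list(s), c(0, max(s)))
  r5 <- adex_raster(list(5 * s), c(0, 5 * max(s)))
  expect_equal(isi_cv(r1)$cv_bar, isi_cv(r5)$cv_bar)
})

test_that("a Poisson train has CV close to 1", {
  r <- synth_raster("poisson", N = 30, window = c(0, 200000), rate = 10,
                    seed = 17)
  expect_equal(isi_cv(r)$cv_bar, 1, tolerance = 0.1)
})

test_that("instantaneous rate conserves the spike count", {
  r <- synth_raster("poisson", N = 50, window = c(0, 5000), rate = 20,
                    seed = 9)
  Ft <- instantaneous_rate(r, bin = 1)
  expect_equal(sum(Ft$F) * 50, n_spikes(r))
  # all neurons spiking once in one bin gives F = 1
  r1 <- adex_raster(rep(list(500.2), 40), c(0, 1000))
  F1 <- instantaneous_rate(r1, bin = 1)
  expect_equal(max(F1$F), 1)
  expect_equal(sum(F1$F > 0), 1)
  # empty raster: all-zero series
  F0 <- instantaneous_rate(adex_raster(rep(list(numeric()), 5), c(0, 100)))
  expect_true(all(F0$F == 0))
})

test_that("mean firing rate is the reciprocal mean ISI in spikes/s", {
  # every neuron periodic at 100 ms: 10 spikes/s
  r <- synth_raster("periodic_synchronous", N = 10, window = c(0, 2000),
                    period = 100)
  expect_equal(mean_firing_rate(r), 10)
  # two neurons with mean ISIs 50 and 150 ms: mean ISI 100 -> 10 spikes/s
  r2 <- adex_raster(list(seq(50, 1000, 50), seq(150, 1000, 150)), c(0, 1000))
  expect_equal(mean_firing_rate(r2), 10)
  expect_error(mean_firing_rate(adex_raster(list(100), c(0, 200))),
               "undefined")
})

test_that("regime classification combines the two thresholds", {
  expect_equal(classify_regime(0.95, 0.3), "synchronized_spikes")
  expect_equal(classify_regime(0.95, 0.7), "synchronized_bursts")
  expect_equal(classify_regime(0.3, 0.3), "desynchronized_spikes")
  expect_equal(classify_regime(0.3, 0.9), "desynchronized_bursts")
  # boundary conventions: sync at R >= threshold, burst at CV >= 0.5
  expect_equal(classify_regime(0.9, 0.5), "synchronized_bursts")
  expect_equal(classify_regime(0.85, 0.2, sync_threshold = 0.8),
               "synchronized_spikes")
  expect_error(classify_regime(NA, 0.3), "finite")
})

test_that("streaming regime summary equals the composed pipeline", {
  sim <- adex_simulate(small_net(), adex_params(g_exc = 1, g_inh = 3),
                       adex_stimulus(r = 2),
                       adex_config(dt = 0.05, duration = 2000),
                       state_seed = 8)
  s <- regime_summary(sim$raster, t_ini = 500, t_fin = 2000)
  clip <- clip_raster(sim$raster, 500, 2000)
  R_ref <- time_average_R(order_parameter(spike_phases(clip)))
  expect_equal(s$R_bar, R_ref, tolerance = 1e-12)
  expect_gte(s$R_bar, 0); expect_lte(s$R_bar, 1)
  expect_equal(s$CV_bar, isi_cv(sim$raster, 500, 2000)$cv_bar)
  expect_equal(s$F_bar, mean_firing_rate(sim$raster, 500, 2000))
})

test_that("identical spike times give R = 1 and shuffling lowers R", {
  r <- synth_raster("periodic_synchronous", N = 40, window = c(0, 4000),
                    period = 80)
  expect_equal(regime_summary(r)$R_bar, 1)
  # nearly synchronous trains (distinct times), then spike times shuffled
  # across neurons with marginal counts preserved
  near <- adex_raster(lapply(1:40, function(j) seq(100, 3900, 80) + 0.1 * j),
                      c(0, 4000))
  s1 <- regime_summary(near)
  expect_gt(s1$R_bar, 0.95)
  all_t <- unlist(near$spike_times)
  set.seed(5)
  shuf <- split(sample(all_t), rep(1:40, each = length(all_t) / 40))
  rs <- adex_raster(lapply(shuf, sort), c(0, 4000))
  expect_lt(regime_summary(rs)$R_bar, s1$R_bar)
})

test_that("synaptic input series reconstructs the conductance sum", {
  # neuron 2 (excitatory) presynaptic to neuron 1; no dynamics needed:
  # feed hand-made traces
  top <- adexnet:::new_adex_topology(matrix(c(0L, 0L, 1L, 0L), 2, 2),
                                     c(TRUE, TRUE))
  par <- adex_params()
  traces <- list(times = 0:2,
                 V = matrix(-70, 3, 2), g = cbind(0, c(0, 0.4, 0.2)))
  out <- synaptic_input_series(traces, top, par)
  # (0 - (-70)) * g2: 0, 28, 14 pA onto neuron 1; nothing onto neuron 2
  expect_equal(out$I_isc[, 1], c(0, 28, 14))
  expect_equal(out$I_isc[, 2], c(0, 0, 0))
  expect_equal(out$I_syn, c(0, 14, 7))
  # all conductances zero -> identically zero
  traces$g[] <- 0
  expect_true(all(synaptic_input_series(traces, top, par)$I_syn == 0))
  expect_error(synaptic_input_series(NULL, top, par), "traces")
})

test_that("recorded population synaptic input matches the direct sum", {
  top <- small_net(N = 20, p = 0.3)
  par <- adex_params(g_exc = 1, g_inh = 3)
  st <- adex_init_state(top, par, seed = 2)
  sim <- adex_simulate(top, par, adex_stimulus(r = 2),
                       adex_config(dt = 0.05, duration = 300, record_dt = 1,
                                   record_neurons = 1:20,
                                   record_isyn = TRUE), init = st)
  rec <- synaptic_input_series(sim$traces, top, par)
  expect_equal(rec$I_syn, as.numeric(sim$traces$I_syn), tolerance = 1e-10)
  expect_equal(rec$I_isc, unclass(sim$traces$I_isc), tolerance = 1e-10,
               ignore_attr = TRUE)
})
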
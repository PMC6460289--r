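---
title: "Methods: AdEx network simulation and synchronization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AdEx network simulation and synchronization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`adexnet` simulates a random directed network of $N$ adaptive exponential
integrate-and-fire (AdEx) neurons coupled by conductance-based synapses.
Each neuron $i$ carries a membrane potential $V_i$ (mV), an adaptation
current $w_i$ (pA) and a synaptic conductance $g_i$ (nS):

$$
C_m \frac{dV_i}{dt} = -g_L (V_i - E_L)
 + g_L \Delta_T \exp\!\Big(\frac{V_i - V_T}{\Delta_T}\Big)
 + I_i + \Gamma_i(t) - w_i
 + \sum_j (V^{rev}_j - V_i)\, M_{ij}\, g_j ,
$$
$$
\tau_w \frac{dw_i}{dt} = a_i (V_i - E_L) - w_i , \qquad
\tau_s \frac{dg_i}{dt} = -g_i .
$$

When $V_i$ exceeds the detection cutoff $V_{thres}$ the neuron is recorded
as spiking and reset: $V_i \to V_r$, $w_i \to w_i + b$, and its own
conductance is incremented by $g_{exc}$ (excitatory neurons) or $g_{inh}$
(inhibitory neurons).  $M_{ij} = 1$ means neuron $j$ is presynaptic to
neuron $i$; the reversal potential $V^{rev}_j$ is selected by the
*presynaptic* class (0 mV excitatory, −80 mV inhibitory).  Units are pF,
nS, mV, pA and ms throughout, so $nS \cdot mV = pA$ and $pA/pF = mV/ms$.

Default constants (see `adex_params()`): $C_m = 200$ pF, $g_L = 12$ nS,
$E_L = -70$ mV, $\Delta_T = 2$ mV, $V_T = -50$ mV, $V_r = -58$ mV,
$\tau_w = 300$ ms, $\tau_s = 2.728$ ms, $b = 70$ pA, and a heterogeneous
subthreshold adaptation $a_i \sim U[0.19, 0.21]$ nS.  The inhibitory
strength is summarised by the ratio $g = g_{inh}/g_{exc}$.

**Spike-detection cutoff.**  $V_{thres}$ only has to sit far enough above
$V_T$ that the exponential blow-up makes the crossing time insensitive to
its exact value; we use $V_T + 5\Delta_T = -40$ mV (configurable).  Beyond
this point the upstroke covers several mV per 0.05 ms step, so moving the
cutoff shifts spike times by well under one step.

**Drive.**  Each neuron receives a constant current expressed relative to
its own rheobase, $I_i = r \cdot I^{rheo}(a_i)$, with the closed form
$I^{rheo}(a) = (g_L + a)(V^* - E_L) - g_L \Delta_T e^{(V^* - V_T)/\Delta_T}$
at $V^* = V_T + \Delta_T \log(1 + a/g_L)$ — the loss point of the stable
subthreshold fixed point.  We use the per-neuron $a_i$ in this expression
(the drive is defined per neuron); with $a_i$ spread over [0.19, 0.21] nS
the resulting currents differ by under 0.3 pA, so this choice is
practically indistinguishable from normalising by a single population
rheobase.  Note that a neuron started from rest can fire one transient
spike marginally below this rheobase because $w$ lags its steady state;
the package tests therefore probe the rheobase by bisection on *sustained*
firing.

## Integration

The integrator (compiled C++, `adex_simulate()`) is explicit Euler with a
default step of $dt = 0.05$ ms.  The choices that matter:

* **Event-driven synaptic bookkeeping.**  All conductances share
  $\tau_s$, so the per-neuron summed presynaptic conductance (split by
  source class) obeys the same per-step linear decay as each $g_j$ and
  only changes when a presynaptic neuron fires.  This is an exact
  algebraic reorganisation of the synaptic sum under the Euler scheme —
  asserted in the tests against a dense-matrix re-implementation — and
  reduces the per-step cost from O(edges) to O(N).
* **Exponential clamp.**  The argument of the exponential term is capped
  at +30.  The cap can only bind at voltages far above $V_{thres}$, where
  the same step already triggers the reset, so it affects overflow safety
  only.
* **Reset rule.**  After each step, every neuron above $V_{thres}$ is
  reset; a neuron can therefore fire at most once per step by
  construction, and the count of resets equals the raster size exactly.
* **Reference oracle.**  `reference_integrate()` is a deliberately plain
  R implementation (dense synaptic sum recomputed each step) run at
  $dt = 0.001$ ms on micro-networks of up to 3 neurons.  The test suite
  requires the production integrator at $dt = 0.05$ ms to reproduce its
  spike counts within ±1 over 1 s, and the oracle to agree with itself
  exactly under step halving.
* **Noise.**  Optional Gaussian current noise is drawn independently per
  neuron per step with standard deviation `noise_sigma` in pA.  By
  default the amplitude is *not* rescaled with $dt$ (pulse-like current
  noise, matching the pA units of the noise level); a
  `noise_dt_invariant` switch rescales by $1/\sqrt{dt}$ for users who
  want a step-size-invariant noise process instead.

## Synchronization and firing-pattern measures

* **Spike phases** (`spike_phases()`): linear interpolation
  $\psi_j(t) = 2\pi m + 2\pi (t - t_{j,m})/(t_{j,m+1} - t_{j,m})$ between
  consecutive spikes.  A phase exists only between a neuron's first and
  last spike; samples outside are masked rather than extrapolated.
* **Order parameter** (`order_parameter()`):
  $R(t) e^{i\Phi(t)} = \langle e^{i\psi_j(t)}\rangle_j$, averaged over the
  neurons with a defined phase at $t$.  Normalising by the count of valid
  neurons (rather than $N$) avoids undefined phases at window edges; with
  windows of many seconds and tonically active networks the two
  normalisations are indistinguishable, and the tests pin the identities
  $R = 1$ for identical phases and $R = 0$ for uniformly spread phases.
  `time_average_R()` is a trapezoidal average, $\bar R$.
* **Coefficient of variation** (`isi_cv()`): per neuron,
  $CV_i = \sigma_{ISI}/\overline{ISI}$ with the population
  (divide-by-$n$) standard deviation; neurons with fewer than 3 spikes in
  the window have no defined CV and are excluded from $\overline{CV}$.
* **Rates**: `instantaneous_rate()` bins spikes at 1 ms and reports the
  population fraction per bin $F(t)$ (so its sum times $N$ is the spike
  count); `mean_firing_rate()` is $1000 / \overline{ISI}$ in spikes/s with
  $\overline{ISI}$ the across-neuron mean of per-neuron mean ISIs.
* **Regime label** (`classify_regime()`): *bursting* iff
  $\overline{CV} \ge 0.5$; *synchronized* iff $\bar R \ge 0.9$ (the
  conventional boundary for these regimes; configurable, since the
  saturation value of $\bar R$ in the synchronized state depends on burst
  shape and network size).

## Experiment protocols and their design choices

All protocols run the standard study conditions by default: $N = 1000$,
connection probability $p = 0.1$, 80% excitatory, $g_{exc} = 0.4$ nS,
drive $r$ times rheobase.  The analysis window is 10 s after a 10 s
transient (`network_args()`); this desk-scale choice keeps a full
parameter sweep within minutes on one core while leaving the regime
statistics stable to within a few percent of longer runs, and every
function accepts longer windows.

**Hysteresis / bistability** (`hysteresis_sweep()`).  $g_{exc}$ is swept
across [0.35, 0.45] nS in 0.01 nS steps in both directions, carrying the
final network state between steps; each step settles 5 s and measures
$\bar R$ over 5 s, with two independent trials averaged.  The backward
pass first settles *beyond* the top of the range (overshoot 0.1 nS,
configurable): the descending branch must enter the range already on the
synchronized attractor, which is only guaranteed beyond the bistable
band, not at its edge.  A grid point is flagged bistable when
$\bar R_{backward} - \bar R_{forward} > 0.4$.

**Operating point for stimulation** (`find_bistable_point()`).  The
square-pulse protocols need a point where both branches are stable over
tens of seconds.  The exact location and width of the bistable band are
emergent properties of the simulated network — they shift with network
realisation, window length and integration detail — so the package
*detects* its operating point from its own hysteresis sweep instead of
hard-coding one: the grid point with the largest branch gap among those
whose backward branch actually stayed synchronized, with the midpoint of
the two branch levels used as the branch-separating threshold for
detectors and settling verification.  In this implementation the detected
point typically sits at the upper end of the swept range, and the
synchronized branch there saturates near $\bar R \approx 0.88$; both are
documented outcomes of the package's own dynamics, which is why the
thresholds are calibrated rather than fixed at 0.9.

**Branch preparation** (`settle_branch()`).  The desynchronized branch is
reached by settling a random initial condition at the operating point
(the high-probability outcome inside the bistable region); the
synchronized branch by settling at $g_{exc} + 0.15$ nS and continuing at
the target.  Because a random initial condition occasionally lands on the
other branch, the preparation verifies the settled branch against the
calibrated threshold and redraws the initial condition if needed.

**Square current pulses** (`scp_trigger()`, `scp_suppress()`).  A pulse
of amplitude $A_I$ and duration $T_I$ is applied to all neurons
(trigger, from the desynchronized branch) or to a random fraction
(suppression, from the synchronized branch).  After switch-off, a sliding
1 s window (step 0.5 s) classifies each window as synchronized bursting
iff its $\bar R$ reaches the calibrated threshold *and* its
$\overline{CV} \ge 0.5$; the reported persistence is the length of the
initial contiguous run of such windows within a 20 s observation window.
Persistence 0 means suppression succeeded.

**Other protocols.**  `sweep_parameter_space()` grids $(g, r)$ or
$(g, g_{exc})$ cells with fresh seeds per cell; `removal_sweep()` deletes
a random subset of inhibitory neurons with all incident edges and tracks
$\max F(t)$; `sync_probability()` repeats a cell from independent random
initial conditions (default 20 trials, binomial CI — the underlying trial
count is a free choice here); `noise_sweep()` repeats the hysteresis
sweep under increasing current noise and reports the bistable-interval
width per noise level; `nullcline_curve()` evaluates
$w_{null}(V) = -g_L(V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} + I$,
whose single interior extremum is a *minimum* at $V = V_T$, and
`phase_plane_trace()` tests whether a recorded trajectory dwells in the
region above the nullcline (where $dV/dt < 0$).  A 5 pA margin is
required to count as dwelling: a resting neuron sits exactly on its
nullcline, so a strict inequality would classify numerical jitter as
burst-like.

## Synthetic rasters and what the tests do and do not show

`synth_raster()` generates rasters with statistics known by construction:
identical periodic trains ($\bar R = 1$, $CV = 0$), trains staggered
evenly over one period (roots-of-unity cancellation, $\bar R \approx 0$),
independent Poisson trains ($CV \approx 1$), and synchronized burst
trains whose CV follows directly from the ISI multiset (e.g. intervals
$\{8,8,8,8,468\}$ ms give $CV = 1.84$).  These fixtures validate every
measure without any network simulation, and `regression_bank()` freezes
seeded simulation summaries to 10^-9 for change detection.

What passing tests show: the integrator solves the stated equations
(oracle agreement), the measures compute the stated statistics
(construction fixtures), and the protocols reproduce the qualitative
phenomenology — inhibition-controlled synchronization, a hysteretic
transition with a coexistence region, pulse-triggered and
pulse-suppressed switching between branches.  What they do not show: the
synthetic generators make no attempt to mimic real cortical recordings
(no refractory structure beyond the model's own, no rate
inhomogeneities, no measurement noise), and quantitative boundaries —
the exact $g_{exc}$ extent of the bistable band, the saturation level of
$\bar R$ in the burst state, the minimal suppressive target fraction —
depend measurably on network size, window length and integrator detail.
Desk-scale runs here use 20 s simulations; conclusions at the boundary of
two regimes should be checked with longer windows via the configuration.

## Known limitations

* Explicit Euler at 0.05 ms is the field-standard compromise for this
  model; spike times converge to within 1 ms over 1 s under step halving,
  but metastable escape times near the bistable boundary remain
  step-sensitive.
* No synaptic delays, autapses or plasticity; one conductance variable
  per neuron (shared by all outgoing synapses).
* The hysteresis protocol's short per-step settling (5 s) deliberately
  measures finite-observation hysteresis; metastable states with escape
  times beyond the settling window count as bistable, which is the
  standard operational reading of a hysteresis experiment.
* Traces are recorded at a configurable stride into plain CSV; there is
  no binary trace container.
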
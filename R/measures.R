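#' Linearly interpolated spike phases
#'
#' Assigns each neuron a phase that advances by 2*pi between consecutive
#' spikes: `psi_j(t) = 2*pi*m + 2*pi*(t - t_{j,m}) / (t_{j,m+1} - t_{j,m})`
#' for `t` between the m-th and (m+1)-th spike.  The phase is defined only
#' between a neuron's first and last spike; samples outside that range (and
#' all samples of neurons with fewer than two spikes) are masked invalid.
#'
#' @param raster an [adex_raster()].
#' @param sample_dt sampling interval of the phase grid (ms).
#' @param t_ini,t_fin grid limits (ms); default the raster window.
#' @return An object of class `adex_phases`: list with `times` (length S),
#'   `psi` (N x S matrix, radians; NA where invalid) and `valid` (N x S
#'   logical matrix).
#' @export
spike_phases <- function(raster, sample_dt = 1, t_ini = raster$window[1],
                         t_fin = raster$window[2]) {
  stopifnot(sample_dt > 0, t_fin >= t_ini)
  times <- seq(t_ini, t_fin, by = sample_dt)
  N <- length(raster$spike_times)
  S <- length(times)
  psi <- matrix(NA_real_, N, S)
  valid <- matrix(FALSE, N, S)
  for (j in seq_len(N)) {
    ph <- neuron_phase(raster$spike_times[[j]], times)
    if (is.null(ph)) next
    psi[j, ] <- ph
    valid[j, ] <- !is.na(ph)
  }
  structure(list(times = times, psi = psi, valid = valid),
            class = "adex_phases")
}

# phase of a single neuron on a sample grid; NULL if < 2 spikes
neuron_phase <- function(s, times) {
  if (length(s) < 2L) return(NULL)
  # interval index m: s[m] <= t < s[m+1]; phase defined on [s[1], s[last])
  m <- findInterval(times, s)
  ok <- m >= 1L & times < s[length(s)]
  ph <- rep(NA_real_, length(times))
  mi <- m[ok]
  ph[ok] <- 2 * pi * (mi - 1) +
    2 * pi * (times[ok] - s[mi]) / (s[mi + 1L] - s[mi])
  ph
}

#' Kuramoto order parameter of a phase series
#'
#' The complex order parameter is the centroid of the unit phase vectors,
#' `R(t) exp(i Phi(t)) = (1/N_valid(t)) * sum_j exp(i psi_j(t))`, taken over
#' the neurons whose phase is defined at time t.  `R` is 0 for fully
#' desynchronized and 1 for fully synchronized populations.
#'
#' @param phases an [spike_phases()] object.
#' @return An object of class `adex_order_parameter`: list with `times`, `R`
#'   (amplitude, NA where no neuron has a defined phase), `Phi` (angle,
#'   radians) and `n_valid`.
#' @export
order_parameter <- function(phases) {
  z <- exp(1i * phases$psi)
  z[!phases$valid] <- 0
  nv <- colSums(phases$valid)
  centroid <- colSums(z) / ifelse(nv > 0, nv, NA_real_)
  structure(list(times = phases$times, R = Mod(centroid),
                 Phi = Arg(centroid), n_valid = nv),
            class = "adex_order_parameter")
}

#' Time-averaged order parameter
#'
#' Trapezoidal average of `R(t)` over the window `[t_ini, t_fin]`; samples
#' where `R` is undefined (no valid neuron) are dropped.
#'
#' @param series an [order_parameter()] object.
#' @param t_ini,t_fin averaging window (ms).
#' @return scalar time average of R.
#' @export
time_average_R <- function(series, t_ini = min(series$times),
                           t_fin = max(series$times)) {
  if (t_fin <= t_ini) stop("empty averaging window: t_fin must exceed t_ini")
  sel <- series$times >= t_ini & series$times <= t_fin & !is.na(series$R)
  if (sum(sel) < 2L) stop("fewer than two valid samples in averaging window")
  trapz_mean(series$times[sel], series$R[sel])
}

trapz_mean <- function(t, y) {
  dt <- diff(t)
  sum(dt * (y[-1] + y[-length(y)]) / 2) / (t[length(t)] - t[1])
}

#' Inter-spike-interval coefficient of variation
#'
#' For each neuron, `CV_i = sigma_ISI / mean_ISI` of its inter-spike
#' intervals within the analysis window, using the population (divide-by-n)
#' standard deviation.  Neurons with fewer than `min_spikes` spikes (fewer
#' than two intervals) have undefined CV and are excluded from the mean.
#' `CV >= 0.5` is the bursting signature; tonic spiking gives `CV < 0.5`.
#'
#' @param raster an [adex_raster()].
#' @param t_ini,t_fin analysis window (ms); default the raster window.
#' @param min_spikes minimum spikes for a defined per-neuron CV (default 3).
#' @return list with `cv` (per-neuron, NA where undefined), `cv_bar` (mean
#'   over defined neurons) and `n_defined`.
#' @examples
#' r <- adex_raster(list(cumsum(c(10, rep(c(1, 3), 10)))), c(0, 100))
#' isi_cv(r)$cv_bar   # alternating 1/3 ms intervals: CV = 0.5
#' @export
isi_cv <- function(raster, t_ini = raster$window[1],
                   t_fin = raster$window[2], min_spikes = 3L) {
  cv <- vapply(raster$spike_times, function(s) {
    s <- s[s >= t_ini & s <= t_fin]
    if (length(s) < min_spikes) return(NA_real_)
    isi <- diff(s)
    m <- mean(isi)
    sqrt(mean((isi - m)^2)) / m
  }, numeric(1))
  if (all(is.na(cv)))
    stop("mean CV undefined: no neuron has >= ", min_spikes, " spikes in window")
  list(cv = cv, cv_bar = mean(cv, na.rm = TRUE), n_defined = sum(!is.na(cv)))
}

#' Instantaneous population firing rate
#'
#' Fraction of the population that fires per time bin:
#' `F(t) = (1/N) * #\{spikes in [t, t + bin)\}`.
#'
#' @param raster an [adex_raster()].
#' @param bin bin width (ms), default 1 ms.
#' @param t_ini,t_fin binning window (ms); default the raster window.
#' @return list with `times` (left bin edges) and `F` (fraction per bin).
#' @export
instantaneous_rate <- function(raster, bin = 1, t_ini = raster$window[1],
                               t_fin = raster$window[2]) {
  stopifnot(bin > 0)
  N <- length(raster$spike_times)
  edges <- seq(t_ini, t_fin + bin, by = bin)
  t <- unlist(raster$spike_times, use.names = FALSE)
  t <- t[t >= t_ini & t < edges[length(edges)]]
  counts <- if (length(t)) tabulate(findInterval(t, edges), length(edges) - 1L)
            else integer(length(edges) - 1L)
  list(times = edges[-length(edges)], F = counts / N)
}

#' Mean firing rate
#'
#' The population mean firing rate is the reciprocal of the mean inter-spike
#' interval, `F_bar = 1 / mean_i(mean ISI_i)`, reported in spikes/s (ISIs are
#' in ms).  Neurons with fewer than two spikes contribute no ISI.
#'
#' @param raster an [adex_raster()].
#' @param t_ini,t_fin analysis window (ms); default the raster window.
#' @return mean firing rate (spikes/s).
#' @export
mean_firing_rate <- function(raster, t_ini = raster$window[1],
                             t_fin = raster$window[2]) {
  mi <- vapply(raster$spike_times, function(s) {
    s <- s[s >= t_ini & s <= t_fin]
    if (length(s) < 2L) return(NA_real_)
    mean(diff(s))
  }, numeric(1))
  if (all(is.na(mi))) stop("mean ISI undefined: no neuron with >= 2 spikes")
  1000 / mean(mi, na.rm = TRUE)
}

#' Per-neuron and population synaptic input series
#'
#' Reconstructs the instantaneous synaptic input of every neuron from
#' recorded conductance and voltage traces:
#' `I_i(t) = sum_j (Vrev_j - V_i(t)) M[i, j] g_j(t)`, and the population
#' mean `I_syn(t)`.  Requires traces recorded for all neurons (practical for
#' micro-networks; large simulations record the population mean directly,
#' see [adex_config()]'s `record_isyn`).
#'
#' @param traces trace list from [adex_simulate()] with `V` and `g` matrices
#'   covering all `N` neurons.
#' @param topology an [adex_topology()].
#' @param params an [adex_params()].
#' @return list with `times`, `I_isc` (S x N matrix, pA) and `I_syn`
#'   (population mean, length S).
#' @export
synaptic_input_series <- function(traces, topology, params) {
  if (is.null(traces) || is.null(traces$V) || is.null(traces$g))
    stop("synaptic input reconstruction requires recorded V and g traces")
  if (ncol(traces$V) != topology$N)
    stop("traces must cover all ", topology$N, " neurons")
  vrev <- ifelse(topology$is_excitatory, params$V_rev_exc, params$V_rev_inh)
  Mt <- t(topology$M)                      # Mt[j, i] = M[i, j]
  gv <- traces$g %*% ((vrev * Mt))         # sum_j Vrev_j M_ij g_j(t)
  gs <- traces$g %*% Mt                    # sum_j M_ij g_j(t)
  I <- gv - traces$V * gs
  list(times = traces$times, I_isc = I, I_syn = rowMeans(I))
}

#' Classify the network regime
#'
#' Regimes combine a synchrony axis and a firing-pattern axis: the network
#' is *synchronized* when the time-averaged order parameter reaches
#' `sync_threshold`, and *bursting* when the mean ISI coefficient of
#' variation is at least 0.5.
#'
#' @param R_bar time-averaged order parameter.
#' @param CV_bar mean ISI coefficient of variation.
#' @param sync_threshold order-parameter threshold for the synchronized
#'   label (default 0.9).
#' @return one of `"desynchronized_spikes"`, `"synchronized_spikes"`,
#'   `"desynchronized_bursts"`, `"synchronized_bursts"`.
#' @export
classify_regime <- function(R_bar, CV_bar, sync_threshold = 0.9) {
  stopifnot(is.finite(R_bar), is.finite(CV_bar))
  paste0(if (R_bar >= sync_threshold) "synchronized" else "desynchronized",
         "_", if (CV_bar >= 0.5) "bursts" else "spikes")
}

#' Regime summary of a spike raster
#'
#' Computes the three summary statistics of a simulation over an analysis
#' window -- time-averaged order parameter `R_bar`, mean ISI coefficient of
#' variation `CV_bar`, mean firing rate `F_bar` (spikes/s) -- and the regime
#' label.  The order parameter uses a streaming accumulation of the complex
#' phase centroid (O(S) memory), equivalent to
#' `time_average_R(order_parameter(spike_phases(...)))`.
#'
#' @param raster an [adex_raster()].
#' @param t_ini,t_fin analysis window (ms).
#' @param sample_dt phase sampling grid (ms), default 1 ms.
#' @param sync_threshold see [classify_regime()].
#' @return An object of class `adex_regime`: list with `R_bar`, `CV_bar`,
#'   `F_bar`, `label`, `window`, `n_spikes`.
#' @export
regime_summary <- function(raster, t_ini = raster$window[1],
                           t_fin = raster$window[2], sample_dt = 1,
                           sync_threshold = 0.9) {
  stopifnot(t_fin > t_ini)
  os <- order_series(raster, t_ini, t_fin, sample_dt)
  sel <- !is.na(os$R)
  if (sum(sel) < 2L) stop("order parameter undefined over the analysis window")
  R_bar <- trapz_mean(os$times[sel], os$R[sel])
  CV_bar <- isi_cv(raster, t_ini, t_fin)$cv_bar
  F_bar <- mean_firing_rate(raster, t_ini, t_fin)
  structure(list(R_bar = R_bar, CV_bar = CV_bar, F_bar = F_bar,
                 label = classify_regime(R_bar, CV_bar, sync_threshold),
                 window = c(t_ini, t_fin),
                 n_spikes = n_spikes(clip_raster(raster, t_ini, t_fin))),
            class = "adex_regime")
}

# streaming order-parameter series: O(S) memory single pass over neurons,
# equivalent to order_parameter(spike_phases(clip_raster(...)))
order_series <- function(raster, t_ini, t_fin, sample_dt = 1) {
  times <- seq(t_ini, t_fin, by = sample_dt)
  S <- length(times)
  re <- numeric(S); im <- numeric(S); nv <- integer(S)
  for (s in raster$spike_times) {
    s <- s[s >= t_ini & s <= t_fin]
    ph <- neuron_phase(s, times)
    if (is.null(ph)) next
    ok <- !is.na(ph)
    re[ok] <- re[ok] + cos(ph[ok])
    im[ok] <- im[ok] + sin(ph[ok])
    nv <- nv + ok
  }
  list(times = times,
       R = sqrt(re^2 + im^2) / ifelse(nv > 0, nv, NA_real_),
       n_valid = nv)
}

#' @export
print.adex_regime <- function(x, ...) {
  cat(sprintf("Regime: %s  (R_bar=%.3f, CV_bar=%.3f, F_bar=%.1f spikes/s over [%g, %g] ms)\n",
              x$label, x$R_bar, x$CV_bar, x$F_bar, x$window[1], x$window[2]))
  invisible(x)
}
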
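#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit-Euler integrator for a network of AdEx neurons with
// conductance-based synapses.
//
// Per-neuron dynamics (units: mV, ms, pA, pF, nS):
//   C_m dV/dt = -g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T)
//               + I + Gamma(t) - w + sum_j (Vrev_j - V) M_ij g_j
//   tau_w dw/dt = a (V - E_L) - w
//   tau_s dg/dt = -g
// Reset on V > V_thres: V -> V_r, w -> w + b, g -> g + g_s(class).
//
// All synaptic conductances share tau_s, so the summed presynaptic
// conductance seen by neuron i, split by source class
//   s_exc[i] = sum_{j exc} M_ij g_j,   s_inh[i] = sum_{j inh} M_ij g_j,
// obeys the same per-step linear decay as each g_j and is incremented by
// g_s only when a presynaptic neuron fires.  This event-driven bookkeeping
// is algebraically identical to recomputing the sum every step under the
// Euler scheme, and turns the per-step cost from O(edges) into O(N) plus
// O(out-degree) per spike.
//
// Adjacency is passed in CSR form over PREsynaptic index j:
// out_idx[out_ptr[j] .. out_ptr[j+1]-1] lists the postsynaptic targets i
// (0-based) of neuron j.

// [[Rcpp::export]]
List adex_integrate_cpp(IntegerVector out_ptr, IntegerVector out_idx,
                        LogicalVector is_exc,
                        NumericVector V0, NumericVector w0, NumericVector g0,
                        NumericVector a, NumericVector Idrive,
                        List par,
                        double scp_amplitude, double scp_on, double scp_off,
                        IntegerVector scp_targets,
                        double noise_sigma, bool noise_dt_invariant,
                        double t0, double duration, double dt,
                        double record_dt, IntegerVector record_neurons,
                        bool record_isyn) {
  const int N = V0.size();
  const double Cm    = as<double>(par["C_m"]);
  const double gL    = as<double>(par["g_L"]);
  const double EL    = as<double>(par["E_L"]);
  const double DT    = as<double>(par["Delta_T"]);
  const double VT    = as<double>(par["V_T"]);
  const double Vth   = as<double>(par["V_thres"]);
  const double Vr    = as<double>(par["V_r"]);
  const double tauw  = as<double>(par["tau_w"]);
  const double taus  = as<double>(par["tau_s"]);
  const double b     = as<double>(par["b"]);
  const double VrevE = as<double>(par["V_rev_exc"]);
  const double VrevI = as<double>(par["V_rev_inh"]);
  const double gexc  = as<double>(par["g_exc"]);
  const double ginh  = as<double>(par["g_inh"]);
  const double expcap = as<double>(par["exp_cap"]);

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> g(g0.begin(), g0.end());
  std::vector<double> sE(N, 0.0), sI(N, 0.0);

  // initial aggregated synaptic state from g0
  for (int j = 0; j < N; ++j) {
    if (g[j] == 0.0) continue;
    double gj = g[j];
    bool exc = is_exc[j];
    for (int k = out_ptr[j]; k < out_ptr[j + 1]; ++k) {
      int i = out_idx[k];
      if (exc) sE[i] += gj; else sI[i] += gj;
    }
  }

  std::vector<char> stim(N, 0);
  for (int k = 0; k < scp_targets.size(); ++k) stim[scp_targets[k]] = 1;
  const bool has_scp = scp_amplitude != 0.0 && scp_off > scp_on &&
                       scp_targets.size() > 0;
  const bool has_noise = noise_sigma > 0.0;
  const double noise_sd = has_noise
      ? (noise_dt_invariant ? noise_sigma / std::sqrt(dt) : noise_sigma)
      : 0.0;

  const long nsteps = (long)std::floor(duration / dt + 1e-9);
  const double decay = 1.0 - dt / taus;
  if (decay <= 0.0) stop("dt too large for synaptic time constant");

  std::vector<double> spk_t;
  std::vector<int> spk_i;
  spk_t.reserve(4096); spk_i.reserve(4096);

  // trace recording
  const int nrec = record_neurons.size();
  long nsamp = 0;
  long rec_stride = 0;
  if (record_dt > 0.0) {
    rec_stride = (long)std::max(1.0, std::floor(record_dt / dt + 0.5));
    nsamp = nsteps / rec_stride + 1;
  }
  NumericMatrix trV, trw, trg, trIsc;
  NumericVector tr_t, isyn;
  if (nsamp > 0) {
    tr_t = NumericVector(nsamp);
    if (nrec > 0) {
      trV = NumericMatrix(nsamp, nrec);
      trw = NumericMatrix(nsamp, nrec);
      trg = NumericMatrix(nsamp, nrec);
      trIsc = NumericMatrix(nsamp, nrec);
    }
    if (record_isyn) isyn = NumericVector(nsamp);
  }
  long isamp = 0;
  auto record_sample = [&](double t) {
    if (isamp >= nsamp) return;
    tr_t[isamp] = t;
    for (int k = 0; k < nrec; ++k) {
      int i = record_neurons[k];
      trV(isamp, k) = V[i];
      trw(isamp, k) = w[i];
      trg(isamp, k) = g[i];
      trIsc(isamp, k) = (VrevE - V[i]) * sE[i] + (VrevI - V[i]) * sI[i];
    }
    if (record_isyn) {
      double acc = 0.0;
      for (int i = 0; i < N; ++i)
        acc += (VrevE - V[i]) * sE[i] + (VrevI - V[i]) * sI[i];
      isyn[isamp] = acc / N;
    }
    ++isamp;
  };
  if (nsamp > 0) record_sample(t0);

  RNGScope rngscope;  // noise uses R's RNG stream

  const double cV = dt / Cm, cw = dt / tauw;
  for (long step = 0; step < nsteps; ++step) {
    double t = t0 + step * dt;
    bool scp_now = has_scp && t >= scp_on && t < scp_off;

    for (int i = 0; i < N; ++i) {
      double Vi = V[i];
      double arg = (Vi - VT) / DT;
      if (arg > expcap) arg = expcap;
      double Isc = (VrevE - Vi) * sE[i] + (VrevI - Vi) * sI[i];
      double Iext = Idrive[i];
      if (scp_now && stim[i]) Iext += scp_amplitude;
      if (has_noise) Iext += norm_rand() * noise_sd;
      double dV = -gL * (Vi - EL) + gL * DT * std::exp(arg) + Iext - w[i] + Isc;
      V[i] = Vi + cV * dV;
      w[i] += cw * (a[i] * (Vi - EL) - w[i]);
      g[i] *= decay;
      sE[i] *= decay;
      sI[i] *= decay;
    }

    double tsp = t0 + (step + 1) * dt;  // == t_end on the last step, exactly
    for (int i = 0; i < N; ++i) {
      if (V[i] > Vth) {
        spk_t.push_back(tsp);
        spk_i.push_back(i);
        V[i] = Vr;
        w[i] += b;
        double gs = is_exc[i] ? gexc : ginh;
        g[i] += gs;
        if (is_exc[i]) {
          for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) sE[out_idx[k]] += gs;
        } else {
          for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) sI[out_idx[k]] += gs;
        }
      } else if (!std::isfinite(V[i])) {
        stop("non-finite membrane potential at t = %f ms (dt too large?)", tsp);
      }
    }

    if (nsamp > 0 && ((step + 1) % rec_stride == 0)) record_sample(tsp);
  }

  List traces = R_NilValue;
  if (nsamp > 0) {
    traces = List::create(
      _["times"] = tr_t, _["V"] = trV, _["w"] = trw, _["g"] = trg,
      _["I_isc"] = trIsc, _["I_syn"] = isyn, _["neurons"] = record_neurons,
      _["dt_record"] = rec_stride * dt);
  }
  return List::create(
    _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["spike_i"] = IntegerVector(spk_i.begin(), spk_i.end()),
    _["V"] = NumericVector(V.begin(), V.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["g"] = NumericVector(g.begin(), g.end()),
    _["t_end"] = t0 + nsteps * dt,
    _["n_steps"] = (double)nsteps,
    _["traces"] = traces);
}
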
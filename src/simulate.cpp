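#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven Euler integration of a conductance-based quadratic
// integrate-and-fire network.  One general core serves the base model
// (global supralinear inhibition, homogeneous membranes), the slow
// NMDA/GABA_B variant, and the clustered E/I variant (explicit inhibitory
// synapses, per-neuron membrane constants, adaptation on a subset).
//
// Synchronous update contract: spikes detected at step t contribute their
// impulses (J*s, inhibitory sum, adaptation drive) at step t+1.  Every
// conductance follows tau dg/dt = -g + drive integrated by forward Euler,
// so spike terms enter scaled by dt/tau exactly like the decay and the
// continuous drives; the slow (NMDA/GABA_B) increments are the stated
// fractions of the corresponding fast increment amplitudes.  Voltages are
// clamped at the inhibitory reversal after each update and a neuron spikes
// when its post-update voltage exceeds v_th.

// [[Rcpp::export]]
List simulate_core_cpp(int n_steps, double dt,
                       NumericVector tau_m,
                       double tau_e, double tau_i, double tau_a,
                       double e_l, double v_th, double v_reset,
                       double e_e, double e_i, double e_a,
                       IntegerVector je_p, IntegerVector je_i, NumericVector je_x,
                       IntegerVector ji_p, IntegerVector ji_i, NumericVector ji_x,
                       double w_i, double c_gain,
                       NumericVector w_a,
                       NumericVector b,
                       NumericMatrix ext,
                       double nmda_frac, double gabab_frac, double tau_slow,
                       NumericVector v0, NumericVector ge0,
                       NumericVector gi0, NumericVector ga0,
                       double gi_glob0,
                       IntegerVector ins_neuron, IntegerVector ins_step,
                       int record_neuron) {
  const int n = v0.size();
  const double k_e = dt / tau_e, k_i = dt / tau_i, k_a = dt / tau_a;
  const double k_s = tau_slow > 0 ? dt / tau_slow : 0.0;
  const bool has_ext = ext.ncol() > 0;
  const int t_ext = ext.ncol();
  const bool has_ji = ji_x.size() > 0;
  const bool has_slow = (nmda_frac > 0) || (gabab_frac > 0);
  const bool global_inh = w_i > 0;

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> ge(ge0.begin(), ge0.end());
  std::vector<double> gi(gi0.begin(), gi0.end());  // synaptic inhibitory
  std::vector<double> ga(ga0.begin(), ga0.end());
  std::vector<double> gn(n, 0.0);                  // NMDA
  double gi_glob = gi_glob0, gb_glob = 0.0;

  std::vector<double> km(n);
  for (int i = 0; i < n; ++i) km[i] = dt / tau_m[i];

  std::vector<int> spk;   // previous-step spikers
  std::vector<int> out_neuron, out_step;
  out_neuron.reserve(1 << 16);
  out_step.reserve(1 << 16);

  NumericVector rec_v, rec_ge, rec_gi, rec_ga;
  const int rn = record_neuron - 1;
  if (rn >= 0) {
    rec_v = NumericVector(n_steps);
    rec_ge = NumericVector(n_steps);
    rec_gi = NumericVector(n_steps);
    rec_ga = NumericVector(n_steps);
  }

  int ins_ptr = 0;
  const int n_ins = ins_neuron.size();
  int n_spk_prev = 0;

  for (int t = 0; t < n_steps; ++t) {
    // global inhibitory feedback from the previous step's population count
    if (global_inh) {
      double imp = (n_spk_prev > 0)
        ? k_i * w_i * std::expm1(c_gain * n_spk_prev) : 0.0;
      gi_glob += -k_i * gi_glob + imp;
      if (gabab_frac > 0) gb_glob += -k_s * gb_glob + gabab_frac * imp;
    }

    // conductance decay + continuous drives
    if (has_ext) {
      const double* ec = &ext(0, t % t_ext);
      for (int i = 0; i < n; ++i) ge[i] += k_e * (b[i] + ec[i] - ge[i]);
    } else {
      for (int i = 0; i < n; ++i) ge[i] += k_e * (b[i] - ge[i]);
    }
    for (int i = 0; i < n; ++i) ga[i] -= k_a * ga[i];
    if (has_slow) for (int i = 0; i < n; ++i) gn[i] -= k_s * gn[i];
    if (has_ji) for (int i = 0; i < n; ++i) gi[i] -= k_i * gi[i];

    // synaptic impulses from previous-step spikes; a neuron's outgoing
    // synapses live in the excitatory or the inhibitory matrix (the other
    // column is empty), so one pass covers both populations
    for (size_t s = 0; s < spk.size(); ++s) {
      const int j = spk[s];
      for (int k = je_p[j]; k < je_p[j + 1]; ++k) {
        ge[je_i[k]] += k_e * je_x[k];
        if (nmda_frac > 0) gn[je_i[k]] += nmda_frac * k_e * je_x[k];
      }
      if (has_ji)
        for (int k = ji_p[j]; k < ji_p[j + 1]; ++k) gi[ji_i[k]] += k_i * ji_x[k];
      ga[j] += k_a * w_a[j];
    }

    // membrane update, clamp, spike test
    spk.clear();
    const double gi_g = gi_glob + gb_glob;
    for (int i = 0; i < n; ++i) {
      const double ge_tot = ge[i] + gn[i];
      const double gi_tot = gi_g + gi[i];
      double vi = v[i];
      vi += km[i] * ((vi - e_l) * (vi - v_th) - ge_tot * (vi - e_e)
                     - gi_tot * (vi - e_i) - ga[i] * (vi - e_a));
      if (vi < e_i) vi = e_i;
      v[i] = vi;
    }
    if (rn >= 0) {
      rec_v[t] = v[rn];
      rec_ge[t] = ge[rn] + gn[rn];
      rec_gi[t] = gi_g + gi[rn];
      rec_ga[t] = ga[rn];
    }
    while (ins_ptr < n_ins && ins_step[ins_ptr] == t) {
      v[ins_neuron[ins_ptr] - 1] = v_th + 1.0;
      ++ins_ptr;
    }
    for (int i = 0; i < n; ++i) {
      if (v[i] > v_th) {
        out_neuron.push_back(i + 1);
        out_step.push_back(t);
        v[i] = v_reset;
        spk.push_back(i);
      }
    }
    n_spk_prev = (int)spk.size();

    if ((t & 1023) == 0) {
      double chk = 0.0;
      for (int i = 0; i < n; ++i) chk += v[i];
      if (!std::isfinite(chk))
        stop("integration failure: non-finite state at step %d (t = %.1f ms)",
             t, t * dt);
    }
  }

  List out = List::create(_["neuron"] = wrap(out_neuron),
                          _["step"] = wrap(out_step),
                          _["final"] = List::create(
                              _["V"] = wrap(v), _["gE"] = wrap(ge),
                              _["gI"] = wrap(gi), _["gA"] = wrap(ga),
                              _["gI_glob"] = gi_glob));
  if (rn >= 0)
    out["trace"] = List::create(_["v"] = rec_v, _["g_e"] = rec_ge,
                                _["g_i"] = rec_gi, _["g_a"] = rec_ga);
  return out;
}
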
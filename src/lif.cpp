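#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire membrane with a delayed sag (Ih-like) relaxation
// and stereotyped spike pasting, advanced by forward Euler at the sampling
// interval.
//
// current_pa : injected current per sample (pA), relative to the bias
//              holding current (so 0 pA keeps the membrane at v_rest)
// z_target   : per-sample target (mV) of the sag relaxation state; 0 when
//              sag is inactive, sag_frac * steady-state deflection during
//              the delayed phase of a hyperpolarizing step. The sag state
//              relaxes toward its target with sag_tau_ms and is subtracted
//              from the output voltage directly (a relaxation of the
//              voltage), so the passive trace has the closed form
//              v = rest + u_RC(t) - z(t).
// waveform   : voltage samples pasted after a threshold crossing; the
//              crossing sample itself is set to spike_threshold
//
// Returns the voltage trace (mV) and 1-based indices of threshold
// crossings.
// [[Rcpp::export]]
List lif_integrate(NumericVector current_pa, double dt_ms,
                   double r_m, double c_m, double v_rest,
                   double spike_threshold, double v_reset,
                   double refractory_ms, NumericVector waveform,
                   double sag_tau_ms, NumericVector z_target) {
  const int n = current_pa.size();
  NumericVector v(n);
  std::vector<int> spikes;
  const double tau_m = r_m * c_m / 1000.0;  // MOhm * pF = us -> ms
  const double a_m = dt_ms / tau_m;
  const double a_z = sag_tau_ms > 0 ? dt_ms / sag_tau_ms : 0.0;
  const int n_refr = (int)std::floor(refractory_ms / dt_ms + 0.5);
  const int n_wave = waveform.size();
  const bool spiking = R_finite(spike_threshold);

  double vm = v_rest, z = 0.0;
  v[0] = vm;
  int i = 1;
  while (i < n) {
    z += a_z * (z_target[i] - z);
    vm += a_m * (v_rest + r_m * current_pa[i - 1] / 1000.0 - vm);
    if (spiking && vm >= spike_threshold) {
      spikes.push_back(i + 1);  // 1-based crossing index
      v[i] = spike_threshold;
      int j = i + 1;
      for (int k = 0; k < n_wave && j < n; ++k, ++j) v[j] = waveform[k];
      for (int k = 0; k < n_refr && j < n; ++k, ++j) v[j] = v_reset;
      // keep the sag state evolving through the pasted region
      for (int t = i + 1; t < j && t < n; ++t) z += a_z * (z_target[t] - z);
      vm = v_reset;
      i = j;
    } else {
      v[i] = vm - z;
      ++i;
    }
  }
  return List::create(_["v"] = v, _["spike_index"] = wrap(spikes));
}
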
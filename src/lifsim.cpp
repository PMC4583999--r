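#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leaky integrate-and-fire network with delta synapses, fixed delay and
// constant (DC-equivalent) drive:
//   tau dv_i/dt = -v_i + drive + tau * sum_j J_ij S_j(t - t_d)
// Exact exponential propagation over each step dt (the equation is linear
// between spikes); delayed spikes add their weight in mV instantaneously;
// threshold crossings are detected at step boundaries, all crossers fire in
// the same step and are reset.
//
// Wp, Wi, Wx: compressed sparse columns of the *transposed* weight matrix,
// i.e. column j holds the targets (0-based) and weights (mV) of presynaptic
// neuron j.
// [[Rcpp::export]]
List cpp_simulate_lif(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                      int n, double dt, double tau, double theta,
                      double v_reset, double drive, int n_steps,
                      int delay_steps, int ref_steps, NumericVector v0) {
  if (v0.size() != n) stop("v0 length must equal the number of neurons");
  if (delay_steps < 1) stop("delay must be at least one step");
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<int> refr(n, 0);
  const double prop = std::exp(-dt / tau);

  // ring buffer of spiker lists, one slot per delay step
  std::vector< std::vector<int> > ring(delay_steps);
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  sp_t.reserve(1 << 16);
  sp_id.reserve(1 << 16);

  for (int s = 0; s < n_steps; ++s) {
    // exact subthreshold decay toward the constant drive
    for (int i = 0; i < n; ++i)
      v[i] = drive + (v[i] - drive) * prop;

    // deliver spikes emitted delay_steps ago
    std::vector<int>& due = ring[s % delay_steps];
    for (size_t q = 0; q < due.size(); ++q) {
      int j = due[q];
      for (int k = Wp[j]; k < Wp[j + 1]; ++k) v[Wi[k]] += Wx[k];
    }
    due.clear();

    // refractory clamp
    if (ref_steps > 0) {
      for (int i = 0; i < n; ++i)
        if (refr[i] > 0) { v[i] = v_reset; --refr[i]; }
    }

    // threshold detection; all simultaneous crossers fire this step
    std::vector<int>& out = ring[(s + delay_steps) % delay_steps];
    double t_now = s * dt;
    for (int i = 0; i < n; ++i) {
      if (v[i] >= theta) {
        v[i] = v_reset;
        refr[i] = ref_steps;
        out.push_back(i);
        sp_t.push_back(t_now);
        sp_id.push_back(i + 1);
      } else if (!std::isfinite(v[i])) {
        stop("non-finite membrane potential at t = %.1f ms (neuron %d)",
             t_now, i + 1);
      }
    }
  }
  return List::create(_["times"] = NumericVector(sp_t.begin(), sp_t.end()),
                      _["ids"] = IntegerVector(sp_id.begin(), sp_id.end()),
                      _["v_final"] = NumericVector(v.begin(), v.end()));
}
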
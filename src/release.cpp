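#include <Rcpp.h>
using namespace Rcpp;

// Event-driven simulation of stochastic vesicle release and replenishment.
//
// Each of M active zones holds n_sites release sites, all occupied at t = 0.
// At every presynaptic spike of a zone, each site whose NextAvailabilityTime
// has passed releases with probability p_v; a released site is refilled after
// an exponential delay with mean tau_rec (seconds). Uses R's RNG so results
// are reproducible under set.seed(). Zones are processed in order; the
// availability fraction is recorded *before* release sampling.
//
// [[Rcpp::export]]
DataFrame release_sim_cpp(List spike_times, int n_sites, double p_v,
                          double tau_rec) {
  int M = spike_times.size();
  std::vector<double> out_t, out_avail;
  std::vector<int> out_zone, out_count;
  RNGScope scope;
  for (int j = 0; j < M; ++j) {
    NumericVector st = spike_times[j];
    std::vector<double> next_avail(n_sites, 0.0);
    for (R_xlen_t i = 0; i < st.size(); ++i) {
      double t = st[i];
      int avail = 0, rel = 0;
      for (int k = 0; k < n_sites; ++k) {
        if (t >= next_avail[k]) {
          ++avail;
          if (p_v > unif_rand()) {
            next_avail[k] = t + exp_rand() * tau_rec;
            ++rel;
          }
        }
      }
      out_t.push_back(t);
      out_zone.push_back(j + 1);
      out_count.push_back(rel);
      out_avail.push_back(n_sites > 0 ? (double)avail / n_sites : 0.0);
    }
  }
  return DataFrame::create(_["time"] = out_t, _["zone"] = out_zone,
                           _["count"] = out_count, _["avail"] = out_avail);
}

// Delete spikes falling within `refractory` (s) of the last retained spike.
// `times` must be sorted increasing.
//
// [[Rcpp::export]]
NumericVector enforce_refractory_cpp(NumericVector times, double refractory) {
  std::vector<double> keep;
  double last = R_NegInf;
  for (R_xlen_t i = 0; i < times.size(); ++i) {
    if (times[i] - last >= refractory) {
      keep.push_back(times[i]);
      last = times[i];
    }
  }
  return wrap(keep);
}
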
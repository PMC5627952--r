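#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integrators for the single-compartment postsynaptic neuron.
//
// Units follow the printed model: v in mV, time step dt in ms, C_m in
// uF.cm^-2, channel conductances in S.cm^-2, gbar (absolute synaptic peak
// conductance) in S, membrane area in cm^2. With v in mV, every current term
// (g * (v - E), and gbar*g*(v - E_syn)/area) is in mA.cm^-2, while
// C_m * dv/dt with dt in ms is in uA.cm^-2; the factor 1000 below converts
// mA -> uA so that, e.g., the passive time constant is C_m/g_l = 5 ms.
//
// The synaptic drive enters the voltage equation with the depolarising
// conductance convention, -gbar*g*(v - E_syn)/area.
//
// r_counts[i] is the number of vesicles released during step i (right-aligned
// binning). The conductance follows dg/dt = -g/tau_d + x with
// tau_rise*dx/dt = -x + r(t); releases are injected as r/dt so that the
// impulse area (the jump in g per vesicle) is dt-invariant. tau_rise = 0 is
// the delta synapse, x(t) = r(t)/dt.

static inline void syn_step(double &g, double &x, double r, double dt,
                            double tau_rise, double tau_d) {
  if (tau_rise > 0.0) {
    x += (dt * (-x) + r) / tau_rise;
  } else {
    x = r / dt;
  }
  g += dt * (-g / tau_d + x);
}

// [[Rcpp::export]]
List hh_sim_cpp(NumericVector r_counts, double dt, double gbar, double e_syn,
                double tau_rise, double tau_d, double c_m, double g_l,
                double g_k, double g_na, double e_l, double e_k, double e_na,
                double tau_m, double tau_h, double tau_n, double area,
                double v0, bool keep_trace) {
  R_xlen_t n = r_counts.size();
  double v = v0, m = 0.0, h = 0.0, nn = 0.0, g = 0.0, x = 0.0;
  std::vector<double> spikes;
  NumericVector tr_v, tr_m, tr_h, tr_n, tr_g;
  if (keep_trace) {
    tr_v = NumericVector(n + 1);
    tr_m = NumericVector(n + 1);
    tr_h = NumericVector(n + 1);
    tr_n = NumericVector(n + 1);
    tr_g = NumericVector(n + 1);
    tr_v[0] = v;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    syn_step(g, x, r_counts[i], dt, tau_rise, tau_d);
    double i_syn = -gbar * g * (v - e_syn) / area; // mA.cm^-2, depolarising
    double dv = dt * 1000.0 / c_m *
                (-g_l * (v - e_l) - g_k * nn * nn * (v - e_k) -
                 g_na * m * m * h * (v - e_na) + i_syn);
    double m_ss = 1.0 / (1.0 + exp(-(v + 40.0) / 3.0));
    double h_ss = 1.0 / (1.0 + exp((v + 45.0) / 3.0));
    double n_ss = m_ss; // printed steady states for m and n coincide
    m += dt * (m_ss - m) / tau_m;
    h += dt * (h_ss - h) / tau_h;
    nn += dt * (n_ss - nn) / tau_n;
    double v_new = v + dv;
    if (v < 10.0 && v_new > 10.0)
      spikes.push_back((i + 1) * dt / 1000.0); // seconds
    if (!R_FINITE(v_new) || fabs(v_new) > 200.0)
      stop("HH integration diverged (|v| > 200 mV); reduce the time step");
    v = v_new;
    if (keep_trace) {
      tr_v[i + 1] = v;
      tr_m[i + 1] = m;
      tr_h[i + 1] = h;
      tr_n[i + 1] = nn;
      tr_g[i + 1] = g;
    }
  }
  List out = List::create(_["spike_times"] = wrap(spikes));
  if (keep_trace) {
    out["v"] = tr_v;
    out["m"] = tr_m;
    out["h"] = tr_h;
    out["n"] = tr_n;
    out["g"] = tr_g;
  }
  return out;
}

// [[Rcpp::export]]
List lif_sim_cpp(NumericVector r_counts, double dt, double gbar, double e_syn,
                 double tau_rise, double tau_d, double c_m, double g_l,
                 double e_l, double area, double v_thresh, double v_reset,
                 double t_refrac, double v0, bool keep_trace) {
  R_xlen_t n = r_counts.size();
  double v = v0, g = 0.0, x = 0.0;
  double refrac_until = -1.0; // ms
  std::vector<double> spikes;
  NumericVector tr_v, tr_g;
  if (keep_trace) {
    tr_v = NumericVector(n + 1);
    tr_g = NumericVector(n + 1);
    tr_v[0] = v;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    double t_ms = (i + 1) * dt;
    syn_step(g, x, r_counts[i], dt, tau_rise, tau_d);
    if (t_ms <= refrac_until) {
      v = v_reset; // held at reset during the refractory time
    } else {
      double i_syn = -gbar * g * (v - e_syn) / area;
      v += dt * 1000.0 / c_m * (-g_l * (v - e_l) + i_syn);
      if (v > v_thresh) {
        spikes.push_back(t_ms / 1000.0); // seconds
        v = v_reset;
        refrac_until = t_ms + t_refrac;
      }
    }
    if (keep_trace) {
      tr_v[i + 1] = v;
      tr_g[i + 1] = g;
    }
  }
  List out = List::create(_["spike_times"] = wrap(spikes));
  if (keep_trace) {
    out["v"] = tr_v;
    out["g"] = tr_g;
  }
  return out;
}
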
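#include <Rcpp.h>
using namespace Rcpp;

// Box-Muller Gaussian deviates (from R's uniform stream) smoothed with a
// centred moving average; the window shrinks symmetrically at the edges.
// [[Rcpp::export]]
NumericVector bm_noise_cpp(int n, double sigma, int window) {
  NumericVector g(n);
  RNGScope scope;
  int i = 0;
  while (i < n) {
    double u1 = unif_rand();
    double u2 = unif_rand();
    // guard against log(0)
    if (u1 <= 0.0) u1 = DBL_MIN;
    double r = std::sqrt(-2.0 * std::log(u1));
    g[i++] = sigma * r * std::cos(2.0 * M_PI * u2);
    if (i < n) g[i++] = sigma * r * std::sin(2.0 * M_PI * u2);
  }
  if (window <= 1) return g;
  int half = window / 2;
  NumericVector out(n);
  // prefix sums for O(n) averaging
  std::vector<double> cs(n + 1, 0.0);
  for (int k = 0; k < n; ++k) cs[k + 1] = cs[k] + g[k];
  for (int k = 0; k < n; ++k) {
    int lo = std::max(0, k - half);
    int hi = std::min(n - 1, k + half);
    // shrink symmetrically so the window stays centred
    int reach = std::min(k - lo, hi - k);
    lo = k - reach;
    hi = k + reach;
    out[k] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
  return out;
}

// Array of leaky integrate-and-fire zones with antidromic cross-zone reset.
//
// Each zone obeys tau * du/dt = -u + R * I_z(t) with R = tau / C, integrated
// by classical RK4 with the current held constant over each input sample
// (n_sub RK4 substeps per sample).  When any zone reaches u >= vbar a spike
// is recorded at the end time of that substep, ALL zones are reset to
// `reset` and are refractory for `refractory` ms.  If several zones cross in
// the same substep the zone with the largest overshoot wins (ties -> lowest
// zone index).  During refractoriness integration is suspended and u is
// clamped at the reset potential (set clamp = false to integrate but ignore
// threshold instead).
//
// currents: samples x zones matrix, mA, on a grid with spacing dt_ms.
// Returns a list with spike times (ms) and 1-based originating zones.
// [[Rcpp::export]]
List lif_integrate_cpp(NumericMatrix currents, double tau, double cap,
                       double vbar, double refractory, double reset,
                       double dt_ms, int n_sub, bool clamp) {
  int n = currents.nrow();
  int nz = currents.ncol();
  double R = tau / cap;
  double h = dt_ms / n_sub;
  std::vector<double> u(nz, 0.0);
  std::vector<double> spike_t;
  std::vector<int> spike_z;
  double refr_until = -1.0;  // absolute time until which all zones are refractory

  for (int k = 0; k < n - 1; ++k) {
    double t0 = k * dt_ms;
    for (int s = 0; s < n_sub; ++s) {
      double t = t0 + s * h;
      double t_end = t + h;
      bool refr = (t < refr_until);
      if (refr) {
        if (clamp) continue;  // integration suspended, u stays at reset
      }
      int winner = -1;
      double best_over = -1.0;
      for (int z = 0; z < nz; ++z) {
        double RI = R * currents(k, z);
        double uz = u[z];
        // RK4 for du/dt = (-u + RI) / tau, RI constant over the substep
        double k1 = (-uz + RI) / tau;
        double k2 = (-(uz + 0.5 * h * k1) + RI) / tau;
        double k3 = (-(uz + 0.5 * h * k2) + RI) / tau;
        double k4 = (-(uz + h * k3) + RI) / tau;
        uz += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
        u[z] = uz;
        if (!refr && uz >= vbar) {
          double over = uz - vbar;
          if (over > best_over + 1e-15) {  // strict: ties keep lowest index
            best_over = over;
            winner = z;
          }
        }
      }
      if (winner >= 0) {
        spike_t.push_back(t_end);
        spike_z.push_back(winner + 1);
        for (int z = 0; z < nz; ++z) u[z] = reset;
        refr_until = t_end + refractory;
      }
    }
  }
  return List::create(_["time_ms"] = wrap(spike_t),
                      _["zone"] = wrap(spike_z));
}
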
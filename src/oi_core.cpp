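#include <Rcpp.h>
using namespace Rcpp;

// Oscillatory-interference grid cell core.
//
// VCO phases are accumulated by path integration,
//   theta_i(t+dt) = theta_i(t) + 2*pi*f_vco_i(t)*dt,
// with f_vco_i = f_theta + beta * s * cos(phi_pref_i - phi).  The
// interference signal is
//   g(t) = n_vco*cos(theta_theta) + sum_i cos(theta_theta + theta_i),
// which reduces to the sum-of-cosines form for constant velocity.  A spike
// is emitted at every step with g >= g_thres, subject to an absolute
// refractory period.

// [[Rcpp::export]]
NumericVector oi_spikes_cpp(NumericVector s, NumericVector phi,
                            double dt, double beta,
                            NumericVector phi_pref, double f_theta,
                            double g_thres, double refractory,
                            NumericVector theta0, double theta_base0 = 0.0) {
  const int n = s.size();
  const int nv = phi_pref.size();
  std::vector<double> theta(nv, 0.0);
  for (int i = 0; i < nv && i < theta0.size(); ++i) theta[i] = theta0[i];
  double theta_base = theta_base0;
  const double twopi = 2.0 * M_PI;
  std::vector<double> out;
  double last_spike = -1e18;
  for (int k = 0; k < n; ++k) {
    double g = nv * std::cos(theta_base);
    for (int i = 0; i < nv; ++i)
      g += std::cos(theta_base + theta[i]);
    double t = k * dt;
    if (g >= g_thres && t - last_spike >= refractory) {
      out.push_back(t);
      last_spike = t;
    }
    // advance phases
    for (int i = 0; i < nv; ++i) {
      double fv = f_theta + beta * s[k] * std::cos(phi_pref[i] - phi[k]);
      theta[i] += twopi * fv * dt;
    }
    theta_base += twopi * f_theta * dt;
  }
  return wrap(out);
}

// Interference signal g(t) on the simulation lattice (for inspection and
// cross-checks).
// [[Rcpp::export]]
NumericVector oi_g_cpp(NumericVector s, NumericVector phi,
                       double dt, double beta,
                       NumericVector phi_pref, double f_theta,
                       NumericVector theta0, double theta_base0 = 0.0) {
  const int n = s.size();
  const int nv = phi_pref.size();
  std::vector<double> theta(nv, 0.0);
  for (int i = 0; i < nv && i < theta0.size(); ++i) theta[i] = theta0[i];
  double theta_base = theta_base0;
  const double twopi = 2.0 * M_PI;
  NumericVector g(n);
  for (int k = 0; k < n; ++k) {
    double gv = nv * std::cos(theta_base);
    for (int i = 0; i < nv; ++i)
      gv += std::cos(theta_base + theta[i]);
    g[k] = gv;
    for (int i = 0; i < nv; ++i) {
      double fv = f_theta + beta * s[k] * std::cos(phi_pref[i] - phi[k]);
      theta[i] += twopi * fv * dt;
    }
    theta_base += twopi * f_theta * dt;
  }
  return g;
}
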
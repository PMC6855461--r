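#include <Rcpp.h>
using namespace Rcpp;

// Multicompartment Hodgkin-Huxley cable integrator.
//
// Units: mV, ms, nA, uS, nF.  Chain topology (soma = compartment 0, then
// the apical cable).  Voltage is advanced by backward Euler with a
// tridiagonal (Thomas) solve; gating variables by exponential Euler at the
// previous step's voltage.  Channels per Eq-style conductance set:
// leak, Na (m^3 h s), K-DR (n), K-M (z), K-A (a b), h-current (q).

struct Gates {
  std::vector<double> m, h, s, n, z, a, b, q;
};

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// steady states / time constants (ms); CA1-style parameterization
static inline double m_inf(double v) { return sigmoid((v + 38.0) / 4.5); }
static inline double tau_m(double v) { (void)v; return 0.15; }
static inline double h_inf(double v) { return sigmoid(-(v + 50.0) / 5.0); }
static inline double tau_h(double v) { return 1.0 + 14.0 * sigmoid(-(v + 46.0) / 6.0); }
static inline double s_inf(double v) { return 0.6 + 0.4 * sigmoid(-(v + 58.0) / 4.0); }
static inline double tau_s(double v) { (void)v; return 300.0; }
static inline double n_inf(double v) { return sigmoid((v + 15.0) / 7.0); }
static inline double tau_n(double v) { return 1.5 + 3.0 * sigmoid(-(v + 30.0) / 8.0); }
static inline double z_inf(double v) { return sigmoid((v + 39.0) / 5.0); }
static inline double tau_z(double v) { (void)v; return 75.0; }
static inline double a_inf(double v) { return sigmoid((v + 5.0) / 11.0); }
static inline double tau_a(double v) { (void)v; return 0.5; }
static inline double b_inf(double v) { return sigmoid(-(v + 60.0) / 8.0); }
static inline double tau_b(double v) { (void)v; return 15.0; }
static inline double q_inf(double v) { return sigmoid(-(v + 80.0) / 7.0); }
static inline double tau_q(double v) { (void)v; return 80.0; }

static inline void gate_step(double &x, double xi, double tau, double dt) {
  x = xi + (x - xi) * std::exp(-dt / tau);
}

// [[Rcpp::export]]
List hh_simulate_cpp(NumericVector cap, NumericVector g_ax,
                     NumericMatrix gbar, NumericVector erev,
                     double dt, int n_steps,
                     IntegerVector syn_step, IntegerVector syn_comp,
                     double syn_w, double syn_tau, double e_syn,
                     double theta_f, double theta_g, double e_theta,
                     NumericVector i_soma,
                     int record_every, int record_comp,
                     double v_init, bool record_gates = false) {
  const int nc = cap.size();
  if (g_ax.size() != nc - 1) stop("g_ax must have length n_comp - 1");
  if (gbar.nrow() != nc || gbar.ncol() != 6) stop("gbar must be n_comp x 6");

  std::vector<double> v(nc, v_init), v_new(nc);
  Gates g;
  g.m.assign(nc, m_inf(v_init)); g.h.assign(nc, h_inf(v_init));
  g.s.assign(nc, s_inf(v_init)); g.n.assign(nc, n_inf(v_init));
  g.z.assign(nc, z_inf(v_init)); g.a.assign(nc, a_inf(v_init));
  g.b.assign(nc, b_inf(v_init)); g.q.assign(nc, q_inf(v_init));

  std::vector<double> g_syn(nc, 0.0);
  const double syn_decay = std::exp(-dt / syn_tau);
  const double two_pi_f = 2.0 * M_PI * theta_f / 1000.0; // rad per ms

  // Thomas solve workspace
  std::vector<double> diag(nc), sub(nc), rhs(nc), cp(nc), dp(nc);

  const int n_rec = n_steps / record_every + 1;
  NumericVector v_soma_rec(n_rec), v_comp_rec(record_comp >= 0 ? n_rec : 0);
  NumericVector t_rec(n_rec);
  std::vector<double> spikes;
  double last_spike = -1e18;
  double v_prev_soma = v_init;
  int ev = 0;
  const int n_ev = syn_step.size();
  const bool scalar_i = (i_soma.size() == 1);
  int rec_i = 0;

  for (int k = 0; k < n_steps; ++k) {
    double t_ms = k * dt;
    // synaptic conductance: decay then add this step's presynaptic events
    for (int i = 0; i < nc; ++i) g_syn[i] *= syn_decay;
    while (ev < n_ev && syn_step[ev] == k) {
      g_syn[syn_comp[ev]] += syn_w;
      ++ev;
    }
    // theta inhibitory conductance at soma: sinusoidally gated, rectified
    double sinv = std::sin(two_pi_f * t_ms);
    double g_th = theta_g * (sinv > 0.0 ? sinv : 0.0);

    // gating update (exponential Euler at current voltage)
    for (int i = 0; i < nc; ++i) {
      double vi = v[i];
      gate_step(g.m[i], m_inf(vi), tau_m(vi), dt);
      gate_step(g.h[i], h_inf(vi), tau_h(vi), dt);
      gate_step(g.s[i], s_inf(vi), tau_s(vi), dt);
      gate_step(g.n[i], n_inf(vi), tau_n(vi), dt);
      gate_step(g.z[i], z_inf(vi), tau_z(vi), dt);
      gate_step(g.a[i], a_inf(vi), tau_a(vi), dt);
      gate_step(g.b[i], b_inf(vi), tau_b(vi), dt);
      gate_step(g.q[i], q_inf(vi), tau_q(vi), dt);
    }

    // assemble tridiagonal system for backward Euler
    for (int i = 0; i < nc; ++i) {
      double gl = gbar(i, 0);
      double gna = gbar(i, 1) * g.m[i] * g.m[i] * g.m[i] * g.h[i] * g.s[i];
      double gkdr = gbar(i, 2) * g.n[i];
      double gkm = gbar(i, 3) * g.z[i];
      double gka = gbar(i, 4) * g.a[i] * g.b[i];
      double gh = gbar(i, 5) * g.q[i];
      double g_tot = gl + gna + gkdr + gkm + gka + gh + g_syn[i];
      double ge = gl * erev[0] + gna * erev[1] + gkdr * erev[2] +
        gkm * erev[3] + gka * erev[4] + gh * erev[5] + g_syn[i] * e_syn;
      if (i == 0) {
        g_tot += g_th;
        ge += g_th * e_theta;
      }
      double cdt = cap[i] / dt;
      diag[i] = cdt + g_tot;
      rhs[i] = cdt * v[i] + ge;
      if (i == 0 && !scalar_i) rhs[i] += i_soma[k];
      else if (i == 0) rhs[i] += i_soma[0];
    }
    for (int i = 0; i < nc - 1; ++i) {
      diag[i] += g_ax[i];
      diag[i + 1] += g_ax[i];
    }
    // Thomas algorithm (sub/super diagonal = -g_ax)
    if (nc == 1) {
      v_new[0] = rhs[0] / diag[0];
    } else {
      cp[0] = -g_ax[0] / diag[0];
      dp[0] = rhs[0] / diag[0];
      for (int i = 1; i < nc; ++i) {
        double a_i = -g_ax[i - 1]; // sub-diagonal
        double denom = diag[i] - a_i * cp[i - 1];
        cp[i] = (i < nc - 1) ? (-g_ax[i] / denom) : 0.0;
        dp[i] = (rhs[i] - a_i * dp[i - 1]) / denom;
      }
      v_new[nc - 1] = dp[nc - 1];
      for (int i = nc - 2; i >= 0; --i)
        v_new[i] = dp[i] - cp[i] * v_new[i + 1];
    }
    for (int i = 0; i < nc; ++i) {
      if (!std::isfinite(v_new[i]) || std::fabs(v_new[i]) > 200.0)
        stop("integration error: |Vm| > 200 mV at step %d", k);
      v[i] = v_new[i];
    }
    // spike detection: upward 0-mV crossing at the soma, 2-ms dead time
    if (v_prev_soma < 0.0 && v[0] >= 0.0 && t_ms - last_spike >= 2.0) {
      spikes.push_back(t_ms / 1000.0);
      last_spike = t_ms;
    }
    v_prev_soma = v[0];
    if (k % record_every == 0) {
      t_rec[rec_i] = t_ms / 1000.0;
      v_soma_rec[rec_i] = v[0];
      if (record_comp >= 0) v_comp_rec[rec_i] = v[record_comp];
      ++rec_i;
    }
  }
  List out = List::create(
    _["t"] = t_rec[Range(0, rec_i - 1)],
    _["v_soma"] = v_soma_rec[Range(0, rec_i - 1)],
    _["spikes"] = wrap(spikes));
  if (record_comp >= 0) out["v_comp"] = v_comp_rec[Range(0, rec_i - 1)];
  if (record_gates) {
    out["gates_final"] = List::create(
      _["m"] = wrap(g.m), _["h"] = wrap(g.h), _["s"] = wrap(g.s),
      _["n"] = wrap(g.n), _["z"] = wrap(g.z), _["a"] = wrap(g.a),
      _["b"] = wrap(g.b), _["q"] = wrap(g.q));
  }
  return out;
}
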
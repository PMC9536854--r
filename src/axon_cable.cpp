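// Double-cable myelinated axon integrator.
//
// Compartment chain: node, MYSA, FLUT, STIN..., FLUT, MYSA, node, ...
// Two potentials per compartment: u (intracellular) and w (periaxonal,
// between axolemma and myelin); the bath potential Ve is imposed from the
// volume conductor (phi per unit current x injected current).
// Crank-Nicolson (second-order implicit) with staggered gating updates;
// the 2x2-block tridiagonal system is solved with a block Thomas sweep.
//
// Units: mV, ms, nF, uS, nA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

// nodal channel rate constants (fast Na, persistent Na, slow K)
static inline void axon_rates(double v, double r[8]) {
  r[0] = 6.57 * vtrap(v + 20.4, 10.3);                 // alpha_m
  r[1] = 0.304 * vtrap(-(v + 25.7), 9.16);             // beta_m
  r[2] = 0.34 * vtrap(-(v + 114.0), 11.0);             // alpha_h
  r[3] = 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));  // beta_h
  r[4] = 0.0353 * vtrap(v + 27.0, 10.2);               // alpha_p
  r[5] = 0.000883 * vtrap(-(v + 34.0), 10.0);          // beta_p
  r[6] = 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));    // alpha_s
  r[7] = 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));   // beta_s
}

// [[Rcpp::export]]
List axon_simulate_cpp(List axon, NumericVector phi_mv, NumericVector current_ua,
                       double dt, double settle_ms, double v_thresh = -20.0,
                       double lockout_ms = 1.0, double v_diverge = 1e6,
                       int trace_comp = 0) {
  IntegerVector type = axon["type"];
  NumericVector cm = axon["cm_nf"], cmy = axon["cmy_nf"], gmy = axon["gmy_us"];
  NumericVector gpas = axon["gpas_us"];
  NumericVector ga = axon["g_axial_us"], gp = axon["g_peri_us"];
  IntegerVector node_idx = axon["node_idx"];
  NumericVector gnaf = axon["g_naf_us"], gnap = axon["g_nap_us"];
  NumericVector gks = axon["g_ks_us"], gl = axon["g_l_us"];
  List mb = axon["membrane"];
  const double ena = mb["e_na"], ek = mb["e_k"], el = mb["e_leak"];
  const double vrest = mb["v_rest"];

  const int n = type.size();
  const int nnode = node_idx.size();
  if (phi_mv.size() != n) stop("phi_mv length must equal compartment count");

  std::vector<double> u(n, vrest), w(n, 0.0), vm(n, vrest);
  // gating states at rest
  std::vector<double> m(nnode), h(nnode), p(nnode), s(nnode);
  {
    double r[8]; axon_rates(vrest, r);
    for (int k = 0; k < nnode; ++k) {
      m[k] = r[0] / (r[0] + r[1]); h[k] = r[2] / (r[2] + r[3]);
      p[k] = r[4] / (r[4] + r[5]); s[k] = r[6] / (r[6] + r[7]);
    }
  }
  std::vector<int> comp_is_node(n, -1);
  for (int k = 0; k < nnode; ++k) comp_is_node[node_idx[k] - 1] = k;

  // block Thomas working arrays
  std::vector<double> D11(n), D12(n), D21(n), D22(n), R1(n), R2(n);
  std::vector<double> gt(n), se(n);
  std::vector<double> cU11(n), cU12(n), cU21(n), cU22(n), cR1(n), cR2(n);

  const int n_settle = (int)std::round(settle_ms / dt);
  const int n_stim = current_ua.size();
  const int n_steps = n_settle + n_stim;

  std::vector< std::vector<double> > spikes(nnode);
  std::vector<double> last_spike(nnode, -1e9);
  std::vector<double> vm_node_prev(nnode, vrest);
  bool diverged = false;

  double ve_now = 0.0, ve_next = 0.0;
  std::vector<double> trace;
  if (trace_comp > 0) trace.reserve(n_steps);

  for (int step = 0; step < n_steps && !diverged; ++step) {
    const bool in_stim = step >= n_settle;
    const double i_now = in_stim ? current_ua[step - n_settle] : 0.0;
    const double i_next = (step + 1 >= n_settle && step + 1 - n_settle < n_stim)
                            ? current_ua[step + 1 - n_settle] : 0.0;

    // gating at the current potential (staggered)
    for (int k = 0; k < nnode; ++k) {
      const int i = node_idx[k] - 1;
      double r[8]; axon_rates(vm[i], r);
      double a, tau;
      a = r[0] + r[1]; tau = std::exp(-dt * a);
      m[k] = r[0] / a + (m[k] - r[0] / a) * tau;
      a = r[2] + r[3]; tau = std::exp(-dt * a);
      h[k] = r[2] / a + (h[k] - r[2] / a) * tau;
      a = r[4] + r[5]; tau = std::exp(-dt * a);
      p[k] = r[4] / a + (p[k] - r[4] / a) * tau;
      a = r[6] + r[7]; tau = std::exp(-dt * a);
      s[k] = r[6] / a + (s[k] - r[6] / a) * tau;
    }

    // membrane conductance and driving terms
    for (int i = 0; i < n; ++i) {
      const int k = comp_is_node[i];
      if (k >= 0) {
        const double gna = gnaf[k] * m[k] * m[k] * m[k] * h[k];
        const double gnp = gnap[k] * p[k] * p[k] * p[k];
        const double gk = gks[k] * s[k];
        gt[i] = gna + gnp + gk + gl[k];
        se[i] = (gna + gnp) * ena + gk * ek + gl[k] * el;
      } else {
        gt[i] = gpas[i];
        se[i] = gpas[i] * el;  // passive reversal = leak reversal (rest)
      }
    }

    // assemble and solve the 2x2-block tridiagonal CN system
    for (int i = 0; i < n; ++i) {
      const double a_sum = (i > 0 ? ga[i - 1] : 0.0) + (i < n - 1 ? ga[i] : 0.0);
      const double p_sum = (i > 0 ? gp[i - 1] : 0.0) + (i < n - 1 ? gp[i] : 0.0);
      const double cmdt = cm[i] / dt, half_gt = 0.5 * gt[i];
      ve_now = phi_mv[i] * i_now; ve_next = phi_mv[i] * i_next;

      D11[i] = cmdt + half_gt + 0.5 * a_sum;
      D12[i] = -(cmdt + half_gt);
      D21[i] = -(cmdt + half_gt);
      D22[i] = cmdt + half_gt + cmy[i] / dt + 0.5 * gmy[i] + 0.5 * p_sum;

      double ax_expl = 0.0, pe_expl = 0.0;
      if (i > 0) { ax_expl += ga[i - 1] * (u[i] - u[i - 1]);
                   pe_expl += gp[i - 1] * (w[i] - w[i - 1]); }
      if (i < n - 1) { ax_expl += ga[i] * (u[i] - u[i + 1]);
                       pe_expl += gp[i] * (w[i] - w[i + 1]); }
      const double vm_i = u[i] - w[i];
      R1[i] = (cmdt - half_gt) * vm_i + se[i] - 0.5 * ax_expl;
      R2[i] = -(cmdt - half_gt) * vm_i - se[i] + (cmy[i] / dt) * w[i]
              - 0.5 * gmy[i] * (w[i] - ve_now) + 0.5 * gmy[i] * ve_next
              - 0.5 * pe_expl;
    }

    // forward elimination (off-diagonal blocks are diagonal matrices
    // L_i = diag(-0.5*ga[i-1], -0.5*gp[i-1]), U_i = diag(-0.5*ga[i], -0.5*gp[i]))
    {
      // block 0
      double a11 = D11[0], a12 = D12[0], a21 = D21[0], a22 = D22[0];
      double det = a11 * a22 - a12 * a21;
      // store inv(D0)*U0 and inv(D0)*R0
      double u1 = -0.5 * ga[0], u2 = -0.5 * gp[0];
      cU11[0] = (a22 * u1) / det;  cU12[0] = (-a12 * u2) / det;
      cU21[0] = (-a21 * u1) / det; cU22[0] = (a11 * u2) / det;
      cR1[0] = (a22 * R1[0] - a12 * R2[0]) / det;
      cR2[0] = (a11 * R2[0] - a21 * R1[0]) / det;
      for (int i = 1; i < n; ++i) {
        const double l1 = -0.5 * ga[i - 1], l2 = -0.5 * gp[i - 1];
        // Dtilde = D_i - L_i * cU_{i-1}
        double a11i = D11[i] - l1 * cU11[i - 1];
        double a12i = D12[i] - l1 * cU12[i - 1];
        double a21i = D21[i] - l2 * cU21[i - 1];
        double a22i = D22[i] - l2 * cU22[i - 1];
        double r1 = R1[i] - l1 * cR1[i - 1];
        double r2 = R2[i] - l2 * cR2[i - 1];
        double deti = a11i * a22i - a12i * a21i;
        if (i < n - 1) {
          double uu1 = -0.5 * ga[i], uu2 = -0.5 * gp[i];
          cU11[i] = (a22i * uu1) / deti;  cU12[i] = (-a12i * uu2) / deti;
          cU21[i] = (-a21i * uu1) / deti; cU22[i] = (a11i * uu2) / deti;
        }
        cR1[i] = (a22i * r1 - a12i * r2) / deti;
        cR2[i] = (a11i * r2 - a21i * r1) / deti;
      }
      // back substitution
      u[n - 1] = cR1[n - 1]; w[n - 1] = cR2[n - 1];
      for (int i = n - 2; i >= 0; --i) {
        u[i] = cR1[i] - (cU11[i] * u[i + 1] + cU12[i] * w[i + 1]);
        w[i] = cR2[i] - (cU21[i] * u[i + 1] + cU22[i] * w[i + 1]);
      }
    }

    const double t_rel = (step + 1 - n_settle) * dt;  // time in stim frame
    for (int i = 0; i < n; ++i) vm[i] = u[i] - w[i];
    for (int k = 0; k < nnode; ++k) {
      const int i = node_idx[k] - 1;
      const double v = vm[i];
      if (in_stim && vm_node_prev[k] < v_thresh && v >= v_thresh &&
          t_rel - last_spike[k] > lockout_ms) {
        spikes[k].push_back(t_rel);
        last_spike[k] = t_rel;
      }
      vm_node_prev[k] = v;
      if (!std::isfinite(v) || std::fabs(v) > v_diverge) diverged = true;
    }
    if (trace_comp > 0) trace.push_back(vm[trace_comp - 1]);
  }

  List spk(nnode);
  for (int k = 0; k < nnode; ++k) spk[k] = wrap(spikes[k]);
  return List::create(_["spikes_by_node"] = spk,
                      _["diverged"] = diverged,
                      _["vm_trace"] = wrap(trace));
}
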
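// Conductance-based dorsal horn network integrator.
//
// Nine four-compartment neurons (EX, IN, WDR per node), Hodgkin-Huxley-type
// Na / delayed-rectifier K on soma, hillock and axon, A-type K on the IN
// soma, slow Ca + Ca-dependent nonspecific cation (CAN) current on the WDR
// soma, and normalized double-exponential synapses (AMPA, NMDA with
// sigmoidal Mg block, NK1, GABA_A, glycine). Crank-Nicolson integration per
// neuron (tridiagonal solve over the 4-compartment chain) with staggered
// gating; synaptic conductances advance analytically between presynaptic
// events. Units: mV, ms, nF, uS, nA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double vtrap2(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

// [[Rcpp::export]]
List dh_network_simulate_cpp(List net, List streams, double duration_ms,
                             double dt, Nullable<List> state_in = R_NilValue,
                             bool return_state = false) {
  NumericMatrix cm = net["cm_nf"], gax = net["g_axial_us"];
  NumericMatrix gna = net["gna_us"], gk = net["gk_us"], gleak = net["gleak_us"];
  NumericMatrix gaA = net["ga_a_us"], gca = net["gca_us"], gcan = net["gcan_us"];
  List cfg = net["config"];
  NumericVector ecan_v = net["e_can_mv"];
  const double ena = cfg["e_na"], ek = cfg["e_k"], eleak = cfg["e_leak"];
  const double vinit = cfg["v_init"];
  const double eca = cfg["e_ca"];
  const double ca_gain = cfg["ca_gain"], ca_tau = cfg["ca_tau_ms"];
  const double ca_half = cfg["ca_half"];
  const double nmda_vhalf = cfg["nmda_vhalf"], nmda_slope = cfg["nmda_slope"];
  const double vth = cfg["spike_thresh_mv"], lockout = cfg["spike_lockout_ms"];

  DataFrame syn = as<DataFrame>(net["synapses"]);
  IntegerVector s_kind = syn["src_kind"], s_id = syn["src_id"];
  IntegerVector s_tgt = syn["tgt_neuron"], s_comp = syn["tgt_comp"];
  CharacterVector s_rec = syn["receptor"];
  NumericVector s_gmax = syn["gmax_ns"], s_tau1 = syn["tau1_ms"];
  NumericVector s_tau2 = syn["tau2_ms"], s_e = syn["e_syn_mv"];
  NumericVector s_delay = syn["delay_ms"];
  const int n_syn = s_kind.size();

  const int NN = 9, NC = 4;
  const int n_steps = (int)std::round(duration_ms / dt);

  // synapse precomputation
  std::vector<double> decay1(n_syn), decay2(n_syn), norm(n_syn);
  std::vector<int> is_nmda(n_syn), ptr(n_syn, 0);
  std::vector<double> A(n_syn, 0.0), B(n_syn, 0.0);
  for (int s = 0; s < n_syn; ++s) {
    decay1[s] = std::exp(-dt / s_tau1[s]);
    decay2[s] = std::exp(-dt / s_tau2[s]);
    const double tp = s_tau1[s] * s_tau2[s] / (s_tau2[s] - s_tau1[s]) *
                      std::log(s_tau2[s] / s_tau1[s]);
    norm[s] = 1.0 / (std::exp(-tp / s_tau2[s]) - std::exp(-tp / s_tau1[s]));
    is_nmda[s] = (s_rec[s] == "NMDA") ? 1 : 0;
  }
  // afferent stream spike arrays
  const int n_streams = streams.size();
  std::vector< std::vector<double> > stream_t(n_streams);
  for (int i = 0; i < n_streams; ++i) {
    stream_t[i] = as< std::vector<double> >(streams[i]);
  }
  // network spike stores (also the event source for neuron->neuron synapses)
  std::vector< std::vector<double> > spikes(NN);
  std::vector<double> last_spike(NN, -1e9);

  // states
  std::vector< std::vector<double> > V(NN, std::vector<double>(NC, vinit));
  std::vector<double> m(NN, 0), h(NN, 0), nK(NN, 0);       // soma
  std::vector<double> m3(NN, 0), h3(NN, 0), n3(NN, 0);     // hillock
  std::vector<double> m4(NN, 0), h4(NN, 0), n4(NN, 0);     // axon
  std::vector<double> aA(NN, 0), bA(NN, 0);                // IN A-type
  std::vector<double> mca(NN, 0), capool(NN, 0);           // WDR Ca / CAN
  LogicalVector diverged(NN);

  // rate helpers
  auto am = [](double v) { return 0.32 * vtrap2(v + 54.0, 4.0); };
  auto bm = [](double v) { return 0.28 * vtrap2(-(v + 27.0), 5.0); };
  auto ah = [](double v) { return 0.128 * std::exp(-(v + 50.0) / 18.0); };
  auto bh = [](double v) { return 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0)); };
  auto an = [](double v) { return 0.032 * vtrap2(v + 52.0, 5.0); };
  auto bn = [](double v) { return 0.5 * std::exp(-(v + 57.0) / 40.0); };

  for (int i = 0; i < NN; ++i) {
    const double v = vinit;
    m[i] = m3[i] = m4[i] = am(v) / (am(v) + bm(v));
    h[i] = h3[i] = h4[i] = ah(v) / (ah(v) + bh(v));
    nK[i] = n3[i] = n4[i] = an(v) / (an(v) + bn(v));
    aA[i] = 1.0 / (1.0 + std::exp(-(v + 50.0) / 20.0));
    bA[i] = 1.0 / (1.0 + std::exp((v + 80.0) / 6.0));
    mca[i] = 1.0 / (1.0 + std::exp(-(v + 30.0) / 7.0));
  }

  std::vector<double> gsyn(NN * NC), esyn_sum(NN * NC);
  std::vector<double> gt(NC), se(NC);
  std::vector<double> a_d(NC), b_d(NC), c_d(NC), r_d(NC);

  // resume from a checkpoint: restore all dynamic state and replay event
  // pointers up to the last executed step (bit-exact continuation as long as
  // stream content before the checkpoint is unchanged)
  int step0 = 0;
  if (state_in.isNotNull()) {
    List st(state_in);
    const double t0 = st["t_ms"];
    step0 = (int)std::round(t0 / dt);
    NumericMatrix Vst = st["v"];
    NumericMatrix G = st["gates"];
    NumericVector cap = st["capool"], Ast = st["A"], Bst = st["B"];
    NumericVector ls = st["last_spike"];
    List spk0 = st["spikes"];
    for (int i = 0; i < NN; ++i) {
      for (int c = 0; c < NC; ++c) V[i][c] = Vst(i, c);
      m[i] = G(i, 0); h[i] = G(i, 1); nK[i] = G(i, 2);
      m3[i] = G(i, 3); h3[i] = G(i, 4); n3[i] = G(i, 5);
      m4[i] = G(i, 6); h4[i] = G(i, 7); n4[i] = G(i, 8);
      aA[i] = G(i, 9); bA[i] = G(i, 10); mca[i] = G(i, 11);
      capool[i] = cap[i]; last_spike[i] = ls[i];
      spikes[i] = as< std::vector<double> >(spk0[i]);
    }
    for (int s = 0; s < n_syn; ++s) { A[s] = Ast[s]; B[s] = Bst[s]; }
    const double t_last = (step0 - 1) * dt;
    for (int s = 0; s < n_syn; ++s) {
      const std::vector<double>& src = (s_kind[s] == 0)
        ? stream_t[s_id[s] - 1] : spikes[s_id[s] - 1];
      const double dl = s_delay[s];
      int p = 0;
      while (p < (int)src.size() && src[p] + dl <= t_last) ++p;
      ptr[s] = p;
    }
  }

  for (int step = step0; step < n_steps; ++step) {
    const double t = step * dt;

    // --- synapses: decay, then deliver due events ---
    std::fill(gsyn.begin(), gsyn.end(), 0.0);
    std::fill(esyn_sum.begin(), esyn_sum.end(), 0.0);
    for (int s = 0; s < n_syn; ++s) {
      A[s] *= decay1[s]; B[s] *= decay2[s];
      const std::vector<double>& src = (s_kind[s] == 0)
        ? stream_t[s_id[s] - 1] : spikes[s_id[s] - 1];
      const double dl = s_delay[s];
      int& p = ptr[s];
      while (p < (int)src.size() && src[p] + dl <= t) { A[s] += 1.0; B[s] += 1.0; ++p; }
      double g = s_gmax[s] * 1e-3 * norm[s] * (B[s] - A[s]);  // nS -> uS
      if (g <= 0) continue;
      const int tn = s_tgt[s] - 1, tc = s_comp[s] - 1;
      if (is_nmda[s]) {
        const double v = V[tn][tc];
        g *= 1.0 / (1.0 + std::exp(-(v - nmda_vhalf) / nmda_slope));
      }
      gsyn[tn * NC + tc] += g;
      esyn_sum[tn * NC + tc] += g * s_e[s];
    }

    // --- neurons ---
    for (int i = 0; i < NN; ++i) {
      if (diverged[i]) continue;
      // gating (staggered, exponential updates at current V)
      const double v2 = V[i][1], v3 = V[i][2], v4 = V[i][3];
      auto upd = [&](double& x, double a, double b) {
        const double s0 = a + b; const double xi = a / s0;
        x = xi + (x - xi) * std::exp(-dt * s0);
      };
      upd(m[i], am(v2), bm(v2)); upd(h[i], ah(v2), bh(v2)); upd(nK[i], an(v2), bn(v2));
      upd(m3[i], am(v3), bm(v3)); upd(h3[i], ah(v3), bh(v3)); upd(n3[i], an(v3), bn(v3));
      upd(m4[i], am(v4), bm(v4)); upd(h4[i], ah(v4), bh(v4)); upd(n4[i], an(v4), bn(v4));
      if (gaA(i, 1) > 0) {
        const double ainf = 1.0 / (1.0 + std::exp(-(v2 + 50.0) / 20.0));
        const double binf = 1.0 / (1.0 + std::exp((v2 + 80.0) / 6.0));
        aA[i] = ainf + (aA[i] - ainf) * std::exp(-dt / 5.0);
        bA[i] = binf + (bA[i] - binf) * std::exp(-dt / 150.0);
      }
      if (gca(i, 1) > 0) {
        const double minf = 1.0 / (1.0 + std::exp(-(v2 + 30.0) / 7.0));
        mca[i] = minf + (mca[i] - minf) * std::exp(-dt / 15.0);
        const double ica = gca(i, 1) * mca[i] * mca[i] * (v2 - eca); // nA
        capool[i] += dt * (-ca_gain * ica - capool[i] / ca_tau);
        if (capool[i] < 0) capool[i] = 0;
      }

      // per-compartment conductance and driving terms
      for (int c = 0; c < NC; ++c) {
        double g = gleak(i, c), e = gleak(i, c) * eleak;
        double gna_c = 0, gk_c = 0;
        if (c == 1) { gna_c = gna(i, 1) * m[i] * m[i] * m[i] * h[i];
                      gk_c = gk(i, 1) * nK[i] * nK[i] * nK[i] * nK[i]; }
        else if (c == 2) { gna_c = gna(i, 2) * m3[i] * m3[i] * m3[i] * h3[i];
                           gk_c = gk(i, 2) * n3[i] * n3[i] * n3[i] * n3[i]; }
        else if (c == 3) { gna_c = gna(i, 3) * m4[i] * m4[i] * m4[i] * h4[i];
                           gk_c = gk(i, 3) * n4[i] * n4[i] * n4[i] * n4[i]; }
        g += gna_c + gk_c; e += gna_c * ena + gk_c * ek;
        if (c == 1) {
          if (gaA(i, 1) > 0) { const double gA = gaA(i, 1) * aA[i] * bA[i];
                               g += gA; e += gA * ek; }
          if (gca(i, 1) > 0) {
            const double gC = gca(i, 1) * mca[i] * mca[i];
            g += gC; e += gC * eca;
            const double w = capool[i] * capool[i] /
              (capool[i] * capool[i] + ca_half * ca_half);
            const double gN = gcan(i, 1) * w;
            g += gN; e += gN * ecan_v[i];
          }
        }
        g += gsyn[i * NC + c]; e += esyn_sum[i * NC + c];
        gt[c] = g; se[c] = e;
      }

      // Crank-Nicolson tridiagonal solve over the 4-compartment chain
      for (int c = 0; c < NC; ++c) {
        const double cmdt = cm(i, c) / dt;
        double axsum = 0, ax_expl = 0;
        if (c > 0) { axsum += gax(i, c - 1);
                     ax_expl += gax(i, c - 1) * (V[i][c] - V[i][c - 1]); }
        if (c < NC - 1) { axsum += gax(i, c);
                          ax_expl += gax(i, c) * (V[i][c] - V[i][c + 1]); }
        b_d[c] = cmdt + 0.5 * gt[c] + 0.5 * axsum;
        a_d[c] = (c > 0) ? -0.5 * gax(i, c - 1) : 0.0;
        c_d[c] = (c < NC - 1) ? -0.5 * gax(i, c) : 0.0;
        r_d[c] = (cmdt - 0.5 * gt[c]) * V[i][c] + se[c] - 0.5 * ax_expl;
      }
      for (int c = 1; c < NC; ++c) {
        const double w = a_d[c] / b_d[c - 1];
        b_d[c] -= w * c_d[c - 1];
        r_d[c] -= w * r_d[c - 1];
      }
      double vprev_soma = V[i][1];
      V[i][NC - 1] = r_d[NC - 1] / b_d[NC - 1];
      for (int c = NC - 2; c >= 0; --c) {
        V[i][c] = (r_d[c] - c_d[c] * V[i][c + 1]) / b_d[c];
      }
      const double vs = V[i][1];
      if (!std::isfinite(vs)) { diverged[i] = true; continue; }
      if (vprev_soma < vth && vs >= vth && (t + dt) - last_spike[i] > lockout) {
        spikes[i].push_back(t + dt);
        last_spike[i] = t + dt;
      }
    }
  }

  List spk(NN);
  for (int i = 0; i < NN; ++i) spk[i] = wrap(spikes[i]);
  List out = List::create(_["spikes"] = spk, _["diverged"] = diverged);
  if (return_state) {
    NumericMatrix Vst(NN, NC), G(NN, 12);
    NumericVector cap(NN), ls(NN), Ast(n_syn), Bst(n_syn);
    for (int i = 0; i < NN; ++i) {
      for (int c = 0; c < NC; ++c) Vst(i, c) = V[i][c];
      G(i, 0) = m[i]; G(i, 1) = h[i]; G(i, 2) = nK[i];
      G(i, 3) = m3[i]; G(i, 4) = h3[i]; G(i, 5) = n3[i];
      G(i, 6) = m4[i]; G(i, 7) = h4[i]; G(i, 8) = n4[i];
      G(i, 9) = aA[i]; G(i, 10) = bA[i]; G(i, 11) = mca[i];
      cap[i] = capool[i]; ls[i] = last_spike[i];
    }
    for (int s = 0; s < n_syn; ++s) { Ast[s] = A[s]; Bst[s] = B[s]; }
    out["state"] = List::create(_["t_ms"] = n_steps * dt, _["v"] = Vst,
                                _["gates"] = G, _["capool"] = cap,
                                _["A"] = Ast, _["B"] = Bst,
                                _["last_spike"] = ls, _["spikes"] = spk);
  }
  return out;
}
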
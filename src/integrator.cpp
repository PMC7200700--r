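// Compartmental Hodgkin-Huxley integrator.
//
// Backward-Euler voltage update with a Hines (tree-ordered) direct solve,
// exponential-Euler gating-state updates, and event-driven double-exponential
// synaptic conductances. Channel set (9 conductances incl. leak) plus an
// intracellular calcium pool gives 18 coupled state equations per
// compartment: V, [Ca] and 16 gating states
//   Na: m, h, s, d        (fast act., fast inact., two slow-inact. states)
//   KDR: n, k             (activation + slow inactivation)
//   KA: a, b  KM: u
//   KC: c, o              (voltage- and calcium-dependent activation)
//   KAHP: q  CaL: e, f    (f = calcium-dependent inactivation)
//   HCN: hf, hs           (fast and slow components)
//
// Units: mV, ms, nA, nF, uS; densities S/cm2 and uF/cm2 scaled by area.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int N_GATES = 16;
static const int N_CHAN = 8; // active channels: Na KDR KA KM KC KAHP CaL HCN

// kinetic parameter layout (see R/kinetics_config): for each of the 12
// voltage gates: vhalf, slope (signed), tau (ms); then floors for s, d, kdr-k;
// then Ca constants and reversals.
struct Kinetics {
  double vh[12], k[12], tau[12];
  double floor_s, floor_d, floor_kdr;
  double kd_kc, kd_ahp, kd_cal, tau_o, tau_q, tau_f;
  double ca_phi, ca_rest, ca_tau;
  double e_na, e_k, e_ca, e_h;
};

// voltage gate order within the 12 V-dependent gates:
// 0 Na.m 1 Na.h 2 Na.s 3 Na.d 4 KDR.n 5 KDR.k 6 KA.a 7 KA.b 8 KM.u
// 9 KC.c 10 CaL.e 11 HCN.h (shared vhalf/slope for hf/hs; taus differ)
static Kinetics parse_kin(const NumericVector& kin) {
  if (kin.size() < 12 * 3 + 3 + 6 + 3 + 4)
    stop("kinetics parameter vector too short");
  Kinetics K;
  int p = 0;
  for (int g = 0; g < 12; ++g) { K.vh[g] = kin[p++]; K.k[g] = kin[p++]; K.tau[g] = kin[p++]; }
  K.floor_s = kin[p++]; K.floor_d = kin[p++]; K.floor_kdr = kin[p++];
  K.kd_kc = kin[p++]; K.kd_ahp = kin[p++]; K.kd_cal = kin[p++];
  K.tau_o = kin[p++]; K.tau_q = kin[p++]; K.tau_f = kin[p++];
  K.ca_phi = kin[p++]; K.ca_rest = kin[p++]; K.ca_tau = kin[p++];
  K.e_na = kin[p++]; K.e_k = kin[p++]; K.e_ca = kin[p++]; K.e_h = kin[p++];
  return K;
}

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

// [[Rcpp::export(name = ".hh_integrate_cpp")]]
List hh_integrate_cpp(IntegerVector parent,       // 0-based, -1 root; parent[i] < i
                      NumericVector area_cm2,
                      NumericVector cm_uF_cm2,
                      NumericVector gpas_S_cm2,
                      double e_pas,
                      NumericVector g_axial_uS,   // coupling to parent, root 0
                      NumericMatrix gbar_S_cm2,   // n_comp x 8
                      NumericVector kin,
                      IntegerVector syn_comp,     // 0-based per synaptic group
                      NumericVector syn_tau_rise,
                      NumericVector syn_tau_decay,
                      NumericVector syn_erev,
                      IntegerVector ev_group,     // 0-based, times sorted
                      NumericVector ev_time,
                      NumericVector ev_weight,    // uS (already peak-normalized)
                      IntegerVector inj_comp,     // 0-based current steps
                      NumericVector inj_t0,
                      NumericVector inj_t1,
                      NumericVector inj_amp_nA,
                      double dt, double duration, double v_init,
                      IntegerVector rec_idx,      // 0-based
                      int rec_every) {
  const int n = parent.size();
  if (gbar_S_cm2.nrow() != n || gbar_S_cm2.ncol() != N_CHAN)
    stop("gbar matrix must be n_comp x 8");
  for (int i = 1; i < n; ++i)
    if (parent[i] < 0 || parent[i] >= i)
      stop("compartments must be ordered parents-first");
  Kinetics K = parse_kin(kin);

  std::vector<double> C(n), Gpas(n);
  std::vector< std::vector<double> > G(N_CHAN, std::vector<double>(n));
  for (int i = 0; i < n; ++i) {
    C[i] = cm_uF_cm2[i] * area_cm2[i] * 1e3;      // nF
    Gpas[i] = gpas_S_cm2[i] * area_cm2[i] * 1e6;  // uS
    for (int c = 0; c < N_CHAN; ++c)
      G[c][i] = gbar_S_cm2(i, c) * area_cm2[i] * 1e6;
  }

  // gate states: [gate][comp]; V-gate alphas (constant tau exponential Euler)
  double alpha[12], alpha_hs, alpha_o, alpha_q, alpha_f;
  for (int g = 0; g < 12; ++g) alpha[g] = 1.0 - std::exp(-dt / K.tau[g]);
  alpha_hs = 1.0 - std::exp(-dt / (K.tau[11] * 7.5)); // slow HCN component
  alpha_o = 1.0 - std::exp(-dt / K.tau_o);
  alpha_q = 1.0 - std::exp(-dt / K.tau_q);
  alpha_f = 1.0 - std::exp(-dt / K.tau_f);

  // voltage lookup tables for the 12 Boltzmann steady states, interleaved
  // (all 12 gates contiguous per voltage bin) for cache locality
  const double VMIN = -120.0, VMAX = 80.0, VSTEP = 0.05;
  const int NTAB = (int)((VMAX - VMIN) / VSTEP) + 2;
  std::vector<double> tab((size_t)NTAB * 12);
  for (int j = 0; j < NTAB; ++j)
    for (int g = 0; g < 12; ++g)
      tab[(size_t)j * 12 + g] = boltz(VMIN + j * VSTEP, K.vh[g], K.k[g]);

  std::vector<double> V(n, v_init), Ca(n, K.ca_rest);
  std::vector< std::vector<double> > X(N_GATES, std::vector<double>(n));
  // init gates at steady state for v_init
  {
    double vv = v_init;
    for (int i = 0; i < n; ++i) {
      double b[12];
      for (int g = 0; g < 12; ++g) b[g] = boltz(vv, K.vh[g], K.k[g]);
      X[0][i] = b[0];
      X[1][i] = b[1];
      X[2][i] = K.floor_s + (1 - K.floor_s) * b[2];
      X[3][i] = K.floor_d + (1 - K.floor_d) * b[3];
      X[4][i] = b[4];
      X[5][i] = K.floor_kdr + (1 - K.floor_kdr) * b[5];
      X[6][i] = b[6]; X[7][i] = b[7]; X[8][i] = b[8]; X[9][i] = b[9];
      X[10][i] = Ca[i] / (Ca[i] + K.kd_kc);                    // KC.o
      X[11][i] = Ca[i] * Ca[i] / (Ca[i] * Ca[i] + K.kd_ahp * K.kd_ahp); // q
      X[12][i] = b[10];                                        // CaL.e
      X[13][i] = K.kd_cal / (K.kd_cal + Ca[i]);                // CaL.f
      X[14][i] = b[11]; X[15][i] = b[11];                      // HCN hf hs
    }
  }

  // synaptic groups
  const int ns = syn_comp.size();
  std::vector<double> A(ns, 0.0), B(ns, 0.0), decA(ns), decB(ns), normf(ns);
  for (int s = 0; s < ns; ++s) {
    double t1 = syn_tau_rise[s], t2 = syn_tau_decay[s];
    decA[s] = std::exp(-dt / t1);
    decB[s] = std::exp(-dt / t2);
    double tp = t1 * t2 / (t2 - t1) * std::log(t2 / t1);
    normf[s] = 1.0 / (std::exp(-tp / t2) - std::exp(-tp / t1));
  }

  const int nsteps = (int)std::floor(duration / dt + 0.5);
  const int nrec = rec_idx.size();
  const int nt = nsteps / rec_every + 1;
  NumericMatrix vout(nt, nrec);
  NumericVector tout(nt);
  for (int r = 0; r < nrec; ++r) vout(0, r) = V[rec_idx[r]];
  tout[0] = 0.0;

  std::vector<double> diag(n), rhs(n);
  int ev_ptr = 0, nev = ev_group.size(), rec_row = 1;

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;

    // deliver synaptic events in (t, t+dt]
    while (ev_ptr < nev && ev_time[ev_ptr] <= t + dt) {
      int g = ev_group[ev_ptr];
      double w = ev_weight[ev_ptr] * normf[g];
      A[g] += w; B[g] += w;
      ++ev_ptr;
    }
    for (int s = 0; s < ns; ++s) { A[s] *= decA[s]; B[s] *= decB[s]; }

    // gate + calcium update (exponential Euler at current V)
    for (int i = 0; i < n; ++i) {
      double vv = V[i];
      double u = (vv - VMIN) / VSTEP;
      int j = (int)u; if (j < 0) j = 0; if (j > NTAB - 2) j = NTAB - 2;
      double fr = u - j;
      double b[12];
      const double* t0 = &tab[(size_t)j * 12];
      for (int g = 0; g < 12; ++g)
        b[g] = t0[g] + fr * (t0[g + 12] - t0[g]);

      X[0][i] += (b[0] - X[0][i]) * alpha[0];
      X[1][i] += (b[1] - X[1][i]) * alpha[1];
      X[2][i] += (K.floor_s + (1 - K.floor_s) * b[2] - X[2][i]) * alpha[2];
      X[3][i] += (K.floor_d + (1 - K.floor_d) * b[3] - X[3][i]) * alpha[3];
      X[4][i] += (b[4] - X[4][i]) * alpha[4];
      X[5][i] += (K.floor_kdr + (1 - K.floor_kdr) * b[5] - X[5][i]) * alpha[5];
      X[6][i] += (b[6] - X[6][i]) * alpha[6];
      X[7][i] += (b[7] - X[7][i]) * alpha[7];
      X[8][i] += (b[8] - X[8][i]) * alpha[8];
      X[9][i] += (b[9] - X[9][i]) * alpha[9];
      double o_inf = Ca[i] / (Ca[i] + K.kd_kc);
      X[10][i] += (o_inf - X[10][i]) * alpha_o;
      double q_inf = Ca[i] * Ca[i] / (Ca[i] * Ca[i] + K.kd_ahp * K.kd_ahp);
      X[11][i] += (q_inf - X[11][i]) * alpha_q;
      X[12][i] += (b[10] - X[12][i]) * alpha[10];
      double f_inf = K.kd_cal / (K.kd_cal + Ca[i]);
      X[13][i] += (f_inf - X[13][i]) * alpha_f;
      X[14][i] += (b[11] - X[14][i]) * alpha[11];
      X[15][i] += (b[11] - X[15][i]) * alpha_hs;

      // calcium pool driven by CaL current density (mA/cm2; inward < 0)
      double ica = gbar_S_cm2(i, 6) * X[12][i] * X[12][i] * X[13][i] * (vv - K.e_ca);
      double dca = -K.ca_phi * ica - (Ca[i] - K.ca_rest) / K.ca_tau;
      Ca[i] += dt * dca;
      if (Ca[i] < 1e-8) Ca[i] = 1e-8;
    }

    // assemble backward-Euler system
    for (int i = 0; i < n; ++i) {
      double gNa  = G[0][i] * X[0][i] * X[0][i] * X[0][i] * X[1][i] * X[2][i] * X[3][i];
      double gKDR = G[1][i] * X[4][i] * X[4][i] * X[5][i];
      double gKA  = G[2][i] * X[6][i] * X[7][i];
      double gKM  = G[3][i] * X[8][i];
      double gKC  = G[4][i] * X[9][i] * X[10][i];
      double gAHP = G[5][i] * X[11][i];
      double gCaL = G[6][i] * X[12][i] * X[12][i] * X[13][i];
      double gH   = G[7][i] * (0.6 * X[14][i] + 0.4 * X[15][i]);
      double gsum = Gpas[i] + gNa + gKDR + gKA + gKM + gKC + gAHP + gCaL + gH;
      double gE = Gpas[i] * e_pas + gNa * K.e_na +
        (gKDR + gKA + gKM + gKC + gAHP) * K.e_k + gCaL * K.e_ca + gH * K.e_h;
      diag[i] = C[i] / dt + gsum;
      rhs[i] = C[i] / dt * V[i] + gE;
    }
    for (int s = 0; s < ns; ++s) {
      double gs = B[s] - A[s];
      if (gs < 0) gs = 0;
      int i = syn_comp[s];
      diag[i] += gs;
      rhs[i] += gs * syn_erev[s];
    }
    for (int kI = 0; kI < inj_comp.size(); ++kI)
      if (t >= inj_t0[kI] && t < inj_t1[kI]) rhs[inj_comp[kI]] += inj_amp_nA[kI];
    for (int i = 1; i < n; ++i) {
      diag[i] += g_axial_uS[i];
      diag[parent[i]] += g_axial_uS[i];
    }

    // Hines solve (children have larger indices)
    for (int i = n - 1; i >= 1; --i) {
      double f = g_axial_uS[i] / diag[i];
      diag[parent[i]] -= f * g_axial_uS[i];
      rhs[parent[i]] += f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      V[i] = (rhs[i] + g_axial_uS[i] * V[parent[i]]) / diag[i];

    for (int i = 0; i < n; ++i)
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 200.0) {
        char msg[128];
        std::snprintf(msg, sizeof(msg),
                      "numerical divergence: |V| > 200 mV at compartment %d, t = %.3f ms",
                      i + 1, t + dt);
        stop(msg);
      }

    if ((step + 1) % rec_every == 0 && rec_row < nt) {
      for (int r = 0; r < nrec; ++r) vout(rec_row, r) = V[rec_idx[r]];
      tout[rec_row] = t + dt;
      ++rec_row;
    }
  }

  return List::create(_["t"] = tout, _["v"] = vout,
                      _["v_final"] = NumericVector(V.begin(), V.end()),
                      _["ca_final"] = NumericVector(Ca.begin(), Ca.end()));
}
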
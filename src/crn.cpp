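// Courtemanche-Ramirez-Nattel human atrial myocyte model (1998 formulation)
// with an acetylcholine-activated K+ current, plus a monodomain tissue
// stepper on precomputed coupling stencils.
//
// Integration scheme: Rush-Larsen exponential update for voltage-gated
// channels, forward Euler for concentrations and membrane potential.
// Voltage-dependent rate expressions are tabulated on a fine Vm grid
// (0.02 mV, linear interpolation) with the Rush-Larsen decay factors
// baked in for the run's fixed dt.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// ---- model constants ------------------------------------------------------
static const double Rgas = 8.3143, Temp = 310.0, Frd = 96.4867;
static const double RTF = Rgas * Temp / Frd;            // ~26.713 mV
static const double Cmem = 100.0;                       // pF
static const double Vi = 13668.0, Vup = 1109.52, Vrel = 96.48; // um^3
static const double Ko = 5.4, Nao = 140.0, Cao = 1.8;   // mM
static const double gNa = 7.8, gK1 = 0.09, gto = 0.1652;
static const double gKr = 0.029411765, gKs = 0.12941176, gCaL = 0.12375;
static const double gbCa = 0.001131, gbNa = 0.0006744375;
static const double INaKmax = 0.59933874, INaCamax = 1600.0, IpCamax = 0.275;
static const double KmNai = 10.0, KmKo = 1.5, KmNa = 87.5, KmCa = 1.38;
static const double ksat = 0.1, gma = 0.35;
static const double Krel = 30.0, Kup = 0.00092, Iupmax = 0.005, Caupmax = 15.0;
static const double tautr = 180.0, tauu = 8.0, taufca = 2.0;
static const double CMDNmax = 0.05, TRPNmax = 0.07, CSQNmax = 10.0;
static const double KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8;
static const double KQ10 = 3.0;
static const double NACA_DEN = (KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao);
static const double CF_ION = 1.0; // currents are pA/pF; Cm folds via Cmem where needed

// state layout (V held separately in tissue runs)
// 0 m 1 h 2 j 3 oa 4 oi 5 ua 6 ui 7 xr 8 xs 9 d 10 f 11 fca 12 u 13 vg 14 w
// 15 Nai 16 Ki 17 Cai 18 Caup 19 Carel
static const int NS = 20;
static const int NCH = 13; // INa ICaL Ito IKur IKr IKs IK1 IKACh INaCa INaK IbNa IbCa IpCa

static inline double safe_div(double num, double den, double lim) {
  return (std::fabs(den) < 1e-9) ? lim : num / den;
}

// ---- exact voltage-dependent kinetics (used for tables and direct calls) --
struct Rates {
  double minf, taum, hinf, tauh, jinf, tauj;
  double oainf, tauoa, oiinf, tauoi, uainf, tauua, uiinf, tauui;
  double xrinf, tauxr, xsinf, tauxs, dinf, taud, finf, tauf, winf, tauw;
};

static void gate_rates(double V, Rates &r) {
  // INa (Luo-Rudy type kinetics as adopted by the CRN model)
  double am = safe_div(0.32 * (V + 47.13), 1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  double bm = 0.08 * std::exp(-V / 11.0);
  r.minf = am / (am + bm); r.taum = 1.0 / (am + bm);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  r.hinf = ah / (ah + bh); r.tauh = 1.0 / (ah + bh);
  r.jinf = aj / (aj + bj); r.tauj = 1.0 / (aj + bj);
  // Ito
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r.tauoa = 1.0 / ((aoa + boa) * KQ10);
  r.oainf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  r.tauoi = 1.0 / ((aoi + boi) * KQ10);
  r.oiinf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  // IKur activation shares oa kinetics shape
  r.tauua = r.tauoa;
  r.uainf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  r.tauui = 1.0 / ((aui + bui) * KQ10);
  r.uiinf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  // IKr / IKs
  double axr = safe_div(0.0003 * (V + 14.1), 1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  double bxr = safe_div(7.3898e-5 * (V - 3.3328),
                        std::exp((V - 3.3328) / 5.1237) - 1.0, 7.3898e-5 * 5.1237);
  r.tauxr = 1.0 / (axr + bxr);
  r.xrinf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  double axs = safe_div(4e-5 * (V - 19.9), 1.0 - std::exp(-(V - 19.9) / 17.0), 4e-5 * 17.0);
  double bxs = safe_div(3.5e-5 * (V - 19.9), std::exp((V - 19.9) / 9.0) - 1.0, 3.5e-5 * 9.0);
  r.tauxs = 0.5 / (axs + bxs);
  r.xsinf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  // ICaL
  double xd = (V + 10.0) / 6.24;
  r.taud = safe_div(1.0 - std::exp(-xd), 0.035 * (V + 10.0) * (1.0 + std::exp(-xd)),
                    1.0 / (0.035 * 6.24 * 2.0));
  r.dinf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  r.tauf = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  r.finf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  // SR release w gate
  double xw = (V - 7.9) / 5.0;
  r.tauw = safe_div(6.0 * (1.0 - std::exp(-xw)),
                    (1.0 + 0.3 * std::exp(-xw)) * xw, 6.0 / 1.3);
  r.winf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
}

// voltage-only current factors
static inline double fac_ik1(double V)  { return 1.0 / (1.0 + std::exp(0.07 * (V + 80.0))); }
static inline double fac_ikr(double V)  { return 1.0 / (1.0 + std::exp((V + 15.0) / 22.4)); }
static inline double fac_gkur(double V) { return 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0)); }
static inline double fac_fnak(double V) {
  double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  return 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) + 0.0365 * sig * std::exp(-V / RTF));
}
static inline double fac_ikach(double V) {
  return 0.0517 + 0.4516 / (1.0 + std::exp((V + 59.53) / 17.18));
}

// ---- lookup table ---------------------------------------------------------
static const int NCOL = 32;
static const double TAB_VMIN = -120.0, TAB_VMAX = 80.0, TAB_DV = 0.02;

static std::vector<float> build_table(double dt) {
  int n = (int)std::floor((TAB_VMAX - TAB_VMIN) / TAB_DV) + 2;
  std::vector<float> tab((size_t)n * NCOL);
  Rates r;
  for (int i = 0; i < n; ++i) {
    double V = TAB_VMIN + i * TAB_DV;
    gate_rates(V, r);
    float *row = &tab[(size_t)i * NCOL];
    row[0] = r.minf;  row[1]  = std::exp(-dt / r.taum);
    row[2] = r.hinf;  row[3]  = std::exp(-dt / r.tauh);
    row[4] = r.jinf;  row[5]  = std::exp(-dt / r.tauj);
    row[6] = r.oainf; row[7]  = std::exp(-dt / r.tauoa);
    row[8] = r.oiinf; row[9]  = std::exp(-dt / r.tauoi);
    row[10] = r.uainf; row[11] = std::exp(-dt / r.tauua);
    row[12] = r.uiinf; row[13] = std::exp(-dt / r.tauui);
    row[14] = r.xrinf; row[15] = std::exp(-dt / r.tauxr);
    row[16] = r.xsinf; row[17] = std::exp(-dt / r.tauxs);
    row[18] = r.dinf;  row[19] = std::exp(-dt / r.taud);
    row[20] = r.finf;  row[21] = std::exp(-dt / r.tauf);
    row[22] = r.winf;  row[23] = std::exp(-dt / r.tauw);
    row[24] = fac_ik1(V);
    row[25] = fac_ikr(V);
    row[26] = fac_gkur(V);
    row[27] = fac_fnak(V);
    row[28] = std::exp(gma * V / RTF);
    row[29] = std::exp((gma - 1.0) * V / RTF);
    row[30] = fac_ikach(V);
    row[31] = 0.0;
  }
  return tab;
}

// Rush-Larsen decay factor for the SR v-gate, tau_v in [1.91, 4.0]:
// tabulated over the sigmoid argument s in [0,1] (tau_v = 1.91 + 2.09 s).
static std::vector<double> build_vgate_table(double dt) {
  int n = 1001;
  std::vector<double> t(n);
  for (int i = 0; i < n; ++i) {
    double s = (double)i / (n - 1);
    t[i] = std::exp(-dt / (1.91 + 2.09 * s));
  }
  return t;
}

// ---- reaction step --------------------------------------------------------
// Advances one node by dt. V by reference; s: 20 states; g: 13 scalings.
// dVext: external dV/dt (diffusion + stimulus), mV/ms. Returns new V.
struct StepCtx {
  const float *tab;
  const double *vtab;
  double dt, rl_u, rl_fca, achG;
};

// Adaptive reaction stepping: when the membrane-potential increment of a
// full step would exceed DV_MAX (fast upstroke), the step is re-done as two
// half steps, down to dt/4. Only depolarizing nodes pay the extra cost.
static const double DV_MAX = 4.0;

// 1/(1+exp(x)) on x in [-40, 40], 0.01 steps (SR-release gate sigmoids)
static std::vector<float> build_sig_table() {
  std::vector<float> t(8001);
  for (int i = 0; i <= 8000; ++i)
    t[i] = (float)(1.0 / (1.0 + std::exp(-40.0 + i * 0.01)));
  return t;
}
static const std::vector<float> SIGT = build_sig_table();
static inline double sig_lookup(double x) {
  if (x >= 40.0) return 0.0;
  if (x <= -40.0) return 1.0;
  return SIGT[(int)((x + 40.0) * 100.0 + 0.5)];
}

struct StepCtxSet {
  StepCtx lev[3];            // dt, dt/2, dt/4
  std::vector<float> tabs[3];
  std::vector<double> vtabs[3];
};

static void init_ctxset(StepCtxSet &cs, double dt, double ach) {
  double achG = ach > 0.0 ? 10.0 / (1.0 + 9.13652 / std::pow(ach, 0.477811)) : 0.0;
  for (int l = 0; l < 3; ++l) {
    double d = dt / (1 << l);
    cs.tabs[l] = build_table(d);
    cs.vtabs[l] = build_vgate_table(d);
    cs.lev[l] = StepCtx{cs.tabs[l].data(), cs.vtabs[l].data(), d,
                        std::exp(-d / tauu), std::exp(-d / taufca), achG};
  }
}

// Per-node slowly varying terms: Nernst potentials and the Nai-dependent
// Na/K-pump saturation factor. Exact in the cell driver; refreshed every
// few steps in tissue runs (their time scales are many ms).
struct SlowTerms { double eNa, eK, eCa, nak1; };

static inline void slow_terms(const double *s, SlowTerms &e) {
  double Nai = s[15], Ki = s[16], Cai = s[17];
  e.eNa = RTF * std::log(Nao / Nai);
  e.eK  = RTF * std::log(Ko / Ki);
  e.eCa = 0.5 * RTF * std::log(Cao / Cai);
  double tnk = KmNai / Nai;
  e.nak1 = 1.0 / (1.0 + tnk * std::sqrt(tnk));
}

// Advances one node by dt given external dV/dt (diffusion + stimulus) in
// mV/ms; updates gates/concentrations in place and returns the new Vm.
static double react_node_lvl(double V, double *s, const double *g,
                             const StepCtxSet &cs, int level, double dVext,
                             const SlowTerms &e);

static inline double react_node_v(double V, double *s, const double *g,
                                  const StepCtxSet &cs, double dVext,
                                  const SlowTerms &e) {
  return react_node_lvl(V, s, g, cs, 0, dVext, e);
}

static double react_node_lvl(double V, double *s, const double *g,
                             const StepCtxSet &cs, int level, double dVext,
                             const SlowTerms &e) {
  const StepCtx &cx = cs.lev[level];
  double Vc = V < TAB_VMIN ? TAB_VMIN : (V > TAB_VMAX - TAB_DV ? TAB_VMAX - TAB_DV : V);
  double x = (Vc - TAB_VMIN) * (1.0 / TAB_DV);
  int i0 = (int)x;
  double fr = x - i0;
  const float *r0 = cx.tab + (size_t)i0 * NCOL;
  const float *r1 = r0 + NCOL;
  double tv[31];
  for (int c = 0; c < 31; ++c) tv[c] = r0[c] + fr * (double)(r1[c] - r0[c]);

  double Nai = s[15], Cai = s[17], Caup = s[18], Carel = s[19];
  double ENa = e.eNa, EK = e.eK, ECa = e.eCa;

  double INa  = g[0] * gNa * s[0] * s[0] * s[0] * s[1] * s[2] * (V - ENa);
  double ICaL = g[1] * gCaL * s[9] * s[10] * s[11] * (V - 65.0);
  double Ito  = g[2] * gto * s[3] * s[3] * s[3] * s[4] * (V - EK);
  double IKur = g[3] * tv[26] * s[5] * s[5] * s[5] * s[6] * (V - EK);
  double IKr  = g[4] * gKr * s[7] * (V - EK) * tv[25];
  double IKs  = g[5] * gKs * s[8] * s[8] * (V - EK);
  double IK1  = g[6] * gK1 * (V - EK) * tv[24];
  double IKACh = cx.achG > 0.0 ? g[7] * cx.achG * tv[30] * (V - EK) : 0.0;
  double INaK = g[9] * INaKmax * tv[27] * (Ko / (Ko + KmKo)) * e.nak1;
  double INaCa = g[8] * (INaCamax / NACA_DEN) *
    (tv[28] * Nai * Nai * Nai * Cao - tv[29] * Nao * Nao * Nao * Cai) /
    (1.0 + ksat * tv[29]);
  double IbNa = g[10] * gbNa * (V - ENa);
  double IbCa = g[11] * gbCa * (V - ECa);
  double IpCa = g[12] * IpCamax * Cai / (0.0005 + Cai);

  double Iion = INa + ICaL + Ito + IKur + IKr + IKs + IK1 + IKACh +
                INaCa + INaK + IbNa + IbCa + IpCa;

  if (level < 2 && std::fabs(cx.dt * (dVext - Iion)) > DV_MAX) {
    double Vh = react_node_lvl(V, s, g, cs, level + 1, dVext, e);
    return react_node_lvl(Vh, s, g, cs, level + 1, dVext, e);
  }

  double Irel = Krel * s[12] * s[12] * s[13] * s[14] * (Carel - Cai);
  double Itr  = (Caup - Carel) * (1.0 / tautr);
  double Iup  = Iupmax * Cai / (Cai + Kup);
  double Iupleak = (Iupmax / Caupmax) * Caup;
  double Fn = 1e-12 * Vrel * Irel -
              (5e-13 / Frd) * (0.5 * ICaL - 0.2 * INaCa) * Cmem;

  double au = -(Fn - 3.4175e-13) * (1.0 / 13.67e-16);
  double sig_u = sig_lookup(au);
  double av = -(Fn - 6.835e-14) * (1.0 / 13.67e-16);
  double sig_v = sig_lookup(av);
  double uinf = sig_u;
  double vinf = 1.0 - sig_v;
  double rl_v = cx.vtab[(int)(sig_u * 1000.0 + 0.5)];

  double cf = Cmem / (Frd * Vi);
  double dNai = -(3.0 * INaK + 3.0 * INaCa + IbNa + INa) * cf;
  double dKi  = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs - IKACh) * cf;
  double b1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * (0.5 * cf) +
              (Vup * (Iupleak - Iup) + Irel * Vrel) * (1.0 / Vi);
  double tt = Cai + KmTrpn, tc = Cai + KmCmdn;
  double b2 = 1.0 + TRPNmax * KmTrpn / (tt * tt) + CMDNmax * KmCmdn / (tc * tc);
  double csq = Carel + KmCsqn;
  double dCarel = (Itr - Irel) / (1.0 + CSQNmax * KmCsqn / (csq * csq));
  double dCaup = Iup - Iupleak - Itr * (Vrel / Vup);

  s[0]  = tv[0]  + (s[0]  - tv[0])  * tv[1];
  s[1]  = tv[2]  + (s[1]  - tv[2])  * tv[3];
  s[2]  = tv[4]  + (s[2]  - tv[4])  * tv[5];
  s[3]  = tv[6]  + (s[3]  - tv[6])  * tv[7];
  s[4]  = tv[8]  + (s[4]  - tv[8])  * tv[9];
  s[5]  = tv[10] + (s[5]  - tv[10]) * tv[11];
  s[6]  = tv[12] + (s[6]  - tv[12]) * tv[13];
  s[7]  = tv[14] + (s[7]  - tv[14]) * tv[15];
  s[8]  = tv[16] + (s[8]  - tv[16]) * tv[17];
  s[9]  = tv[18] + (s[9]  - tv[18]) * tv[19];
  s[10] = tv[20] + (s[10] - tv[20]) * tv[21];
  double fcainf = 1.0 / (1.0 + Cai * (1.0 / 0.00035));
  s[11] = fcainf + (s[11] - fcainf) * cx.rl_fca;
  s[12] = uinf + (s[12] - uinf) * cx.rl_u;
  s[13] = vinf + (s[13] - vinf) * rl_v;
  s[14] = tv[22] + (s[14] - tv[22]) * tv[23];

  s[15] = Nai + cx.dt * dNai;
  s[16] = s[16] + cx.dt * dKi;
  double nc = Cai + cx.dt * b1 / b2;
  s[17] = nc > 1e-9 ? nc : 1e-9;
  s[18] = Caup + cx.dt * dCaup;
  s[19] = Carel + cx.dt * dCarel;

  return V + cx.dt * (dVext - Iion);
}

// ---- default state and direct current evaluation --------------------------

static const char *STATE_NAMES[21] = {
  "vm", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "fca",
  "u", "v", "w", "nai", "ki", "cai", "caup", "carel"};

// [[Rcpp::export]]
NumericVector crn_default_state() {
  NumericVector s(21);
  double init[21] = {-81.18, 2.908e-3, 9.649e-1, 9.775e-1, 3.043e-2, 9.992e-1,
                     4.966e-3, 9.986e-1, 3.296e-5, 1.869e-2, 1.367e-4, 9.996e-1,
                     7.755e-1, 0.0, 1.0, 9.992e-1, 11.17, 139.0, 1.013e-4,
                     1.488, 1.488};
  CharacterVector nm(21);
  for (int i = 0; i < 21; ++i) { s[i] = init[i]; nm[i] = STATE_NAMES[i]; }
  s.names() = nm;
  return s;
}

// Exact (non-tabulated) evaluation of all 13 membrane currents, pA/pF.
// [[Rcpp::export]]
NumericVector crn_ionic_currents(NumericVector state, NumericVector scaling,
                                 double ach = 0.0) {
  double V = state[0];
  const double *s = &state[1]; // 20 states following vm
  const double *g = &scaling[0];
  double Nai = s[15], Ki = s[16], Cai = s[17];
  double ENa = RTF * std::log(Nao / Nai);
  double EK  = RTF * std::log(Ko / Ki);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);
  double achG = ach > 0.0 ? 10.0 / (1.0 + 9.13652 / std::pow(ach, 0.477811)) : 0.0;

  NumericVector out(14);
  out[0] = g[0] * gNa * s[0] * s[0] * s[0] * s[1] * s[2] * (V - ENa);
  out[1] = g[1] * gCaL * s[9] * s[10] * s[11] * (V - 65.0);
  out[2] = g[2] * gto * s[3] * s[3] * s[3] * s[4] * (V - EK);
  out[3] = g[3] * fac_gkur(V) * s[5] * s[5] * s[5] * s[6] * (V - EK);
  out[4] = g[4] * gKr * s[7] * (V - EK) * fac_ikr(V);
  out[5] = g[5] * gKs * s[8] * s[8] * (V - EK);
  out[6] = g[6] * gK1 * (V - EK) * fac_ik1(V);
  out[7] = g[7] * achG * fac_ikach(V) * (V - EK);
  double e1 = std::exp(gma * V / RTF), e2 = std::exp((gma - 1.0) * V / RTF);
  out[8] = g[8] * INaCamax *
    (e1 * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai) /
    ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) * (1.0 + ksat * e2));
  double tnk = KmNai / Nai;
  out[9] = g[9] * INaKmax * fac_fnak(V) * (Ko / (Ko + KmKo)) /
           (1.0 + tnk * std::sqrt(tnk));
  out[10] = g[10] * gbNa * (V - ENa);
  out[11] = g[11] * gbCa * (V - ECa);
  out[12] = g[12] * IpCamax * Cai / (0.0005 + Cai);
  double tot = 0.0;
  for (int i = 0; i < 13; ++i) tot += out[i];
  out[13] = tot;
  out.names() = CharacterVector::create(
    "INa", "ICaL", "Ito", "IKur", "IKr", "IKs", "IK1", "IKACh", "INaCa",
    "INaK", "IbNa", "IbCa", "IpCa", "Iion");
  return out;
}

// ---- per-node online AP event detection -----------------------------------
struct NodeDetect {
  double v_diast;    // running diastolic (pre-upstroke) potential
  double v_peak, t_act, dvdtmax;
  long pending;      // index of the event row awaiting repolarization
  int phase;         // 0 diastole, 1 action potential
};

struct EventLog {
  std::vector<double> node, t_act, apd90, dvdtmax, v_peak, v_takeoff;
};

// Logs an event row at activation (upstroke crossing of vthr); APD90,
// peak and maximal dV/dt are filled in once 90% repolarization is seen.
static inline bool detect_update(NodeDetect &d, EventLog &ev, int node,
                                 double t, double dt, double vold, double vnew,
                                 double vthr) {
  bool activated = false;
  if (d.phase == 0) {
    if (vnew < d.v_diast) d.v_diast = vnew;
    if (vold < vthr && vnew >= vthr) {
      double frac = (vthr - vold) / (vnew - vold);
      d.t_act = t + frac * dt;
      d.v_peak = vnew;
      d.dvdtmax = (vnew - vold) / dt;
      d.phase = 1;
      activated = true;
      d.pending = (long)ev.node.size();
      ev.node.push_back((double)(node + 1));
      ev.t_act.push_back(d.t_act);
      ev.apd90.push_back(NA_REAL);
      ev.dvdtmax.push_back(NA_REAL);
      ev.v_peak.push_back(NA_REAL);
      ev.v_takeoff.push_back(d.v_diast);
    }
  } else {
    double dv = (vnew - vold) / dt;
    if (dv > d.dvdtmax) d.dvdtmax = dv;
    if (vnew > d.v_peak) d.v_peak = vnew;
    double v90 = d.v_peak - 0.9 * (d.v_peak - d.v_diast);
    if (vnew <= v90 && vold > v90) {
      double frac = (vold - v90) / (vold - vnew);
      double t90 = t + frac * dt;
      ev.apd90[d.pending] = t90 - d.t_act;
      ev.dvdtmax[d.pending] = d.dvdtmax; // mV/ms == V/s
      ev.v_peak[d.pending] = d.v_peak;
      d.phase = 0;
      d.v_diast = vnew;
    }
  }
  return activated;
}

static List eventlog_to_list(const EventLog &ev) {
  return List::create(
    _["node"] = wrap(ev.node), _["t_act"] = wrap(ev.t_act),
    _["apd90"] = wrap(ev.apd90), _["dvdt_max"] = wrap(ev.dvdtmax),
    _["v_peak"] = wrap(ev.v_peak), _["v_takeoff"] = wrap(ev.v_takeoff));
}

// ---- single-cell driver ----------------------------------------------------
// stim: matrix with columns t_on, duration, amplitude (pA/pF, depolarizing
// positive). Records vm every rec_dt.
// [[Rcpp::export]]
List crn_cell_run(NumericVector state0, NumericVector scaling,
                  NumericMatrix stim, double t_end, double dt,
                  double rec_dt, double ach = 0.0, double vthresh = -40.0) {
  if (dt <= 0 || dt > 0.11)
    stop("dt = %f ms outside the declared stability bound (0, 0.11] for the cell model", dt);
  StepCtxSet cs;
  init_ctxset(cs, dt, ach);

  double V = state0[0];
  double s[NS];
  for (int i = 0; i < NS; ++i) s[i] = state0[i + 1];
  const double *g = &scaling[0];

  long nsteps = (long)std::llround(t_end / dt);
  int rec_every = rec_dt > 0 ? (int)std::llround(rec_dt / dt) : 0;
  std::vector<double> tr_t, tr_v;
  if (rec_every > 0) { tr_t.reserve(nsteps / rec_every + 2); tr_v.reserve(nsteps / rec_every + 2); }

  NodeDetect det{V, 0, 0, 0, -1, 0};
  EventLog ev;

  int nstim = stim.nrow();
  if (rec_every > 0) { tr_t.push_back(0.0); tr_v.push_back(V); }
  SlowTerms et;
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    double amp = 0.0;
    for (int e = 0; e < nstim; ++e)
      if (t >= stim(e, 0) && t < stim(e, 0) + stim(e, 1)) amp += stim(e, 2);
    double vold = V;
    slow_terms(s, et);
    V = react_node_v(V, s, g, cs, amp, et);
    if (!std::isfinite(V) || std::fabs(V) > 200.0)
      stop("integration unstable at step %ld (t = %.3f ms): vm = %f", k, t, V);
    detect_update(det, ev, 0, t, dt, vold, V, vthresh);
    if (rec_every > 0 && ((k + 1) % rec_every == 0)) {
      tr_t.push_back((k + 1) * dt);
      tr_v.push_back(V);
    }
  }

  NumericVector sf(21);
  sf[0] = V;
  for (int i = 0; i < NS; ++i) sf[i + 1] = s[i];
  CharacterVector nm(21);
  for (int i = 0; i < 21; ++i) nm[i] = STATE_NAMES[i];
  sf.names() = nm;

  return List::create(
    _["time_ms"] = wrap(tr_t), _["vm_mV"] = wrap(tr_v),
    _["events"] = eventlog_to_list(ev), _["state"] = sf);
}

// ---- tissue driver ---------------------------------------------------------
// Coupling operator in CSR form (0-based): row_ptr (N+1), col, w (1/ms);
// diagonal passed separately. alive[i] = 0 marks lesion/hole nodes (clamped).
// scaling: 13 x N matrix (column per node). stim_nodes: list of 0-based
// integer vectors; stim_par: matrix t_on, dur, amp.
// rec_nodes: 0-based nodes recorded every rec_dt (0 = none).
// rec2: all-node window recorder [rec2_t0, rec2_t1] every rec2_dt (0 = off).
// Early stop: if quiet_stop > 0 and no activation anywhere for quiet_stop ms
// after t_quiet_from, the run ends early.
// [[Rcpp::export]]
List crn_tissue_run(NumericVector state0, IntegerVector row_ptr,
                    IntegerVector col, NumericVector w, NumericVector diag,
                    IntegerVector alive, NumericMatrix scaling,
                    List stim_nodes, NumericMatrix stim_par,
                    double t_end, double dt, double rec_dt,
                    IntegerVector rec_nodes, double rec2_t0, double rec2_t1,
                    double rec2_dt, double ach = 0.0, double vthresh = -40.0,
                    double quiet_stop = 0.0, double t_quiet_from = 0.0,
                    Nullable<NumericMatrix> init_override = R_NilValue) {
  int N = alive.size();
  if (dt <= 0 || dt > 0.11)
    stop("dt = %f ms outside the declared stability bound (0, 0.11]", dt);
  // explicit-diffusion stability check
  double wmax = 0.0;
  for (int i = 0; i < N; ++i) if (-diag[i] > wmax) wmax = -diag[i];
  if (dt * wmax > 0.9)
    stop("dt = %.3f ms violates the diffusion stability bound (dt * max row sum = %.3f > 0.9)",
         dt, dt * wmax);

  StepCtxSet cs;
  init_ctxset(cs, dt, ach);

  std::vector<double> V(N), lap(N), stimbuf(N, 0.0);
  std::vector<SlowTerms> eterm(N);
  std::vector<double> S((size_t)N * NS);
  NumericMatrix iovr;
  bool has_override = init_override.isNotNull();
  if (has_override) {
    iovr = NumericMatrix(init_override.get());
    if (iovr.nrow() != 21 || iovr.ncol() != N)
      stop("init_override must be a 21 x n_nodes state matrix");
  }
  for (int i = 0; i < N; ++i) {
    if (has_override) {
      V[i] = iovr(0, i);
      for (int q = 0; q < NS; ++q) S[(size_t)i * NS + q] = iovr(q + 1, i);
    } else {
      V[i] = state0[0];
      for (int q = 0; q < NS; ++q) S[(size_t)i * NS + q] = state0[q + 1];
    }
  }

  for (int i = 0; i < N; ++i) slow_terms(&S[(size_t)i * NS], eterm[i]);

  // deduplicate scaling columns: most nodes share a handful of profiles,
  // which keeps the per-node channel factors hot in L1
  std::vector<double> profs;
  std::vector<int> prof_of(N);
  {
    std::vector<int> rep;  // representative node of each profile
    for (int i = 0; i < N; ++i) {
      const double *ci = &scaling[(size_t)i * NCH];
      int found = -1;
      for (size_t p = 0; p < rep.size(); ++p) {
        const double *cp = &scaling[(size_t)rep[p] * NCH];
        bool eq = true;
        for (int q = 0; q < NCH; ++q) if (ci[q] != cp[q]) { eq = false; break; }
        if (eq) { found = (int)p; break; }
      }
      if (found < 0) { rep.push_back(i); found = (int)rep.size() - 1; }
      prof_of[i] = found;
      if (rep.size() > 64) break; // fall back below if too many distinct
    }
    if (rep.size() <= 64) {
      profs.resize(rep.size() * NCH);
      for (size_t p = 0; p < rep.size(); ++p)
        std::memcpy(&profs[p * NCH], &scaling[(size_t)rep[p] * NCH],
                    sizeof(double) * NCH);
    } else {
      profs.assign(&scaling[0], &scaling[0] + (size_t)N * NCH);
      for (int i = 0; i < N; ++i) prof_of[i] = i;
    }
  }
  const double *scal = profs.data(); // indexed via prof_of

  int nstim = stim_par.nrow();
  std::vector<std::vector<int>> snodes(nstim);
  for (int e = 0; e < nstim; ++e) {
    IntegerVector v = stim_nodes[e];
    snodes[e] = std::vector<int>(v.begin(), v.end());
  }

  long nsteps = (long)std::llround(t_end / dt);
  int rec_every = (rec_dt > 0 && rec_nodes.size() > 0) ? (int)std::llround(rec_dt / dt) : 0;
  int nrec = rec_nodes.size();
  std::vector<double> tr_t;
  std::vector<double> tr_v; // nrec x nt, column per time point
  int rec2_every = rec2_dt > 0 ? (int)std::llround(rec2_dt / dt) : 0;
  std::vector<double> tr2_t, tr2_v;

  std::vector<NodeDetect> det(N);
  for (int i = 0; i < N; ++i) det[i] = NodeDetect{V[i], 0, 0, 0, -1, 0};
  EventLog ev;
  double last_act = 0.0;
  bool stopped_early = false;
  double t_stop = t_end;

  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    // stimulus accumulation
    bool any_stim = false;
    for (int e = 0; e < nstim; ++e) {
      if (t >= stim_par(e, 0) && t < stim_par(e, 0) + stim_par(e, 1)) {
        if (!any_stim) { std::memset(stimbuf.data(), 0, sizeof(double) * N); any_stim = true; }
        for (int id : snodes[e]) stimbuf[id] += stim_par(e, 2);
      }
    }
    // diffusion
    for (int i = 0; i < N; ++i) {
      double acc = diag[i] * V[i];
      for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p)
        acc += w[p] * V[col[p]];
      lap[i] = acc;
    }
    // reaction (Nernst/pump slow terms refreshed every 16 steps)
    bool refresh = (k & 0xF) == 0;
    for (int i = 0; i < N; ++i) {
      if (!alive[i]) continue;
      double *si = &S[(size_t)i * NS];
      if (refresh) slow_terms(si, eterm[i]);
      double dVext = lap[i] + (any_stim ? stimbuf[i] : 0.0);
      double vold = V[i];
      double vnew = react_node_v(vold, si, scal + (size_t)prof_of[i] * NCH, cs, dVext, eterm[i]);
      if (!std::isfinite(vnew) || std::fabs(vnew) > 200.0)
        stop("integration unstable at t = %.2f ms, node %d: vm = %f", t, i + 1, vnew);
      V[i] = vnew;
      if (detect_update(det[i], ev, i, t, dt, vold, vnew, vthresh))
        last_act = t;
    }
    double tnow = (k + 1) * dt;
    if (rec_every > 0 && ((k + 1) % rec_every == 0)) {
      tr_t.push_back(tnow);
      for (int r = 0; r < nrec; ++r) tr_v.push_back(V[rec_nodes[r]]);
    }
    if (rec2_every > 0 && tnow >= rec2_t0 && tnow <= rec2_t1 &&
        ((k + 1) % rec2_every == 0)) {
      tr2_t.push_back(tnow);
      for (int i = 0; i < N; ++i) tr2_v.push_back(V[i]);
    }
    if (quiet_stop > 0 && tnow > t_quiet_from &&
        tnow - std::max(last_act, t_quiet_from - quiet_stop) > quiet_stop) {
      stopped_early = true;
      t_stop = tnow;
      break;
    }
    if ((k & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix vm(nrec, (int)tr_t.size());
  if (nrec > 0 && tr_t.size() > 0)
    std::memcpy(&vm[0], tr_v.data(), sizeof(double) * tr_v.size());
  NumericMatrix vm2(tr2_t.size() > 0 ? N : 0, (int)tr2_t.size());
  if (tr2_t.size() > 0)
    std::memcpy(&vm2[0], tr2_v.data(), sizeof(double) * tr2_v.size());

  NumericMatrix sf(21, N);
  for (int i = 0; i < N; ++i) {
    sf(0, i) = V[i];
    for (int q = 0; q < NS; ++q) sf(q + 1, i) = S[(size_t)i * NS + q];
  }

  return List::create(
    _["time_ms"] = wrap(tr_t), _["vm"] = vm,
    _["time2_ms"] = wrap(tr2_t), _["vm2"] = vm2,
    _["events"] = eventlog_to_list(ev),
    _["stopped_early"] = stopped_early, _["t_stop"] = t_stop,
    _["state_final"] = sf);
}
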
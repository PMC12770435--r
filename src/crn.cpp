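// Modified Courtemanche-Ramirez-Nattel (CRN++) human atrial myocyte model
// with extracellular-electrolyte parameterisation, per-current electrolyte
// override masks, fibrosis remodelling hooks, a Rush-Larsen 0D stepper and a
// monodomain finite-difference tissue solver (1D strands / 2D sheets).
//
// Units: time ms, voltage mV, concentrations mM, conductances nS/pF,
// currents pA/pF (whole-cell pA = Cm * pA/pF with Cm = 100 pF), space cm,
// diffusivity cm^2/ms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// ---- canonical layouts (mirrored in R/cell_model.R; keep in sync) ---------

enum ParamIdx {
  P_GNA = 0, P_GK1, P_GTO, P_GKR, P_GKS, P_GCAL, P_GBCA, P_GBNA,
  P_INAKMAX, P_INACAMAX, P_IPCAMAX, P_GKUR_SCALE,
  P_FIBROTIC, P_VARIABLE_ECA, P_K_ANCHOR, P_K_EXPONENT, P_TEMP,
  NPARAM
};

enum StateIdx {
  S_V = 0, S_M, S_H, S_J, S_OA, S_OI, S_UA, S_UI, S_XR, S_XS,
  S_D, S_F, S_FCA, S_U, S_VGATE, S_W, S_NAI, S_KI, S_CAI, S_CAUP, S_CAREL,
  NSTATE
};

enum CurrIdx {
  C_INA = 0, C_IK1, C_ITO, C_IKUR, C_IKR, C_IKS, C_ICAL, C_INAK,
  C_INACA, C_IBNA, C_IBCA, C_ICAP,
  NCURR
};

// physical constants (CRN 1998)
static const double PHYS_R = 8.3143;     // J/(K mol)
static const double PHYS_F = 96.4867;    // C/mmol
static const double CM     = 100.0;      // pF
static const double VOL_I  = 13668.0;    // um^3
static const double VOL_UP = 1109.52;
static const double VOL_REL = 96.48;

// buffering
static const double CMDN_MAX = 0.05, KM_CMDN = 0.00238;
static const double TRPN_MAX = 0.07, KM_TRPN = 0.0005;
static const double CSQN_MAX = 10.0, KM_CSQN = 0.8;
static const double CA_UP_MAX = 15.0;

// exchanger / pump constants
static const double K_M_NA_I = 10.0, K_M_K_O = 1.5;
static const double K_M_NA = 87.5, K_M_CA = 1.38, K_SAT = 0.1, GAMMA_NACA = 0.35;
static const double K_REL = 30.0, TAU_TR = 180.0;
static const double I_UP_MAX = 0.005, K_UP = 0.00092;
static const double KQ10 = 3.0;

static inline double safe_div(double num, double den) { return num / den; }

// ---- voltage-dependent gate kinetics (exact formulas) ---------------------
// gates in LUT order: m h j oa oi ua ui xr xs d f w  (12 gates)
static const int NVGATE = 12;

static void gate_inf_tau(double V, double* inf, double* tau) {
  double a, b;
  // m
  if (std::fabs(V + 47.13) < 1e-10) a = 3.2;
  else a = 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  inf[0] = a / (a + b); tau[0] = 1.0 / (a + b);
  // h
  if (V < -40.0) {
    a = 0.135 * std::exp((V + 80.0) / -6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  } else {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
  }
  inf[1] = a / (a + b); tau[1] = 1.0 / (a + b);
  // j
  if (V < -40.0) {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  inf[2] = a / (a + b); tau[2] = 1.0 / (a + b);
  // oa
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  tau[3] = 1.0 / ((a + b) * KQ10);
  // oi
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  inf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  tau[4] = 1.0 / ((a + b) * KQ10);
  // ua (same rate constants as oa)
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  tau[5] = 1.0 / ((a + b) * KQ10);
  // ui
  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  inf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  tau[6] = 1.0 / ((a + b) * KQ10);
  // xr
  if (std::fabs(V + 14.1) < 1e-10) a = 0.0015;
  else a = 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  if (std::fabs(V - 3.3328) < 1e-10) b = 3.7836118e-4;
  else b = 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  inf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  tau[7] = 1.0 / (a + b);
  // xs
  if (std::fabs(V - 19.9) < 1e-10) { a = 6.8e-4; b = 3.15e-4; }
  else {
    a = 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
    b = 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  }
  inf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  tau[8] = 0.5 / (a + b);
  // d
  inf[9] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  if (std::fabs(V + 10.0) < 1e-10) tau[9] = 1.0 / (0.035 * 6.24 * 2.0);
  else {
    double e = std::exp(-(V + 10.0) / 6.24);
    tau[9] = (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }
  // f
  inf[10] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  // w
  inf[11] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  if (std::fabs(V - 7.9) < 1e-10) tau[11] = 6.0 / (5.0 * 1.3);
  else {
    double e = std::exp(-(V - 7.9) / 5.0);
    tau[11] = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }
}

// positions of the 12 LUT gates in the state vector
static const int GATE_STATE[NVGATE] = {
  S_M, S_H, S_J, S_OA, S_OI, S_UA, S_UI, S_XR, S_XS, S_D, S_F, S_W
};

// ---- current evaluation ----------------------------------------------------
// elec_pert / elec_ref: (Ko, Nao, Cao); mask[c] = 1 -> current c sees perturbed
struct ElecCtx {
  double ep[3], er[3];
  int mask[NCURR];
  inline double Ko(int c)  const { return mask[c] ? ep[0] : er[0]; }
  inline double Nao(int c) const { return mask[c] ? ep[1] : er[1]; }
  inline double Cao(int c) const { return mask[c] ? ep[2] : er[2]; }
};

// Computes all 12 membrane currents (pA/pF). V-dependent helper factors are
// passed in so the LUT path can share this code with the exact path.
struct VFactors {
  double gkur;      // voltage-dependent IKur conductance (nS/pF)
  double ik1_den;   // 1/(1+exp(0.07(V+80)))
  double ikr_den;   // 1/(1+exp((V+15)/22.4))
  double fnak_e1;   // exp(-0.1 F V / RT)
  double fnak_e2;   // exp(-F V / RT)
  double naca_e1;   // exp(gamma F V / RT)
  double naca_e2;   // exp((gamma-1) F V / RT)
};

static void vfactors_exact(double V, double RT_F, VFactors* f) {
  f->gkur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  f->ik1_den = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
  f->ikr_den = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
  f->fnak_e1 = std::exp(-0.1 * V / RT_F);
  f->fnak_e2 = std::exp(-V / RT_F);
  f->naca_e1 = std::exp(GAMMA_NACA * V / RT_F);
  f->naca_e2 = std::exp((GAMMA_NACA - 1.0) * V / RT_F);
}

static void compute_currents(const double* y, const double* p,
                             const ElecCtx& ec, const VFactors& vf,
                             double RT_F, double* I) {
  const double V = y[S_V];
  const double Nai = y[S_NAI], Ki = y[S_KI], Cai = y[S_CAI];

  // reversal potentials per current (respecting the override mask)
  const double ENa_ina  = RT_F * std::log(ec.Nao(C_INA)  / Nai);
  const double ENa_ibna = (ec.mask[C_IBNA] == ec.mask[C_INA]) ? ENa_ina
                        : RT_F * std::log(ec.Nao(C_IBNA) / Nai);
  double EK_cache[2]; bool EK_have[2] = {false, false};
  #define EK_FOR(c) (EK_have[ec.mask[c]] ? EK_cache[ec.mask[c]] : \
    (EK_have[ec.mask[c]] = true, EK_cache[ec.mask[c]] = RT_F * std::log(ec.Ko(c) / Ki)))

  I[C_INA] = p[P_GNA] * y[S_M]*y[S_M]*y[S_M] * y[S_H] * y[S_J] * (V - ENa_ina);

  // Ko-sensitive conductance scaling for IK1 and IKr (CRN++): (Ko/anchor)^exp
  const double gk1 = p[P_GK1] * std::pow(ec.Ko(C_IK1) / p[P_K_ANCHOR], p[P_K_EXPONENT]);
  const double gkr = p[P_GKR] * std::pow(ec.Ko(C_IKR) / p[P_K_ANCHOR], p[P_K_EXPONENT]);

  I[C_IK1]  = gk1 * (V - EK_FOR(C_IK1)) * vf.ik1_den;
  I[C_ITO]  = p[P_GTO] * y[S_OA]*y[S_OA]*y[S_OA] * y[S_OI] * (V - EK_FOR(C_ITO));
  I[C_IKUR] = p[P_GKUR_SCALE] * vf.gkur * y[S_UA]*y[S_UA]*y[S_UA] * y[S_UI] *
              (V - EK_FOR(C_IKUR));
  I[C_IKR]  = gkr * y[S_XR] * (V - EK_FOR(C_IKR)) * vf.ikr_den;
  I[C_IKS]  = p[P_GKS] * y[S_XS]*y[S_XS] * (V - EK_FOR(C_IKS));

  // ICaL: fixed +65 mV driving term (CRN default) or variable Nernst ECa
  double eca_l = 65.0;
  if (p[P_VARIABLE_ECA] != 0.0)
    eca_l = 0.5 * RT_F * std::log(ec.Cao(C_ICAL) / Cai);
  I[C_ICAL] = p[P_GCAL] * y[S_D] * y[S_F] * y[S_FCA] * (V - eca_l);

  // INaK
  const double sigma = (std::exp(ec.Nao(C_INAK) / 67.3) - 1.0) / 7.0;
  const double fnak = 1.0 / (1.0 + 0.1245 * vf.fnak_e1 + 0.0365 * sigma * vf.fnak_e2);
  I[C_INAK] = p[P_INAKMAX] * fnak *
              (1.0 / (1.0 + std::pow(K_M_NA_I / Nai, 1.5))) *
              (ec.Ko(C_INAK) / (ec.Ko(C_INAK) + K_M_K_O));

  // INaCa
  {
    const double nao = ec.Nao(C_INACA), cao = ec.Cao(C_INACA);
    const double num = vf.naca_e1 * Nai*Nai*Nai * cao -
                       vf.naca_e2 * nao*nao*nao * Cai;
    const double den = (K_M_NA*K_M_NA*K_M_NA + nao*nao*nao) * (K_M_CA + cao) *
                       (1.0 + K_SAT * vf.naca_e2);
    I[C_INACA] = p[P_INACAMAX] * num / den;
  }

  I[C_IBNA] = p[P_GBNA] * (V - ENa_ibna);
  const double ECa_b = 0.5 * RT_F * std::log(ec.Cao(C_IBCA) / Cai);
  I[C_IBCA] = p[P_GBCA] * (V - ECa_b);
  I[C_ICAP] = p[P_IPCAMAX] * Cai / (0.0005 + Cai);
  #undef EK_FOR
}

// Non-gate derivatives (V, fCa/u/v updates, concentrations). Returns Fn-gate
// infos through pointers so Rush-Larsen can use them.
struct CaGateKinetics { double fca_inf, u_inf, v_inf, tau_v; };

static void calcium_subsystem(const double* y, const double* I,
                              CaGateKinetics* k, double* dconc /*Nai Ki Cai Caup Carel*/) {
  const double Cai = y[S_CAI], Caup = y[S_CAUP], Carel = y[S_CAREL];
  const double i_rel = K_REL * y[S_U]*y[S_U] * y[S_VGATE] * y[S_W] * (Carel - Cai);
  const double i_tr = (Caup - Carel) / TAU_TR;
  const double i_up = I_UP_MAX / (1.0 + K_UP / Cai);
  const double i_up_leak = I_UP_MAX * Caup / CA_UP_MAX;

  // whole-cell currents in pA for Fn and concentration balances
  const double iCaL = CM * I[C_ICAL], iNaCa = CM * I[C_INACA];
  const double Fn = 1e-12 * VOL_REL * i_rel -
                    (5e-13 / PHYS_F) * (0.5 * iCaL - 0.2 * iNaCa);
  const double fn_e = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
  k->fca_inf = 1.0 / (1.0 + Cai / 0.00035);
  k->u_inf = 1.0 / (1.0 + fn_e);
  k->v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  k->tau_v = 1.91 + 2.09 / (1.0 + fn_e);

  const double FVi = PHYS_F * VOL_I;
  dconc[0] = (-3.0 * CM * I[C_INAK] -
              (3.0 * CM * I[C_INACA] + CM * I[C_IBNA] + CM * I[C_INA])) / FVi;
  dconc[1] = (2.0 * CM * I[C_INAK] -
              CM * (I[C_IK1] + I[C_ITO] + I[C_IKUR] + I[C_IKR] + I[C_IKS])) / FVi;
  const double B1 = (2.0 * CM * I[C_INACA] -
                     (CM * I[C_ICAP] + CM * I[C_ICAL] + CM * I[C_IBCA])) /
                    (2.0 * FVi) +
                    (VOL_UP * (i_up_leak - i_up) + i_rel * VOL_REL) / VOL_I;
  const double B2 = 1.0 + TRPN_MAX * KM_TRPN / ((Cai + KM_TRPN) * (Cai + KM_TRPN)) +
                    CMDN_MAX * KM_CMDN / ((Cai + KM_CMDN) * (Cai + KM_CMDN));
  dconc[2] = B1 / B2;
  dconc[3] = i_up - (i_up_leak + i_tr * VOL_REL / VOL_UP);
  dconc[4] = (i_tr - i_rel) /
             (1.0 + CSQN_MAX * KM_CSQN / ((Carel + KM_CSQN) * (Carel + KM_CSQN)));
}

static void fill_ec(ElecCtx& ec, const NumericVector& ep, const NumericVector& er,
                    const IntegerVector& mask) {
  for (int i = 0; i < 3; ++i) { ec.ep[i] = ep[i]; ec.er[i] = er[i]; }
  for (int c = 0; c < NCURR; ++c) ec.mask[c] = mask[c];
}

// ---- exact RHS (reference path; used by derivatives() and deSolve oracle) --

// [[Rcpp::export(name = ".crn_rhs_cpp")]]
List crn_rhs_cpp(NumericVector state, NumericVector params,
                 NumericVector elec_pert, NumericVector elec_ref,
                 IntegerVector mask, double stim) {
  ElecCtx ec; fill_ec(ec, elec_pert, elec_ref, mask);
  const double* y = state.begin();
  const double* p = params.begin();
  const double RT_F = PHYS_R * p[P_TEMP] / PHYS_F;

  VFactors vf; vfactors_exact(y[S_V], RT_F, &vf);
  double I[NCURR];
  compute_currents(y, p, ec, vf, RT_F, I);

  double inf[NVGATE], tau[NVGATE];
  gate_inf_tau(y[S_V], inf, tau);

  CaGateKinetics k; double dconc[5];
  calcium_subsystem(y, I, &k, dconc);

  NumericVector dy(NSTATE);
  double Iion = 0.0;
  for (int c = 0; c < NCURR; ++c) Iion += I[c];
  dy[S_V] = -Iion + stim;
  for (int g = 0; g < NVGATE; ++g)
    dy[GATE_STATE[g]] = (inf[g] - y[GATE_STATE[g]]) / tau[g];
  dy[S_FCA] = (k.fca_inf - y[S_FCA]) / 2.0;
  dy[S_U] = (k.u_inf - y[S_U]) / 8.0;
  dy[S_VGATE] = (k.v_inf - y[S_VGATE]) / k.tau_v;
  dy[S_NAI] = dconc[0]; dy[S_KI] = dconc[1]; dy[S_CAI] = dconc[2];
  dy[S_CAUP] = dconc[3]; dy[S_CAREL] = dconc[4];

  NumericVector Iout(NCURR);
  for (int c = 0; c < NCURR; ++c) Iout[c] = I[c];
  return List::create(_["deriv"] = dy, _["currents"] = Iout,
                      _["total_current"] = Iion);
}

// ---- lookup-table Rush-Larsen stepper --------------------------------------

// LUT columns: [0..11] gate inf, [12..23] gate RL factor exp(-dt/tau),
// [24..30] VFactors members.
static const int LUT_NCOL = 31;

struct Lut {
  double vmin, vmax, inv_dv;
  int n;
  std::vector<double> tab; // n rows x LUT_NCOL
  void build(double dt, double RT_F, double vmin_, double vmax_, double dv) {
    vmin = vmin_; vmax = vmax_; inv_dv = 1.0 / dv;
    n = (int)std::floor((vmax - vmin) / dv) + 1;
    tab.assign((size_t)n * LUT_NCOL, 0.0);
    double inf[NVGATE], tau[NVGATE];
    VFactors vf;
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      gate_inf_tau(V, inf, tau);
      vfactors_exact(V, RT_F, &vf);
      double* row = &tab[(size_t)i * LUT_NCOL];
      for (int g = 0; g < NVGATE; ++g) {
        row[g] = inf[g];
        row[12 + g] = std::exp(-dt / tau[g]);
      }
      row[24] = vf.gkur; row[25] = vf.ik1_den; row[26] = vf.ikr_den;
      row[27] = vf.fnak_e1; row[28] = vf.fnak_e2;
      row[29] = vf.naca_e1; row[30] = vf.naca_e2;
    }
  }
  inline void lookup(double V, double* out) const {
    double x = (V - vmin) * inv_dv;
    if (x < 0.0) x = 0.0;
    if (x > n - 1.000001) x = n - 1.000001;
    int i = (int)x;
    double w = x - i;
    const double* r0 = &tab[(size_t)i * LUT_NCOL];
    const double* r1 = r0 + LUT_NCOL;
    for (int c = 0; c < LUT_NCOL; ++c) out[c] = r0[c] + w * (r1[c] - r0[c]);
  }
};

// one Rush-Larsen / forward-Euler step of the ionic model for a single node;
// ext = diffusion + stimulus term added to dV/dt (mV/ms).
// Returns the total ionic current (pA/pF) before the update.
static inline double rl_step_node(double* y, const double* p, const ElecCtx& ec,
                                  const Lut& lut, double RT_F, double dt,
                                  double ext, double rl_fca, double rl_u) {
  double row[LUT_NCOL];
  lut.lookup(y[S_V], row);

  VFactors vf;
  vf.gkur = row[24]; vf.ik1_den = row[25]; vf.ikr_den = row[26];
  vf.fnak_e1 = row[27]; vf.fnak_e2 = row[28];
  vf.naca_e1 = row[29]; vf.naca_e2 = row[30];

  double I[NCURR];
  compute_currents(y, p, ec, vf, RT_F, I);

  CaGateKinetics k; double dconc[5];
  calcium_subsystem(y, I, &k, dconc);

  double Iion = 0.0;
  for (int c = 0; c < NCURR; ++c) Iion += I[c];

  // gates: exponential (Rush-Larsen) update
  for (int g = 0; g < NVGATE; ++g) {
    double* yg = &y[GATE_STATE[g]];
    *yg = row[g] + (*yg - row[g]) * row[12 + g];
  }
  y[S_FCA] = k.fca_inf + (y[S_FCA] - k.fca_inf) * rl_fca;
  y[S_U]   = k.u_inf + (y[S_U] - k.u_inf) * rl_u;
  double rv = std::exp(-dt / k.tau_v);
  y[S_VGATE] = k.v_inf + (y[S_VGATE] - k.v_inf) * rv;

  // concentrations and voltage: forward Euler
  y[S_NAI] += dt * dconc[0];
  y[S_KI]  += dt * dconc[1];
  y[S_CAI] += dt * dconc[2];
  y[S_CAUP] += dt * dconc[3];
  y[S_CAREL] += dt * dconc[4];
  y[S_V] += dt * (-Iion + ext);
  return Iion;
}

// ---- 0D pacing --------------------------------------------------------------

// Pre-pace to (approach) a limit cycle. Returns final state, per-beat
// residuals (max-norm of scaled state difference between successive beat
// starts) and the stimulus count.
// [[Rcpp::export(name = ".crn_prepace_cpp")]]
List crn_prepace_cpp(NumericVector state, NumericVector params,
                     NumericVector elec_pert, NumericVector elec_ref,
                     IntegerVector mask, double cl, int n_beats,
                     double stim_amp, double stim_dur, double dt) {
  ElecCtx ec; fill_ec(ec, elec_pert, elec_ref, mask);
  const double* p = params.begin();
  const double RT_F = PHYS_R * p[P_TEMP] / PHYS_F;
  Lut lut; lut.build(dt, RT_F, -120.0, 80.0, 0.05);
  const double rl_fca = std::exp(-dt / 2.0), rl_u = std::exp(-dt / 8.0);

  double y[NSTATE], prev[NSTATE];
  std::memcpy(y, state.begin(), sizeof(y));
  NumericVector residuals(n_beats > 0 ? n_beats : 0, NA_REAL);

  const int steps_per_beat = (int)std::llround(cl / dt);
  const int stim_steps = (int)std::llround(stim_dur / dt);

  for (int b = 0; b < n_beats; ++b) {
    std::memcpy(prev, y, sizeof(y));
    for (int s = 0; s < steps_per_beat; ++s) {
      double ext = (s < stim_steps) ? stim_amp : 0.0;
      rl_step_node(y, p, ec, lut, RT_F, dt, ext, rl_fca, rl_u);
    }
    if (!R_finite(y[S_V]))
      stop("numerical failure during pre-pacing at beat %d", b + 1);
    double res = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      double scale = std::max(std::fabs(prev[i]), 1e-3);
      res = std::max(res, std::fabs(y[i] - prev[i]) / scale);
    }
    residuals[b] = res;
  }

  NumericVector out(NSTATE);
  std::memcpy(out.begin(), y, sizeof(y));
  return List::create(_["state"] = out,
                      _["residuals"] = residuals,
                      _["n_stimuli"] = n_beats);
}

// Record a dense voltage/current trace over n_beats paced beats.
// [[Rcpp::export(name = ".crn_record_cpp")]]
List crn_record_cpp(NumericVector state, NumericVector params,
                    NumericVector elec_pert, NumericVector elec_ref,
                    IntegerVector mask, double cl, int n_beats,
                    double stim_amp, double stim_dur, double dt, double out_dt) {
  ElecCtx ec; fill_ec(ec, elec_pert, elec_ref, mask);
  const double* p = params.begin();
  const double RT_F = PHYS_R * p[P_TEMP] / PHYS_F;
  Lut lut; lut.build(dt, RT_F, -120.0, 80.0, 0.05);
  const double rl_fca = std::exp(-dt / 2.0), rl_u = std::exp(-dt / 8.0);

  double y[NSTATE];
  std::memcpy(y, state.begin(), sizeof(y));

  const long n_steps = (long)std::llround(cl * n_beats / dt);
  const int every = std::max(1, (int)std::llround(out_dt / dt));
  const long n_out = n_steps / every + 1;
  const int steps_per_beat = (int)std::llround(cl / dt);
  const int stim_steps = (int)std::llround(stim_dur / dt);

  NumericVector time(n_out), V(n_out);
  NumericMatrix Imat(n_out, NCURR);
  long k = 0;

  // sample at t = 0 before stepping (trace starts at the input state)
  time[k] = 0.0; V[k] = y[S_V];
  {
    VFactors vf; vfactors_exact(y[S_V], RT_F, &vf);
    double I[NCURR]; compute_currents(y, p, ec, vf, RT_F, I);
    for (int c = 0; c < NCURR; ++c) Imat(k, c) = I[c];
  }
  ++k;

  for (long s = 0; s < n_steps; ++s) {
    int sb = (int)(s % steps_per_beat);
    double ext = (sb < stim_steps) ? stim_amp : 0.0;
    rl_step_node(y, p, ec, lut, RT_F, dt, ext, rl_fca, rl_u);
    if ((s + 1) % every == 0 && k < n_out) {
      if (!R_finite(y[S_V]))
        stop("numerical failure at t = %.3f ms", (s + 1) * dt);
      time[k] = (s + 1) * dt;
      V[k] = y[S_V];
      VFactors vf; vfactors_exact(y[S_V], RT_F, &vf);
      double I[NCURR]; compute_currents(y, p, ec, vf, RT_F, I);
      for (int c = 0; c < NCURR; ++c) Imat(k, c) = I[c];
      ++k;
    }
  }

  NumericVector out(NSTATE);
  std::memcpy(out.begin(), y, sizeof(y));
  return List::create(_["time"] = time, _["V"] = V, _["currents"] = Imat,
                      _["state"] = out);
}

// Sample the state along one paced beat (for spiral phase maps).
// Returns n_samples x NSTATE matrix; sample i taken at t = i/n_samples * cl.
// [[Rcpp::export(name = ".crn_cycle_states_cpp")]]
NumericMatrix crn_cycle_states_cpp(NumericVector state, NumericVector params,
                                   NumericVector elec_pert, NumericVector elec_ref,
                                   IntegerVector mask, double cl, int n_samples,
                                   double stim_amp, double stim_dur, double dt) {
  ElecCtx ec; fill_ec(ec, elec_pert, elec_ref, mask);
  const double* p = params.begin();
  const double RT_F = PHYS_R * p[P_TEMP] / PHYS_F;
  Lut lut; lut.build(dt, RT_F, -120.0, 80.0, 0.05);
  const double rl_fca = std::exp(-dt / 2.0), rl_u = std::exp(-dt / 8.0);

  double y[NSTATE];
  std::memcpy(y, state.begin(), sizeof(y));
  NumericMatrix out(n_samples, NSTATE);
  const long n_steps = (long)std::llround(cl / dt);
  const int stim_steps = (int)std::llround(stim_dur / dt);
  long next = 0;
  for (long s = 0; s < n_steps; ++s) {
    if (next < n_samples &&
        s >= (long)std::floor((double)next / n_samples * n_steps)) {
      for (int i = 0; i < NSTATE; ++i) out(next, i) = y[i];
      ++next;
    }
    double ext = (s < stim_steps) ? stim_amp : 0.0;
    rl_step_node(y, p, ec, lut, RT_F, dt, ext, rl_fca, rl_u);
  }
  while (next < n_samples) {
    for (int i = 0; i < NSTATE; ++i) out(next, i) = y[i];
    ++next;
  }
  return out;
}

// ---- monodomain solver ------------------------------------------------------
//
// Cm dV/dt = -Iion + Istim + div(D grad V), with D (cm^2/ms) per node and
// no-flux boundaries, on a regular nx x ny grid (ny = 1 -> 1D strand).
// Operator: flux-form finite differences, face diffusivity = arithmetic mean.
// Node index: k = i + nx*j (column-major in x).

// [[Rcpp::export(name = ".solve_monodomain_cpp")]]
List solve_monodomain_cpp(NumericMatrix states0,      // nnodes x NSTATE
                          IntegerVector region,        // 1-based region per node
                          NumericMatrix params_mat,    // nregion x NPARAM
                          NumericVector elec_pert, NumericVector elec_ref,
                          IntegerVector mask,
                          int nx, int ny, double dx,
                          NumericVector Dxx, NumericVector Dyy,
                          NumericVector Dxy,
                          List stim_nodes,             // list of 1-based index vectors
                          NumericVector stim_onset, NumericVector stim_dur,
                          NumericVector stim_amp,
                          double t_end, double dt, double out_dt,
                          IntegerVector record_nodes,  // 1-based; empty -> all
                          double act_threshold, double act_refractory,
                          bool return_states) {
  const int nn = nx * ny;
  if (states0.nrow() != nn || states0.ncol() != NSTATE)
    stop("states0 must be (nx*ny) x %d", NSTATE);

  const int nreg = params_mat.nrow();
  const double RT_F = PHYS_R * params_mat(0, P_TEMP) / PHYS_F;
  ElecCtx ec; fill_ec(ec, elec_pert, elec_ref, mask);
  Lut lut; lut.build(dt, RT_F, -120.0, 80.0, 0.05);
  const double rl_fca = std::exp(-dt / 2.0), rl_u = std::exp(-dt / 8.0);

  // flatten states (node-major)
  std::vector<double> Y((size_t)nn * NSTATE);
  for (int k = 0; k < nn; ++k)
    for (int s = 0; s < NSTATE; ++s) Y[(size_t)k * NSTATE + s] = states0(k, s);

  std::vector<const double*> preg(nn);
  std::vector<double> pflat((size_t)nreg * NPARAM);
  for (int r = 0; r < nreg; ++r)
    for (int c = 0; c < NPARAM; ++c) pflat[(size_t)r * NPARAM + c] = params_mat(r, c);
  for (int k = 0; k < nn; ++k) {
    int r = region[k] - 1;
    if (r < 0 || r >= nreg) stop("region id out of range at node %d", k + 1);
    preg[k] = &pflat[(size_t)r * NPARAM];
  }

  const bool any_dxy = [&]{
    for (int k = 0; k < nn; ++k) if (Dxy[k] != 0.0) return true;
    return false; }();

  // stimuli
  const int nstim = stim_onset.size();
  std::vector<std::vector<int>> snodes(nstim);
  for (int s = 0; s < nstim; ++s) {
    IntegerVector v = stim_nodes[s];
    snodes[s].assign(v.begin(), v.end());
    for (size_t q = 0; q < snodes[s].size(); ++q) snodes[s][q] -= 1;
  }

  // recording
  std::vector<int> rec;
  if (record_nodes.size() == 0) { rec.resize(nn); for (int k = 0; k < nn; ++k) rec[k] = k; }
  else { rec.assign(record_nodes.begin(), record_nodes.end());
         for (size_t q = 0; q < rec.size(); ++q) rec[q] -= 1; }

  const long n_steps = (long)std::llround(t_end / dt);
  const int every = std::max(1, (int)std::llround(out_dt / dt));
  const long n_out = n_steps / every + 1;
  NumericMatrix Vm(n_out, (int)rec.size());
  NumericVector times(n_out);

  // activation bookkeeping
  std::vector<std::vector<double>> acts(nn);
  std::vector<double> last_act(nn, -1e9);
  const size_t max_acts = 512;

  std::vector<double> lap(nn), stimbuf(nn), Vcur(nn);
  for (int k = 0; k < nn; ++k) Vcur[k] = Y[(size_t)k * NSTATE + S_V];

  long outk = 0;
  times[outk] = 0.0;
  for (size_t q = 0; q < rec.size(); ++q) Vm(outk, (int)q) = Vcur[rec[q]];
  ++outk;

  const double inv_dx2 = 1.0 / (dx * dx);

  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // diffusion term (flux form, no-flux boundaries)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int k = i + nx * j;
        double acc = 0.0;
        if (i + 1 < nx) {
          double Df = 0.5 * (Dxx[k] + Dxx[k + 1]);
          acc += Df * (Vcur[k + 1] - Vcur[k]);
        }
        if (i > 0) {
          double Df = 0.5 * (Dxx[k] + Dxx[k - 1]);
          acc -= Df * (Vcur[k] - Vcur[k - 1]);
        }
        if (j + 1 < ny) {
          double Df = 0.5 * (Dyy[k] + Dyy[k + nx]);
          acc += Df * (Vcur[k + nx] - Vcur[k]);
        }
        if (j > 0) {
          double Df = 0.5 * (Dyy[k] + Dyy[k - nx]);
          acc -= Df * (Vcur[k] - Vcur[k - nx]);
        }
        lap[k] = acc * inv_dx2;
      }
    }
    if (any_dxy) {
      // cross-derivative terms, centred differences (interior only)
      for (int j = 1; j + 1 < ny; ++j) {
        for (int i = 1; i + 1 < nx; ++i) {
          const int k = i + nx * j;
          double dVdy_e = 0.25 * (Vcur[k + 1 + nx] - Vcur[k + 1 - nx] +
                                  Vcur[k + nx] - Vcur[k - nx]);
          double dVdy_w = 0.25 * (Vcur[k - 1 + nx] - Vcur[k - 1 - nx] +
                                  Vcur[k + nx] - Vcur[k - nx]);
          double dVdx_n = 0.25 * (Vcur[k + 1 + nx] - Vcur[k - 1 + nx] +
                                  Vcur[k + 1] - Vcur[k - 1]);
          double dVdx_s = 0.25 * (Vcur[k + 1 - nx] - Vcur[k - 1 - nx] +
                                  Vcur[k + 1] - Vcur[k - 1]);
          double Dxy_e = 0.5 * (Dxy[k] + Dxy[k + 1]);
          double Dxy_w = 0.5 * (Dxy[k] + Dxy[k - 1]);
          double Dxy_n = 0.5 * (Dxy[k] + Dxy[k + nx]);
          double Dxy_s = 0.5 * (Dxy[k] + Dxy[k - nx]);
          lap[k] += (Dxy_e * dVdy_e - Dxy_w * dVdy_w +
                     Dxy_n * dVdx_n - Dxy_s * dVdx_s) * inv_dx2;
        }
      }
    }

    // stimuli
    std::fill(stimbuf.begin(), stimbuf.end(), 0.0);
    for (int q = 0; q < nstim; ++q) {
      if (t >= stim_onset[q] && t < stim_onset[q] + stim_dur[q]) {
        for (size_t m = 0; m < snodes[q].size(); ++m)
          stimbuf[snodes[q][m]] += stim_amp[q];
      }
    }

    // reaction step
    for (int k = 0; k < nn; ++k) {
      double* y = &Y[(size_t)k * NSTATE];
      rl_step_node(y, preg[k], ec, lut, RT_F, dt, lap[k] + stimbuf[k],
                   rl_fca, rl_u);
      const double Vnew = y[S_V];
      if (Vcur[k] < act_threshold && Vnew >= act_threshold &&
          (t - last_act[k]) > act_refractory) {
        if (acts[k].size() < max_acts) acts[k].push_back(t + dt);
        last_act[k] = t;
      }
      Vcur[k] = Vnew;
    }

    if ((s + 1) % every == 0 && outk < n_out) {
      if (!R_finite(Vcur[0]) || !R_finite(Vcur[nn / 2]))
        stop("numerical failure at t = %.2f ms", (s + 1) * dt);
      times[outk] = (s + 1) * dt;
      for (size_t q = 0; q < rec.size(); ++q) Vm(outk, (int)q) = Vcur[rec[q]];
      ++outk;
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  for (int k = 0; k < nn; k += std::max(1, nn / 16))
    if (!R_finite(Vcur[k])) stop("numerical failure (non-finite voltage) at end");

  List actlist(nn);
  for (int k = 0; k < nn; ++k) actlist[k] = NumericVector(acts[k].begin(), acts[k].end());

  List out = List::create(_["times"] = times, _["vm"] = Vm,
                          _["record_nodes"] = record_nodes,
                          _["activations"] = actlist);
  if (return_states) {
    NumericMatrix fin(nn, NSTATE);
    for (int k = 0; k < nn; ++k)
      for (int si = 0; si < NSTATE; ++si) fin(k, si) = Y[(size_t)k * NSTATE + si];
    out["states"] = fin;
  }
  return out;
}
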
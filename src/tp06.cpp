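// Modified ten Tusscher-Panfilov 2006 (TP06) endocardial ventricular cell model
// and a 2D isotropic monodomain tissue integrator.
//
// Modifications relative to the published TP06 endocardial set:
//   * G_CaL baseline doubled (2 x 0.00003980 mm^3 uF^-1 ms^-1)
//   * tau_f(V) multiplied by a uniform scale (default 0.5)
//   * G_CaL, G_Ks, G_Kr, k_NaCa exposed as dimensionless multipliers
//
// Gates are advanced by Rush-Larsen (exact exponential) updates by default,
// with a pure forward-Euler mode for fidelity checks; V and concentrations are
// forward Euler.  Units: mV, ms, pA/pF, mM.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int N_STATE = 19;
// state layout
enum { iV = 0, iM, iH, iJ, iD, iF, iF2, iFCASS, iR, iS, iXR1, iXR2, iXS,
       iNAI, iKI, iCAI, iCASS, iCASR, iRBAR };
static const int N_VGATE = 12; // m h j d f f2 r s xr1 xr2 xs  (+ fCass handled on Ca_SS)

struct Params {
  // effective maximal conductances (multipliers folded in)
  double GNa, GK1, Gto, GKr, GKs, GCaL, knaca;
  double GpCa, KpCa, GpK, GbNa, GbCa;
  double PNaK, KmK, KmNa, KmNai, KmCa, ksat, gamma_naca, alpha_naca;
  double pKNa, Ko, Nao, Cao;
  double Rgas, Temp, Fcst, RTONF, FONRT;
  double Vc, Vsr, Vss, Cm;
  double Vmaxup, Kup, Vrel, k1p, k2p, k3, k4, EC, maxsr, minsr, Vleak, Vxfer;
  double Bufc, Kbufc, Bufsr, Kbufsr, Bufss, Kbufss;
  double tau_f_scale;
};

static Params unpack_params(const List& pl) {
  Params p;
  p.GNa   = as<double>(pl["G_Na"]);
  p.GK1   = as<double>(pl["G_K1"]);
  p.Gto   = as<double>(pl["G_to"]);
  p.GKr   = as<double>(pl["G_Kr_base"]) * as<double>(pl["mult_Kr"]);
  p.GKs   = as<double>(pl["G_Ks_base"]) * as<double>(pl["mult_Ks"]);
  p.GCaL  = as<double>(pl["G_CaL_base"]) * as<double>(pl["mult_CaL"]);
  p.knaca = as<double>(pl["k_NaCa_base"]) * as<double>(pl["mult_NaCa"]);
  p.GpCa  = as<double>(pl["G_pCa"]);   p.KpCa = as<double>(pl["K_pCa"]);
  p.GpK   = as<double>(pl["G_pK"]);
  p.GbNa  = as<double>(pl["G_bNa"]);   p.GbCa = as<double>(pl["G_bCa"]);
  p.PNaK  = as<double>(pl["P_NaK"]);   p.KmK  = as<double>(pl["K_mK"]);
  p.KmNa  = as<double>(pl["K_mNa"]);
  p.KmNai = as<double>(pl["K_mNai"]);  p.KmCa = as<double>(pl["K_mCa"]);
  p.ksat  = as<double>(pl["k_sat"]);
  p.gamma_naca = as<double>(pl["gamma_NaCa"]);
  p.alpha_naca = as<double>(pl["alpha_NaCa"]);
  p.pKNa  = as<double>(pl["p_KNa"]);
  p.Ko    = as<double>(pl["K_o"]);
  p.Nao   = as<double>(pl["Na_o"]);
  p.Cao   = as<double>(pl["Ca_o"]);
  p.Rgas  = as<double>(pl["R"]);
  p.Temp  = as<double>(pl["T"]);
  p.Fcst  = as<double>(pl["F"]);
  p.RTONF = p.Rgas * p.Temp / p.Fcst;
  p.FONRT = 1.0 / p.RTONF;
  p.Vc    = as<double>(pl["V_c"]);
  p.Vsr   = as<double>(pl["V_sr"]);
  p.Vss   = as<double>(pl["V_ss"]);
  p.Cm    = as<double>(pl["C_m"]);
  p.Vmaxup = as<double>(pl["V_maxup"]); p.Kup  = as<double>(pl["K_up"]);
  p.Vrel  = as<double>(pl["V_rel"]);
  p.k1p   = as<double>(pl["k1_prime"]); p.k2p = as<double>(pl["k2_prime"]);
  p.k3    = as<double>(pl["k3"]);       p.k4  = as<double>(pl["k4"]);
  p.EC    = as<double>(pl["EC"]);
  p.maxsr = as<double>(pl["max_sr"]);   p.minsr = as<double>(pl["min_sr"]);
  p.Vleak = as<double>(pl["V_leak"]);   p.Vxfer = as<double>(pl["V_xfer"]);
  p.Bufc  = as<double>(pl["Buf_c"]);    p.Kbufc = as<double>(pl["K_bufc"]);
  p.Bufsr = as<double>(pl["Buf_sr"]);   p.Kbufsr = as<double>(pl["K_bufsr"]);
  p.Bufss = as<double>(pl["Buf_ss"]);   p.Kbufss = as<double>(pl["K_bufss"]);
  p.tau_f_scale = as<double>(pl["tau_f_scale"]);
  return p;
}

// steady states and time constants of the 12 voltage-dependent gates
static void gate_rates(double V, double tau_f_scale, double* inf, double* tau) {
  double a, b, c;
  // m
  inf[0] = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  a = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  b = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
      0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  tau[0] = a * b;
  // h
  inf[1] = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  if (V >= -40.0) {
    a = 0.0;
    b = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.057 * std::exp(-(V + 80.0) / 6.8);
    b = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
  }
  tau[1] = 1.0 / (a + b);
  // j
  inf[2] = inf[1];
  if (V >= -40.0) {
    a = 0.0;
    b = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.02424 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  tau[2] = 1.0 / (a + b);
  // d
  inf[3] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  tau[3] = a * b + c;
  // f  (tau uniformly scaled: the EAD-promoting modification)
  inf[4] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  tau[4] = (1102.5 * std::exp(-std::pow(V + 27.0, 2.0) / 225.0) +
            200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
            180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0) * tau_f_scale;
  // f2
  inf[5] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  tau[5] = 562.0 * std::exp(-std::pow(V + 27.0, 2.0) / 240.0) +
           31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
           80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  // r
  inf[6] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  tau[6] = 9.5 * std::exp(-std::pow(V + 40.0, 2.0) / 1800.0) + 0.8;
  // s (endocardial)
  inf[7] = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
  tau[7] = 1000.0 * std::exp(-std::pow(V + 67.0, 2.0) / 1000.0) + 8.0;
  // xr1
  inf[8] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  tau[8] = a * b;
  // xr2
  inf[9] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  tau[9] = a * b;
  // xs
  inf[10] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  b = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  tau[10] = a * b + 80.0;
  // placeholder to keep arrays length 12: slot 11 unused by V (fCass is Ca_SS
  // dependent) -- filled with inert values
  inf[11] = 0.0; tau[11] = 1.0;
}
// gate slots in state vector matching gate_rates ordering (slot 11 unused)
static const int GATE_IDX[N_VGATE] = { iM, iH, iJ, iD, iF, iF2, iR, iS,
                                       iXR1, iXR2, iXS, -1 };

// all membrane currents [pA/pF] from an instantaneous state
static void currents(const double* s, const Params& p, double* I) {
  const double V = s[iV];
  const double Ek  = p.RTONF * std::log(p.Ko / s[iKI]);
  const double Ena = p.RTONF * std::log(p.Nao / s[iNAI]);
  const double Eks = p.RTONF * std::log((p.Ko + p.pKNa * p.Nao) /
                                        (s[iKI] + p.pKNa * s[iNAI]));
  const double Eca = 0.5 * p.RTONF * std::log(p.Cao / s[iCAI]);

  // I_Na
  I[0] = p.GNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - Ena);
  // I_K1 (inward rectification on V - E_K)
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                std::exp(0.1 * (V - Ek - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - Ek)));
  I[1] = p.GK1 * std::sqrt(p.Ko / 5.4) * ak1 / (ak1 + bk1) * (V - Ek);
  // I_to
  I[2] = p.Gto * s[iR] * s[iS] * (V - Ek);
  // I_Kr
  I[3] = p.GKr * std::sqrt(p.Ko / 5.4) * s[iXR1] * s[iXR2] * (V - Ek);
  // I_Ks
  I[4] = p.GKs * s[iXS] * s[iXS] * (V - Eks);
  // I_CaL: GHK-type driving force in subspace Ca
  double vm15 = V - 15.0;
  double ical;
  if (std::fabs(vm15) < 1e-6) {
    // limit of (V-15)/(exp(2(V-15)F/RT)-1) -> RT/(2F)
    ical = p.GCaL * s[iD] * s[iF] * s[iF2] * s[iFCASS] * 2.0 * p.Fcst *
           (0.25 * s[iCASS] - p.Cao);
  } else {
    double ex = std::exp(2.0 * vm15 * p.FONRT);
    // 4 (V-15) F^2/(RT) = 4 (V-15) F * FONRT
    ical = p.GCaL * s[iD] * s[iF] * s[iF2] * s[iFCASS] * 4.0 * vm15 *
           p.Fcst * p.FONRT *
           (0.25 * s[iCASS] * ex - p.Cao) / (ex - 1.0);
  }
  I[5] = ical;
  // I_NaCa
  {
    double e1 = std::exp(p.gamma_naca * V * p.FONRT);
    double e2 = std::exp((p.gamma_naca - 1.0) * V * p.FONRT);
    double nai3 = s[iNAI] * s[iNAI] * s[iNAI];
    double nao3 = p.Nao * p.Nao * p.Nao;
    I[6] = p.knaca *
           (e1 * nai3 * p.Cao - e2 * nao3 * s[iCAI] * p.alpha_naca) /
           ((p.KmNai * p.KmNai * p.KmNai + nao3) * (p.KmCa + p.Cao) *
            (1.0 + p.ksat * e2));
  }
  // I_NaK
  I[7] = p.PNaK * (p.Ko / (p.Ko + p.KmK)) * (s[iNAI] / (s[iNAI] + p.KmNa)) /
         (1.0 + 0.1245 * std::exp(-0.1 * V * p.FONRT) +
          0.0353 * std::exp(-V * p.FONRT));
  // I_pCa
  I[8] = p.GpCa * s[iCAI] / (p.KpCa + s[iCAI]);
  // I_pK
  I[9] = p.GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  // I_bCa, I_bNa
  I[10] = p.GbCa * (V - Eca);
  I[11] = p.GbNa * (V - Ena);
  // total
  I[12] = I[0] + I[1] + I[2] + I[3] + I[4] + I[5] + I[6] + I[7] + I[8] +
          I[9] + I[10] + I[11];
}

// quadratic-formula rapid-buffering update (TP06 formulation)
static inline double buffered_update(double conc, double dconc,
                                     double buf, double kbuf) {
  double bound = buf * conc / (conc + kbuf);
  double b = buf - bound - dconc - conc + kbuf;
  double c = kbuf * (bound + dconc + conc);
  return (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
}

// one explicit time step for a single node; istim in pA/pF, negative value
// depolarizes (TP06 sign convention).  Returns total ionic current.
static double step_node(double* s, const Params& p, double istim, double dt,
                        bool euler_gates) {
  double I[13];
  currents(s, p, I);
  const double iion = I[12];

  // --- concentrations ---------------------------------------------------
  const double caf = p.Cm / (2.0 * p.Vc * p.Fcst);
  const double naf = p.Cm / (p.Vc * p.Fcst);
  // SR release machinery
  double casr = s[iCASR], cass = s[iCASS], cai = s[iCAI];
  double kCaSR = p.maxsr - (p.maxsr - p.minsr) /
                 (1.0 + (p.EC / casr) * (p.EC / casr));
  double k1 = p.k1p / kCaSR;
  double k2 = p.k2p * kCaSR;
  double rbar = s[iRBAR];
  s[iRBAR] = rbar + dt * (p.k4 * (1.0 - rbar) - k2 * cass * rbar);
  double O = k1 * cass * cass * s[iRBAR] / (p.k3 + k1 * cass * cass);
  double Irel  = p.Vrel * O * (casr - cass);
  double Ileak = p.Vleak * (casr - cai);
  double Iup   = p.Vmaxup / (1.0 + (p.Kup / cai) * (p.Kup / cai));
  double Ixfer = p.Vxfer * (cass - cai);

  double dcasr = dt * (Iup - Irel - Ileak);
  s[iCASR] = buffered_update(casr, dcasr, p.Bufsr, p.Kbufsr);
  double dcass = dt * (-Ixfer * (p.Vc / p.Vss) + Irel * (p.Vsr / p.Vss) -
                       I[5] * p.Cm / (2.0 * p.Vss * p.Fcst));
  s[iCASS] = buffered_update(cass, dcass, p.Bufss, p.Kbufss);
  double dcai = dt * (-(I[10] + I[8] - 2.0 * I[6]) * caf -
                      (Iup - Ileak) * (p.Vsr / p.Vc) + Ixfer);
  s[iCAI] = buffered_update(cai, dcai, p.Bufc, p.Kbufc);
  s[iNAI] += dt * (-(I[0] + I[11] + 3.0 * I[7] + 3.0 * I[6]) * naf);
  s[iKI]  += dt * (-(istim + I[1] + I[2] + I[3] + I[4] - 2.0 * I[7] + I[9]) * naf);

  // --- gates ------------------------------------------------------------
  const double V = s[iV];
  double inf[N_VGATE], tau[N_VGATE];
  gate_rates(V, p.tau_f_scale, inf, tau);
  for (int g = 0; g < N_VGATE - 1; ++g) {
    int k = GATE_IDX[g];
    if (euler_gates)
      s[k] += dt * (inf[g] - s[k]) / tau[g];
    else
      s[k] = inf[g] + (s[k] - inf[g]) * std::exp(-dt / tau[g]);
  }
  // fCass (subspace-Ca dependent)
  {
    double q = (cass / 0.05) * (cass / 0.05);
    double fci = 0.6 / (1.0 + q) + 0.4;
    double fct = 80.0 / (1.0 + q) + 2.0;
    if (euler_gates)
      s[iFCASS] += dt * (fci - s[iFCASS]) / fct;
    else
      s[iFCASS] = fci + (s[iFCASS] - fci) * std::exp(-dt / fct);
  }

  // --- membrane voltage ---------------------------------------------------
  s[iV] = V - dt * (iion + istim);
  return iion;
}

// ---------------------------------------------------------------------------
// Voltage lookup tables (0.02 mV grid, linear interpolation), the standard
// acceleration for this model: gate steady states enter as Rush-Larsen
// factors exp(-dt/tau) so the inner loop is almost free of transcendentals.
// Tables are rebuilt per run (they depend on dt, the multipliers and the
// integration mode).
// ---------------------------------------------------------------------------
struct Tables {
  double v0, dv; int nv;
  double u0, du; int nu;          // u = V - E_K grid for I_K1
  std::vector<double> ginf[11], grl[11];
  std::vector<double> nakf, ncxA, ncxB, icalA, icalB, ipkf, k1f;
};

static Tables build_tables(const Params& p, double dt, bool euler_gates) {
  Tables tb;
  tb.v0 = -150.0; tb.dv = 0.02; tb.nv = 15001;
  tb.u0 = -250.0; tb.du = 0.02; tb.nu = 27501;
  for (int g = 0; g < 11; ++g) { tb.ginf[g].resize(tb.nv); tb.grl[g].resize(tb.nv); }
  tb.nakf.resize(tb.nv); tb.ncxA.resize(tb.nv); tb.ncxB.resize(tb.nv);
  tb.icalA.resize(tb.nv); tb.icalB.resize(tb.nv); tb.ipkf.resize(tb.nv);
  tb.k1f.resize(tb.nu);
  double inf[N_VGATE], tau[N_VGATE];
  const double nao3 = p.Nao * p.Nao * p.Nao;
  const double ncx_den0 = (p.KmNai * p.KmNai * p.KmNai + nao3) * (p.KmCa + p.Cao);
  for (int i = 0; i < tb.nv; ++i) {
    double V = tb.v0 + i * tb.dv;
    gate_rates(V, p.tau_f_scale, inf, tau);
    for (int g = 0; g < 11; ++g) {
      tb.ginf[g][i] = inf[g];
      tb.grl[g][i] = euler_gates ? dt / tau[g] : std::exp(-dt / tau[g]);
    }
    tb.nakf[i] = p.PNaK * (p.Ko / (p.Ko + p.KmK)) /
                 (1.0 + 0.1245 * std::exp(-0.1 * V * p.FONRT) +
                  0.0353 * std::exp(-V * p.FONRT));
    double e1 = std::exp(p.gamma_naca * V * p.FONRT);
    double e2 = std::exp((p.gamma_naca - 1.0) * V * p.FONRT);
    double den = ncx_den0 * (1.0 + p.ksat * e2);
    tb.ncxA[i] = p.knaca * p.Cao * e1 / den;
    tb.ncxB[i] = p.knaca * nao3 * p.alpha_naca * e2 / den;
    double vm15 = V - 15.0;
    if (std::fabs(vm15) < 1e-9) {
      tb.icalA[i] = 2.0 * p.Fcst;
      tb.icalB[i] = 2.0 * p.Fcst;
    } else {
      double ex = std::exp(2.0 * vm15 * p.FONRT);
      double base = 4.0 * vm15 * p.Fcst * p.FONRT / (ex - 1.0);
      tb.icalA[i] = base * ex;
      tb.icalB[i] = base;
    }
    tb.ipkf[i] = p.GpK / (1.0 + std::exp((25.0 - V) / 5.98));
  }
  for (int i = 0; i < tb.nu; ++i) {
    double u = tb.u0 + i * tb.du;
    double ak1 = 0.1 / (1.0 + std::exp(0.06 * (u - 200.0)));
    double bk1 = (3.0 * std::exp(0.0002 * (u + 100.0)) +
                  std::exp(0.1 * (u - 10.0))) /
                 (1.0 + std::exp(-0.5 * u));
    tb.k1f[i] = p.GK1 * std::sqrt(p.Ko / 5.4) * ak1 / (ak1 + bk1);
  }
  return tb;
}

static inline double lk(const std::vector<double>& t, int i0, double w) {
  return t[i0] + w * (t[i0 + 1] - t[i0]);
}

// table-driven currents; fills I[0..12] like currents()
static inline void currents_fast(const double* s, const Params& p,
                                 const Tables& tb, int i0, double w,
                                 double Ek, double Ena, double Eks, double Eca,
                                 double* I) {
  const double V = s[iV];
  I[0] = p.GNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - Ena);
  double u = V - Ek;
  double uxi = (u - tb.u0) / tb.du;
  int j0 = (int)uxi; double wu = uxi - j0;
  I[1] = lk(tb.k1f, j0, wu) * u;
  I[2] = p.Gto * s[iR] * s[iS] * (V - Ek);
  I[3] = p.GKr * std::sqrt(p.Ko / 5.4) * s[iXR1] * s[iXR2] * (V - Ek);
  I[4] = p.GKs * s[iXS] * s[iXS] * (V - Eks);
  I[5] = p.GCaL * s[iD] * s[iF] * s[iF2] * s[iFCASS] *
         (0.25 * s[iCASS] * lk(tb.icalA, i0, w) - p.Cao * lk(tb.icalB, i0, w));
  double nai3 = s[iNAI] * s[iNAI] * s[iNAI];
  I[6] = lk(tb.ncxA, i0, w) * nai3 - lk(tb.ncxB, i0, w) * s[iCAI];
  I[7] = lk(tb.nakf, i0, w) * s[iNAI] / (s[iNAI] + p.KmNa);
  I[8] = p.GpCa * s[iCAI] / (p.KpCa + s[iCAI]);
  I[9] = lk(tb.ipkf, i0, w) * (V - Ek);
  I[10] = p.GbCa * (V - Eca);
  I[11] = p.GbNa * (V - Ena);
  I[12] = I[0] + I[1] + I[2] + I[3] + I[4] + I[5] + I[6] + I[7] + I[8] +
          I[9] + I[10] + I[11];
}

// fast single-node step (tables); same scheme as step_node
static inline void step_node_fast(double* s, const Params& p, const Tables& tb,
                                  double istim, double dt, bool euler_gates) {
  const double V = s[iV];
  const double Ek  = p.RTONF * std::log(p.Ko / s[iKI]);
  const double Ena = p.RTONF * std::log(p.Nao / s[iNAI]);
  const double Eks = p.RTONF * std::log((p.Ko + p.pKNa * p.Nao) /
                                        (s[iKI] + p.pKNa * s[iNAI]));
  const double Eca = 0.5 * p.RTONF * std::log(p.Cao / s[iCAI]);
  double xi = (V - tb.v0) / tb.dv;
  int i0 = (int)xi; double w = xi - i0;

  double I[13];
  currents_fast(s, p, tb, i0, w, Ek, Ena, Eks, Eca, I);
  const double iion = I[12];

  const double caf = p.Cm / (2.0 * p.Vc * p.Fcst);
  const double naf = p.Cm / (p.Vc * p.Fcst);
  double casr = s[iCASR], cass = s[iCASS], cai = s[iCAI];
  double kCaSR = p.maxsr - (p.maxsr - p.minsr) /
                 (1.0 + (p.EC / casr) * (p.EC / casr));
  double k1 = p.k1p / kCaSR;
  double k2 = p.k2p * kCaSR;
  double rbar = s[iRBAR];
  s[iRBAR] = rbar + dt * (p.k4 * (1.0 - rbar) - k2 * cass * rbar);
  double O = k1 * cass * cass * s[iRBAR] / (p.k3 + k1 * cass * cass);
  double Irel  = p.Vrel * O * (casr - cass);
  double Ileak = p.Vleak * (casr - cai);
  double Iup   = p.Vmaxup / (1.0 + (p.Kup / cai) * (p.Kup / cai));
  double Ixfer = p.Vxfer * (cass - cai);

  double dcasr = dt * (Iup - Irel - Ileak);
  s[iCASR] = buffered_update(casr, dcasr, p.Bufsr, p.Kbufsr);
  double dcass = dt * (-Ixfer * (p.Vc / p.Vss) + Irel * (p.Vsr / p.Vss) -
                       I[5] * p.Cm / (2.0 * p.Vss * p.Fcst));
  s[iCASS] = buffered_update(cass, dcass, p.Bufss, p.Kbufss);
  double dcai = dt * (-(I[10] + I[8] - 2.0 * I[6]) * caf -
                      (Iup - Ileak) * (p.Vsr / p.Vc) + Ixfer);
  s[iCAI] = buffered_update(cai, dcai, p.Bufc, p.Kbufc);
  s[iNAI] += dt * (-(I[0] + I[11] + 3.0 * I[7] + 3.0 * I[6]) * naf);
  s[iKI]  += dt * (-(istim + I[1] + I[2] + I[3] + I[4] - 2.0 * I[7] + I[9]) * naf);

  for (int g = 0; g < 11; ++g) {
    int k = GATE_IDX[g];
    double gi = lk(tb.ginf[g], i0, w);
    if (euler_gates)
      s[k] += lk(tb.grl[g], i0, w) * (gi - s[k]);
    else
      s[k] = gi + (s[k] - gi) * lk(tb.grl[g], i0, w);
  }
  {
    double q = (cass / 0.05) * (cass / 0.05);
    double fci = 0.6 / (1.0 + q) + 0.4;
    double fct = 80.0 / (1.0 + q) + 2.0;
    if (euler_gates)
      s[iFCASS] += dt * (fci - s[iFCASS]) / fct;
    else
      s[iFCASS] = fci + (s[iFCASS] - fci) * std::exp(-dt / fct);
  }
  s[iV] = V - dt * (iion + istim);
}

static void check_v_range(double V) {
  if (!(V > -150.0 && V < 150.0))
    stop("membrane voltage %f mV outside the numerical guard range [-150, 150]", V);
}

// [[Rcpp::export]]
NumericVector cpp_currents(NumericVector state, List params) {
  if (state.size() != N_STATE) stop("state must have %d elements", N_STATE);
  check_v_range(state[iV]);
  Params p = unpack_params(params);
  double I[13];
  currents(REAL(state), p, I);
  NumericVector out(13);
  for (int k = 0; k < 13; ++k) out[k] = I[k];
  out.attr("names") = CharacterVector::create(
      "I_Na", "I_K1", "I_to", "I_Kr", "I_Ks", "I_CaL", "I_NaCa", "I_NaK",
      "I_pCa", "I_pK", "I_bCa", "I_bNa", "I_ion");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gate_rates(double V, double tau_f_scale) {
  double inf[N_VGATE], tau[N_VGATE];
  gate_rates(V, tau_f_scale, inf, tau);
  NumericVector out(2 * (N_VGATE - 1));
  CharacterVector nm(2 * (N_VGATE - 1));
  const char* gn[11] = { "m", "h", "j", "d", "f", "f2", "r", "s",
                         "xr1", "xr2", "xs" };
  for (int g = 0; g < N_VGATE - 1; ++g) {
    out[g] = inf[g];
    out[g + 11] = tau[g];
    nm[g] = std::string(gn[g]) + "_inf";
    nm[g + 11] = std::string("tau_") + gn[g];
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_step_cell(NumericVector state, List params, double istim,
                            double dt, bool euler_gates) {
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms");
  check_v_range(state[iV]);
  Params p = unpack_params(params);
  NumericVector s = clone(state);
  step_node(REAL(s), p, istim, dt, euler_gates);
  for (int k = 0; k < N_STATE; ++k)
    if (!R_finite(s[k]))
      stop("integration failure: state field %d became non-finite", k + 1);
  return s;
}

// [[Rcpp::export]]
List cpp_run_cell(NumericVector state, List params, double dt, double duration,
                  NumericVector stim_onsets, double stim_dur, double stim_amp,
                  double record_every, bool record_currents, bool euler_gates) {
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1] ms");
  Params p = unpack_params(params);
  Tables tb = build_tables(p, dt, euler_gates);
  NumericVector s = clone(state);
  double* sp = REAL(s);

  const long nsteps = (long)std::floor(duration / dt + 0.5);
  const long rec_steps = std::max(1L, (long)std::floor(record_every / dt + 0.5));
  const long nrec = nsteps / rec_steps + 1;
  NumericVector t_out(nrec), v_out(nrec);
  NumericMatrix cur_out = record_currents ? NumericMatrix(nrec, 13)
                                          : NumericMatrix(0, 0);
  double I[13];

  long ri = 0;
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % rec_steps == 0) {
      check_v_range(sp[iV]);
      t_out[ri] = t;
      v_out[ri] = sp[iV];
      if (record_currents) {
        currents(sp, p, I);
        for (int k = 0; k < 13; ++k) cur_out(ri, k) = I[k];
      }
      ++ri;
    }
    if (step == nsteps) break;
    double istim = 0.0;
    for (int k = 0; k < stim_onsets.size(); ++k) {
      if (t >= stim_onsets[k] && t < stim_onsets[k] + stim_dur) {
        istim = -stim_amp;  // positive configured amplitude depolarizes
        break;
      }
    }
    step_node_fast(sp, p, tb, istim, dt, euler_gates);
    if (!R_finite(sp[iV]))
      stop("integration failure at t = %f ms: V became non-finite", t);
  }
  List out = List::create(_["t"] = t_out, _["V"] = v_out,
                          _["final_state"] = s);
  if (record_currents) out["currents"] = cur_out;
  return out;
}

// 5-point Laplacian with per-edge coupling mask; masked or boundary edges
// contribute the centre value (zero flux).
// [[Rcpp::export]]
NumericMatrix cpp_laplacian5(NumericMatrix field, double dx,
                             LogicalMatrix conn_r, LogicalMatrix conn_u) {
  int nx = field.nrow(), ny = field.ncol();
  if (conn_r.nrow() != nx || conn_r.ncol() != ny ||
      conn_u.nrow() != nx || conn_u.ncol() != ny)
    stop("coupling mask shape does not match the field");
  NumericMatrix out(nx, ny);
  double dx2 = dx * dx;
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double c = field(x, y), acc = 0.0;
      if (x + 1 < nx && conn_r(x, y)) acc += field(x + 1, y) - c;
      if (x > 0 && conn_r(x - 1, y)) acc += field(x - 1, y) - c;
      if (y + 1 < ny && conn_u(x, y)) acc += field(x, y + 1) - c;
      if (y > 0 && conn_u(x, y - 1)) acc += field(x, y - 1) - c;
      out(x, y) = acc / dx2;
    }
  }
  return out;
}

// 2D monodomain tissue run.
//
// state: N x 19 matrix (node-major, node index = x + nx*y, x fastest).
// conn_r[i]: edge between node i and its +x neighbour conducts.
// conn_u[i]: edge between node i and its +y neighbour conducts.
// stims: list of list(onset=double (NA => waveback trigger), dur, amp,
//        nodes=integer vector 1-based).  A triggered stimulus arms when any
//        node of the monitored column exceeds trigger_arm_v and fires when
//        the whole column has repolarized below trigger_fire_v (the S1
//        waveback passing the column).
// D in cm^2/ms, dx in mm (converted internally), dt/duration/frame_every ms.
// [[Rcpp::export]]
List cpp_run_tissue(NumericMatrix state, int nx, int ny,
                    LogicalVector conn_r, LogicalVector conn_u,
                    List params, double D, double dx, double dt,
                    double duration, List stims,
                    double trigger_col_frac, double trigger_arm_v,
                    double trigger_fire_v,
                    double frame_every, bool record_gates,
                    bool diffusion_only, bool euler_gates) {
  const int N = nx * ny;
  if (state.nrow() != N || state.ncol() != N_STATE)
    stop("state matrix must be %d x %d", N, N_STATE);
  if (conn_r.size() != N || conn_u.size() != N)
    stop("coupling mask length must equal nx*ny");
  Params p = unpack_params(params);
  Tables tb = build_tables(p, dt, euler_gates);
  const double Dmm = D * 100.0;           // cm^2/ms -> mm^2/ms
  const double dfac = Dmm / (dx * dx);
  if (!diffusion_only && 4.0 * dfac * dt > 1.0)
    stop("explicit-scheme stability bound violated: dt <= dx^2/(4 D)");

  // local copies for fast access
  std::vector<double> S(N * (size_t)N_STATE);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < N_STATE; ++k) S[(size_t)i * N_STATE + k] = state(i, k);
  std::vector<char> cr(N), cu(N);
  for (int i = 0; i < N; ++i) { cr[i] = conn_r[i]; cu[i] = conn_u[i]; }

  // stimuli
  const int ns = stims.size();
  std::vector<double> s_on(ns), s_dur(ns), s_amp(ns);
  std::vector<bool> s_trig(ns), s_fired(ns);
  std::vector<std::vector<int>> s_nodes(ns);
  for (int k = 0; k < ns; ++k) {
    List st = stims[k];
    double on = as<double>(st["onset"]);
    s_trig[k] = !R_finite(on);
    s_on[k] = s_trig[k] ? R_PosInf : on;
    s_fired[k] = !s_trig[k];
    s_dur[k] = as<double>(st["dur"]);
    s_amp[k] = as<double>(st["amp"]);
    IntegerVector nd = st["nodes"];
    s_nodes[k].resize(nd.size());
    for (int q = 0; q < nd.size(); ++q) {
      int idx = nd[q] - 1;
      if (idx < 0 || idx >= N) stop("stimulus node index out of range");
      s_nodes[k][q] = idx;
    }
  }
  int trig_x = (int)std::floor(trigger_col_frac * nx);
  if (trig_x < 0) trig_x = 0;
  if (trig_x >= nx) trig_x = nx - 1;
  bool trig_armed = false;

  const long nsteps = (long)std::floor(duration / dt + 0.5);
  const long f_steps = std::max(1L, (long)std::floor(frame_every / dt + 0.5));
  const long nf = nsteps / f_steps + 1;
  NumericVector v_frames((size_t)N * nf);
  NumericVector na_frames(record_gates ? (size_t)N * nf : 0);
  NumericVector ca_frames(record_gates ? (size_t)N * nf : 0);
  NumericVector f_times(nf);
  std::vector<double> vnew(N), istim(N);

  long fi = 0;
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;

    // waveback trigger check (every ms): arm while the monitored column is
    // excited, fire once it has fully repolarized again
    if (step % std::max(1L, (long)std::floor(1.0 / dt + 0.5)) == 0) {
      bool any_pending = false;
      for (int k = 0; k < ns; ++k) if (!s_fired[k]) any_pending = true;
      if (any_pending) {
        double colmax = -1e30;
        for (int y = 0; y < ny; ++y) {
          double v = S[(size_t)(trig_x + nx * y) * N_STATE + iV];
          if (v > colmax) colmax = v;
        }
        if (!trig_armed && colmax > trigger_arm_v) trig_armed = true;
        if (trig_armed && colmax < trigger_fire_v)
          for (int k = 0; k < ns; ++k)
            if (!s_fired[k]) { s_fired[k] = true; s_on[k] = t; }
      }
    }

    if (step % f_steps == 0) {
      f_times[fi] = t;
      for (int i = 0; i < N; ++i) {
        double V = S[(size_t)i * N_STATE + iV];
        if (!R_finite(V))
          stop("NaN/Inf voltage at node (x=%d, y=%d), t = %f ms",
               i % nx, i / nx, t);
        check_v_range(V);
        v_frames[(size_t)fi * N + i] = V;
        if (record_gates) {
          double* si = &S[(size_t)i * N_STATE];
          double m = si[iM];
          na_frames[(size_t)fi * N + i] = m * m * m * si[iH] * si[iJ];
          ca_frames[(size_t)fi * N + i] =
              si[iD] * si[iF] * si[iF2] * si[iFCASS];
        }
      }
      ++fi;
      Rcpp::checkUserInterrupt();
    }
    if (step == nsteps) break;

    // stimulus field
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int k = 0; k < ns; ++k)
      if (t >= s_on[k] && t < s_on[k] + s_dur[k])
        for (size_t q = 0; q < s_nodes[k].size(); ++q)
          istim[s_nodes[k][q]] = -s_amp[k];

    // diffusion term on V (mask-aware 5-point stencil, zero-flux defaults)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * y;
        double c = S[(size_t)i * N_STATE + iV], acc = 0.0;
        if (x + 1 < nx && cr[i]) acc += S[(size_t)(i + 1) * N_STATE + iV] - c;
        if (x > 0 && cr[i - 1]) acc += S[(size_t)(i - 1) * N_STATE + iV] - c;
        if (y + 1 < ny && cu[i]) acc += S[(size_t)(i + nx) * N_STATE + iV] - c;
        if (y > 0 && cu[i - nx]) acc += S[(size_t)(i - nx) * N_STATE + iV] - c;
        vnew[i] = dt * dfac * acc;
      }
    }
    if (diffusion_only) {
      for (int i = 0; i < N; ++i) S[(size_t)i * N_STATE + iV] += vnew[i];
    } else {
      for (int i = 0; i < N; ++i) {
        step_node_fast(&S[(size_t)i * N_STATE], p, tb, istim[i], dt, euler_gates);
        S[(size_t)i * N_STATE + iV] += vnew[i];
      }
    }
  }

  NumericMatrix fstate(N, N_STATE);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < N_STATE; ++k) fstate(i, k) = S[(size_t)i * N_STATE + k];

  NumericVector onsets(ns);
  for (int k = 0; k < ns; ++k) onsets[k] = s_fired[k] ? s_on[k] : NA_REAL;

  v_frames.attr("dim") = IntegerVector::create(nx, ny, nf);
  List out = List::create(_["times"] = f_times, _["V"] = v_frames,
                          _["final_state"] = fstate,
                          _["stim_onsets"] = onsets);
  if (record_gates) {
    na_frames.attr("dim") = IntegerVector::create(nx, ny, nf);
    ca_frames.attr("dim") = IntegerVector::create(nx, ny, nf);
    out["na_gate"] = na_frames;
    out["ca_gate"] = ca_frames;
  }
  return out;
}
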
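// Ventricular myocyte cell models and hybrid Rush-Larsen integration.
//
// Models (state/parameter orders are mirrored in R/model-registry.R):
//   1 = LR1    : Luo & Rudy 1991 phase-1 guinea-pig ventricular model
//                states V, m, h, j, d, f, X, Cai; 6 scalable conductances
//   2 = TNNP   : ten Tusscher, Noble, Noble & Panfilov 2004 human ventricular
//                model, epicardial variant; states V, m, h, j, d, f, fCa, r, s,
//                xr1, xr2, xs, g, Cai, CaSR, Nai, Ki; 16 scalable parameters
//   3 = BERNUS : six-variable reduced human ventricular model in the style of
//                Bernus et al. 2002; states V, m, v, f, to, X; 8 scalable
//                parameters; fixed intracellular concentrations
//
// Numerics: Hodgkin-Huxley gates are advanced with the Rush-Larsen exact
// exponential update x <- xinf + (x - xinf) exp(-dt/tau), which is
// unconditionally stable and removes the sub-microsecond gate stiffness of
// the fast Na+ activation gate.  Voltage and ion concentrations are advanced
// explicitly with an adaptive step chosen so the voltage change per step
// stays below a target (and the relative Ca2+ change stays small), clamped
// to [dt_min, dt_max].
//
// Conventions: time in ms, voltage in mV, currents in pA/pF, concentrations
// in mM.  The stimulus is a depolarizing current in pA/pF added to dV/dt.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double Rgas = 8314.472;   // mJ/(mol K)
static const double Temp = 310.0;      // K
static const double Frdy = 96485.3415; // C/mol

static inline double sq(double x) { return x * x; }
static inline double cube(double x) { return x * x * x; }

// Per-state integration metadata filled by the model evaluators: for gate
// states inf/tau are set (tau = INFINITY freezes the gate), for non-gate
// states dy is set.
struct Eval {
  double dy[20];
  double inf[20];
  double tau[20];
};

// ---------------------------------------------------------------------------
// LR1: Luo & Rudy 1991.  p = {GNa, Gsi, GK, GK1, GKp, Gb}
// ---------------------------------------------------------------------------
static const int LR1_NSTATE = 8;
static const int LR1_NPAR = 6;

static void eval_lr1(const double *y, const double *p, double Ko, double stim,
                     Eval &e) {
  const double V = y[0], m = y[1], h = y[2], j = y[3];
  const double d = y[4], f = y[5], X = y[6], Cai = y[7];
  const double Nao = 140.0, Nai = 18.0, Ki = 145.0;
  const double RTF = Rgas * Temp / Frdy;

  const double ENa = RTF * std::log(Nao / Nai);
  const double INa = p[0] * cube(m) * h * j * (V - ENa);
  const double am = std::fabs(V + 47.13) < 1e-9
                        ? 3.2
                        : 0.32 * (V + 47.13) /
                              (1.0 - std::exp(-0.1 * (V + 47.13)));
  const double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(80.0 + V) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }

  const double Esi = 7.7 - 13.0287 * std::log(Cai);
  const double Isi = p[1] * d * f * (V - Esi);
  const double ad = 0.095 * std::exp(-0.01 * (V - 5.0)) /
                    (1.0 + std::exp(-0.072 * (V - 5.0)));
  const double bd = 0.07 * std::exp(-0.017 * (V + 44.0)) /
                    (1.0 + std::exp(0.05 * (V + 44.0)));
  const double af = 0.012 * std::exp(-0.008 * (V + 28.0)) /
                    (1.0 + std::exp(0.15 * (V + 28.0)));
  const double bf = 0.0065 * std::exp(-0.02 * (V + 30.0)) /
                    (1.0 + std::exp(-0.2 * (V + 30.0)));

  const double PRNaK = 0.01833;
  const double EK = RTF * std::log((Ko + PRNaK * Nao) / (Ki + PRNaK * Nai));
  const double GKbar = p[2] * std::sqrt(Ko / 5.4);
  double Xi;
  if (V > -100.0) {
    Xi = std::fabs(V + 77.0) < 1e-9
             ? 2.837 * 0.04 / std::exp(0.04 * (V + 35.0))
             : 2.837 * (std::exp(0.04 * (V + 77.0)) - 1.0) /
                   ((V + 77.0) * std::exp(0.04 * (V + 35.0)));
  } else {
    Xi = 1.0;
  }
  const double IK = GKbar * X * Xi * (V - EK);
  const double aX = 0.0005 * std::exp(0.083 * (V + 50.0)) /
                    (1.0 + std::exp(0.057 * (V + 50.0)));
  const double bX = 0.0013 * std::exp(-0.06 * (V + 20.0)) /
                    (1.0 + std::exp(-0.04 * (V + 20.0)));

  const double EK1 = RTF * std::log(Ko / Ki);
  const double GK1bar = p[3] * std::sqrt(Ko / 5.4);
  const double aK1 = 1.02 / (1.0 + std::exp(0.2385 * (V - EK1 - 59.215)));
  const double bK1 =
      (0.49124 * std::exp(0.08032 * (V - EK1 + 5.476)) +
       std::exp(0.06175 * (V - EK1 - 594.31))) /
      (1.0 + std::exp(-0.5143 * (V - EK1 + 4.753)));
  const double IK1 = GK1bar * (aK1 / (aK1 + bK1)) * (V - EK1);
  const double Kp = 1.0 / (1.0 + std::exp((7.488 - V) / 5.98));
  const double IKp = p[4] * Kp * (V - EK1);
  const double Ib = p[5] * (V + 59.87);

  const double Iion = INa + Isi + IK + IK1 + IKp + Ib;
  e.dy[0] = -Iion + stim;
  e.dy[7] = -1.0e-4 * Isi + 0.07 * (1.0e-4 - Cai);
  const double a[6] = {am, ah, aj, ad, af, aX};
  const double b[6] = {bm, bh, bj, bd, bf, bX};
  for (int g = 0; g < 6; ++g) {
    e.inf[g + 1] = a[g] / (a[g] + b[g]);
    e.tau[g + 1] = 1.0 / (a[g] + b[g]);
  }
}

// ---------------------------------------------------------------------------
// TNNP: ten Tusscher et al. 2004, epicardial.
// p = {GNa, GCaL, Gto, GKr, GKs, GK1, GpK, GbNa, GbCa, GpCa(K_pCa),
//      PNaK(K_NaK), kNaCa(K_NCX), Vmaxup(K_up), Vleak(K_leak),
//      arel(K_rel1), crel(K_rel2)}
// ---------------------------------------------------------------------------
static const int TNNP_NSTATE = 17;
static const int TNNP_NPAR = 16;

static void eval_tnnp(const double *y, const double *p, double Ko, double stim,
                      Eval &e) {
  const double V = y[0], m = y[1], h = y[2], j = y[3], d = y[4], f = y[5];
  const double fCa = y[6], r = y[7], s = y[8], xr1 = y[9], xr2 = y[10];
  const double xs = y[11], g = y[12];
  const double Cai = y[13], CaSR = y[14], Nai = y[15], Ki = y[16];

  const double Nao = 140.0, Cao = 2.0;
  const double RTF = Rgas * Temp / Frdy;
  const double FRT = 1.0 / RTF;
  const double Cm = 0.185;
  const double Vc = 0.016404;
  const double Vsr = 0.001094;
  const double pKNa = 0.03;

  const double EK = RTF * std::log(Ko / Ki);
  const double ENa = RTF * std::log(Nao / Nai);
  const double EKs = RTF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  const double INa = p[0] * cube(m) * h * j * (V - ENa);
  const double minf = 1.0 / sq(1.0 + std::exp((-56.86 - V) / 9.03));
  const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                    0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  const double taum = am * bm;
  const double hinf = 1.0 / sq(1.0 + std::exp((V + 71.55) / 7.43));
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    aj = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }

  double ICaL;
  const double expo = std::exp(2.0 * V * FRT);
  if (std::fabs(V) < 1.0e-6) {
    ICaL = p[1] * d * f * fCa * 2.0 * Frdy * (Cai - 0.341 * Cao);
  } else {
    ICaL = p[1] * d * f * fCa * 4.0 * V * Frdy * FRT *
           (Cai * expo - 0.341 * Cao) / (expo - 1.0);
  }
  const double dinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 7.5));
  const double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  const double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  const double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  const double taud = ad * bd + gd;
  const double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  const double tauf = 1125.0 * std::exp(-sq(V + 27.0) / 240.0) + 80.0 +
                      165.0 / (1.0 + std::exp((25.0 - V) / 10.0));
  const double afca = 1.0 / (1.0 + std::pow(Cai / 0.000325, 8.0));
  const double bfca = 0.1 / (1.0 + std::exp((Cai - 0.0005) / 0.0001));
  const double gfca = 0.2 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
  const double fcainf = (afca + bfca + gfca + 0.23) / 1.46;

  const double Ito = p[2] * r * s * (V - EK);
  const double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  const double taur = 9.5 * std::exp(-sq(V + 40.0) / 1800.0) + 0.8;
  const double sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  const double taus = 85.0 * std::exp(-sq(V + 45.0) / 320.0) +
                      5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;

  const double IKr = p[3] * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
  const double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  const double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));

  const double IKs = p[4] * sq(xs) * (V - EKs);
  const double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  const double axs = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0));
  const double bxs = 1.0 / (1.0 + std::exp((V - 60.0) / 20.0));

  const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  const double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                      std::exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - EK)));
  const double IK1 = p[5] * std::sqrt(Ko / 5.4) * (aK1 / (aK1 + bK1)) * (V - EK);

  const double IpK = p[6] * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = p[7] * (V - ENa);
  const double IbCa = p[8] * (V - ECa);
  const double IpCa = p[9] * Cai / (Cai + 0.0005);
  const double INaK = p[10] * Ko * Nai /
                      ((Ko + 1.0) * (Nai + 40.0) *
                       (1.0 + 0.1245 * std::exp(-0.1 * V * FRT) +
                        0.0353 * std::exp(-V * FRT)));
  const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35, alp = 2.5;
  const double INaCa =
      p[11] *
      (std::exp(gam * V * FRT) * cube(Nai) * Cao -
       std::exp((gam - 1.0) * V * FRT) * cube(Nao) * Cai * alp) /
      ((cube(KmNai) + cube(Nao)) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((gam - 1.0) * V * FRT)));

  const double Ileak = p[13] * (CaSR - Cai);
  const double Iup = p[12] / (1.0 + sq(0.00025 / Cai));
  const double Irel = (p[14] * sq(CaSR) / (sq(0.25) + sq(CaSR)) + p[15]) * d * g;
  double ginf;
  if (Cai < 0.00035) {
    ginf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 6.0));
  } else {
    ginf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 16.0));
  }

  const double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + IpK + IbNa + IbCa +
                      IpCa + INaK + INaCa;
  e.dy[0] = -Iion + stim;

  e.inf[1] = minf; e.tau[1] = taum;
  e.inf[2] = hinf; e.tau[2] = 1.0 / (ah + bh);
  e.inf[3] = hinf; e.tau[3] = 1.0 / (aj + bj);
  e.inf[4] = dinf; e.tau[4] = taud;
  e.inf[5] = finf; e.tau[5] = tauf;
  // fCa and g only relax toward lower values while depolarized
  e.inf[6] = fcainf;
  e.tau[6] = (fcainf > fCa && V > -60.0) ? R_PosInf : 2.0;
  e.inf[7] = rinf; e.tau[7] = taur;
  e.inf[8] = sinf; e.tau[8] = taus;
  e.inf[9] = xr1inf; e.tau[9] = axr1 * bxr1;
  e.inf[10] = xr2inf; e.tau[10] = axr2 * bxr2;
  e.inf[11] = xsinf; e.tau[11] = axs * bxs;
  e.inf[12] = ginf;
  e.tau[12] = (ginf > g && V > -60.0) ? R_PosInf : 2.0;

  const double bufc = 1.0 / (1.0 + 0.15 * 0.001 / sq(Cai + 0.001));
  const double bufsr = 1.0 / (1.0 + 10.0 * 0.3 / sq(CaSR + 0.3));
  e.dy[13] = bufc * (-(ICaL + IbCa + IpCa - 2.0 * INaCa) * Cm /
                         (2.0 * Vc * Frdy) +
                     Ileak - Iup + Irel);
  e.dy[14] = bufsr * (Vc / Vsr) * (Iup - Irel - Ileak);
  e.dy[15] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm / (Vc * Frdy);
  e.dy[16] = -(IK1 + Ito + IKr + IKs + IpK - 2.0 * INaK - stim) * Cm /
             (Vc * Frdy);
}

// ---------------------------------------------------------------------------
// BERNUS: six-variable reduced human ventricular model (Bernus-type).
// p = {GNa, GCa, Gto, GK, GK1, PNaK(K_NaK), kNaCa(K_NCX), GbNa}
// Fixed Nai = 10 mM, Ki = 140 mM, Cai = 0.0002 mM.
// ---------------------------------------------------------------------------
static const int BRN_NSTATE = 6;
static const int BRN_NPAR = 8;

static void eval_bernus(const double *y, const double *p, double Ko,
                        double stim, Eval &e) {
  const double V = y[0], m = y[1], v = y[2], f = y[3], to = y[4], X = y[5];
  const double Nao = 140.0, Nai = 10.0, Ki = 140.0, Cao = 2.0, Cai = 0.0002;
  const double RTF = Rgas * Temp / Frdy;
  const double FRT = 1.0 / RTF;

  const double ENa = RTF * std::log(Nao / Nai);
  const double EK = RTF * std::log(Ko / Ki);
  const double ECa = 51.8;

  const double INa = p[0] * cube(m) * sq(v) * (V - ENa);
  const double am = std::fabs(V + 47.13) < 1e-9
                        ? 3.2
                        : 0.32 * (V + 47.13) /
                              (1.0 - std::exp(-0.1 * (V + 47.13)));
  const double bm = 0.08 * std::exp(-V / 11.0);
  const double vinf = 0.5 * (1.0 - std::tanh((V + 71.55) / 7.43));
  const double tauv = 1.5 + 130.0 * std::exp(-sq(V + 80.0) / 450.0);

  const double dinf = 1.0 / (1.0 + std::exp(-(V + 6.0) / 7.5));
  const double ICa = p[1] * dinf * f * (V - ECa);
  const double finf = 1.0 / (1.0 + std::exp((V + 25.0) / 7.0));
  const double tauf = 260.0 * std::exp(-sq(V + 25.0) / 240.0) + 60.0;

  const double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  const double Ito = p[2] * rinf * to * (V - EK);
  const double toinf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
  const double tauto = 35.0 * std::exp(-sq(V + 45.0) / 320.0) +
                       8.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 5.0;

  const double IK = p[3] * std::sqrt(Ko / 5.4) * sq(X) * (V - EK);
  const double Xinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  const double aX = 380.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0));
  const double bX = 1.0 / (1.0 + std::exp((V - 60.0) / 20.0));
  const double tauX = aX * bX + 80.0;

  const double aK1 = 1.02 / (1.0 + std::exp(0.2385 * (V - EK - 59.215)));
  const double bK1 = (0.49124 * std::exp(0.08032 * (V - EK + 5.476)) +
                      std::exp(0.06175 * (V - EK - 594.31))) /
                     (1.0 + std::exp(-0.5143 * (V - EK + 4.753)));
  const double IK1 = p[4] * std::sqrt(Ko / 5.4) * (aK1 / (aK1 + bK1)) * (V - EK);

  const double INaK = p[5] * Ko * Nai /
                      ((Ko + 1.0) * (Nai + 40.0) *
                       (1.0 + 0.1245 * std::exp(-0.1 * V * FRT) +
                        0.0353 * std::exp(-V * FRT)));
  const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35, alp = 2.5;
  const double INaCa =
      p[6] *
      (std::exp(gam * V * FRT) * cube(Nai) * Cao -
       std::exp((gam - 1.0) * V * FRT) * cube(Nao) * Cai * alp) /
      ((cube(KmNai) + cube(Nao)) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((gam - 1.0) * V * FRT)));
  const double IbNa = p[7] * (V - ENa);

  const double Iion = INa + ICa + Ito + IK + IK1 + INaK + INaCa + IbNa;
  e.dy[0] = -Iion + stim;
  e.inf[1] = am / (am + bm); e.tau[1] = 1.0 / (am + bm);
  e.inf[2] = vinf; e.tau[2] = tauv;
  e.inf[3] = finf; e.tau[3] = tauf;
  e.inf[4] = toinf; e.tau[4] = tauto;
  e.inf[5] = Xinf; e.tau[5] = tauX;
}

// ---------------------------------------------------------------------------
// dispatch
// ---------------------------------------------------------------------------
static int model_nstate(int model) {
  if (model == 1) return LR1_NSTATE;
  if (model == 2) return TNNP_NSTATE;
  if (model == 3) return BRN_NSTATE;
  stop("unknown model code %d", model);
  return 0;
}
static int model_npar(int model) {
  if (model == 1) return LR1_NPAR;
  if (model == 2) return TNNP_NPAR;
  if (model == 3) return BRN_NPAR;
  stop("unknown model code %d", model);
  return 0;
}
// index range [lo, hi] of gate states; non-gates are everything else
static void model_gates(int model, int &lo, int &hi) {
  if (model == 1) { lo = 1; hi = 6; }
  else if (model == 2) { lo = 1; hi = 12; }
  else { lo = 1; hi = 5; }
}
static int cai_index(int model) {
  if (model == 1) return 7;
  if (model == 2) return 13;
  return -1;
}
static void model_eval(int model, const double *y, const double *p, double Ko,
                       double stim, Eval &e) {
  if (model == 1) eval_lr1(y, p, Ko, stim, e);
  else if (model == 2) eval_tnnp(y, p, Ko, stim, e);
  else eval_bernus(y, p, Ko, stim, e);
}

// [[Rcpp::export]]
NumericVector cm_derivs_cpp(int model, NumericVector state, NumericVector params,
                            double stim, double Ko) {
  const int ns = model_nstate(model);
  if ((int)state.size() != ns)
    stop("state length %d does not match model (expected %d)", state.size(), ns);
  if ((int)params.size() != model_npar(model))
    stop("parameter length %d does not match model (expected %d)",
         params.size(), model_npar(model));
  for (int i = 0; i < ns; ++i)
    if (!R_finite(state[i])) stop("non-finite state entry at position %d", i + 1);
  Eval e;
  model_eval(model, REAL(state), REAL(params), Ko, stim, e);
  int glo, ghi;
  model_gates(model, glo, ghi);
  NumericVector dy(ns);
  for (int i = 0; i < ns; ++i) {
    if (i >= glo && i <= ghi) {
      dy[i] = R_finite(e.tau[i]) ? (e.inf[i] - state[i]) / e.tau[i] : 0.0;
    } else {
      dy[i] = e.dy[i];
    }
  }
  return dy;
}

// ---------------------------------------------------------------------------
// integration
// ---------------------------------------------------------------------------
struct StepRecorder {
  std::vector<double> t_acc, v_acc, cai_acc;
  bool want_trace;
  double dt_out, next_out, t_end_out;
  std::vector<double> trace;
  int cai; // Cai state index or -1
};

struct SpanResult {
  int status;
  double dvdt_max, t_dvdt_max, v_max, t_v_max;
};

// accuracy knobs: acc[0] = dv_step (mV per step), acc[1] = dt_min (ms),
// acc[2] = dt_max (ms), acc[3] = relative Ca change per step
static SpanResult integrate_span(int model, const double *p, double Ko,
                                 double stim, double *y, double t0, double t1,
                                 const double *acc, double hmax,
                                 StepRecorder *rec) {
  const int ns = model_nstate(model);
  int glo, ghi;
  model_gates(model, glo, ghi);
  const int cai = cai_index(model);

  SpanResult res;
  res.status = 0;
  res.dvdt_max = R_NegInf;
  res.t_dvdt_max = t0;
  res.v_max = y[0];
  res.t_v_max = t0;

  const double dv_step = acc[0], dt_min = acc[1], cai_step = acc[3];
  double dt_max = acc[2];
  if (hmax > 0 && hmax < dt_max) dt_max = hmax;

  Eval e;
  double t = t0;
  double yprev[20];
  while (t < t1 - 1.0e-9) {
    model_eval(model, y, p, Ko, stim, e);
    const double dvdt = e.dy[0];
    if (dvdt > res.dvdt_max) { res.dvdt_max = dvdt; res.t_dvdt_max = t; }
    if (y[0] > res.v_max) { res.v_max = y[0]; res.t_v_max = t; }

    double dt = dv_step / (std::fabs(dvdt) + 1.0e-12);
    if (cai >= 0) {
      const double dtc = cai_step * (std::fabs(y[cai]) + 1.0e-4) /
                         (std::fabs(e.dy[cai]) + 1.0e-12);
      if (dtc < dt) dt = dtc;
    }
    if (dt < dt_min) dt = dt_min;
    if (dt > dt_max) dt = dt_max;
    if (t + dt > t1) dt = t1 - t;

    for (int i = 0; i < ns; ++i) yprev[i] = y[i];
    for (int i = 0; i < ns; ++i) {
      if (i >= glo && i <= ghi) {
        if (R_finite(e.tau[i]))
          y[i] = e.inf[i] + (y[i] - e.inf[i]) * std::exp(-dt / e.tau[i]);
      } else {
        y[i] += dt * e.dy[i];
      }
    }
    const double tprev = t;
    t += dt;
    if (!R_finite(y[0]) || (cai >= 0 && (!R_finite(y[cai]) || y[cai] <= 0))) {
      res.status = 1;
      return res;
    }

    if (rec) {
      rec->t_acc.push_back(t);
      rec->v_acc.push_back(y[0]);
      if (rec->cai >= 0) rec->cai_acc.push_back(y[rec->cai]);
      if (rec->want_trace) {
        while (rec->next_out <= t + 1.0e-12 &&
               rec->next_out <= rec->t_end_out + 1.0e-12) {
          const double w = (rec->next_out - tprev) / (t - tprev);
          rec->trace.push_back(rec->next_out);
          for (int i = 0; i < ns; ++i)
            rec->trace.push_back(yprev[i] + w * (y[i] - yprev[i]));
          rec->trace.push_back(stim);
          rec->next_out += rec->dt_out;
        }
      }
    }
  }
  if (y[0] > res.v_max) { res.v_max = y[0]; res.t_v_max = t1; }
  return res;
}

static double apd_crossing(const std::vector<double> &t,
                           const std::vector<double> &v, double t_from,
                           double thr) {
  for (size_t i = 1; i < t.size(); ++i) {
    if (t[i] <= t_from) continue;
    if (v[i - 1] > thr && v[i] <= thr) {
      const double w = (thr - v[i - 1]) / (v[i] - v[i - 1]);
      return t[i - 1] + w * (t[i] - t[i - 1]);
    }
  }
  return NA_REAL;
}

// [[Rcpp::export]]
List cm_run_cpp(int model, NumericVector params, NumericVector state0,
                double duration, double stim_amp, double stim_start,
                double stim_dur, double Ko, double dt_out,
                NumericVector acc, double t_offset) {
  const int ns = model_nstate(model);
  if ((int)state0.size() != ns) stop("state length does not match model");
  if ((int)params.size() != model_npar(model))
    stop("parameter length does not match model");
  if (acc.size() != 4) stop("acc must have length 4");
  std::vector<double> y(state0.begin(), state0.end());

  StepRecorder rec;
  rec.want_trace = dt_out > 0;
  rec.dt_out = dt_out;
  rec.next_out = 0.0;
  rec.t_end_out = duration;
  rec.cai = cai_index(model);
  const double hmax_rec = dt_out > 0 ? dt_out : -1.0;

  if (rec.want_trace) {
    rec.trace.push_back(0.0);
    for (int i = 0; i < ns; ++i) rec.trace.push_back(y[i]);
    rec.trace.push_back(
        stim_start <= 0 && stim_dur > 0 && stim_amp != 0 ? stim_amp : 0.0);
    rec.next_out = dt_out;
  }
  rec.t_acc.push_back(0.0);
  rec.v_acc.push_back(y[0]);
  if (rec.cai >= 0) rec.cai_acc.push_back(y[rec.cai]);

  const double v_rest = y[0];
  SpanResult agg;
  agg.status = 0;
  agg.dvdt_max = R_NegInf;
  agg.t_dvdt_max = 0.0;
  agg.v_max = y[0];
  agg.t_v_max = 0.0;

  bool have_stim = stim_amp != 0.0 && stim_dur > 0 && stim_start < duration &&
                   stim_start + stim_dur > 0;
  std::vector<std::pair<std::pair<double, double>, double> > segs;
  if (have_stim) {
    const double s0 = std::max(0.0, stim_start);
    const double s1 = std::min(duration, stim_start + stim_dur);
    if (s0 > 0) segs.push_back({{0.0, s0}, 0.0});
    segs.push_back({{s0, s1}, stim_amp});
    if (s1 < duration) segs.push_back({{s1, duration}, 0.0});
  } else {
    segs.push_back({{0.0, duration}, 0.0});
  }

  for (size_t k = 0; k < segs.size(); ++k) {
    SpanResult r =
        integrate_span(model, REAL(params), Ko, segs[k].second, y.data(),
                       segs[k].first.first, segs[k].first.second, REAL(acc),
                       hmax_rec, &rec);
    if (r.dvdt_max > agg.dvdt_max) {
      agg.dvdt_max = r.dvdt_max;
      agg.t_dvdt_max = r.t_dvdt_max;
    }
    if (r.v_max > agg.v_max) { agg.v_max = r.v_max; agg.t_v_max = r.t_v_max; }
    if (r.status != 0) { agg.status = r.status; break; }
  }

  const double thr = v_rest + 0.1 * (agg.v_max - v_rest);
  double apd = NA_REAL;
  if (agg.status == 0 && have_stim && agg.v_max > 0) {
    const double c = apd_crossing(rec.t_acc, rec.v_acc, agg.t_v_max, thr);
    if (R_finite(c)) apd = c - agg.t_dvdt_max;
  }

  List out = List::create(
      _["status"] = agg.status, _["state"] = NumericVector(y.begin(), y.end()),
      _["v_peak"] = agg.v_max, _["t_v_peak"] = agg.t_v_max + t_offset,
      _["dvdt_max"] = agg.dvdt_max, _["t_upstroke"] = agg.t_dvdt_max + t_offset,
      _["apd"] = apd, _["v_rest"] = v_rest);
  if (rec.want_trace) {
    const int ncol = ns + 2;
    const int nrow = rec.trace.size() / ncol;
    NumericMatrix tr(nrow, ncol);
    for (int i = 0; i < nrow; ++i)
      for (int jj = 0; jj < ncol; ++jj) tr(i, jj) = rec.trace[i * ncol + jj];
    for (int i = 0; i < nrow; ++i) tr(i, 0) += t_offset;
    out["trace"] = tr;
  } else {
    out["trace"] = R_NilValue;
  }
  return out;
}

// [[Rcpp::export]]
List cm_pace_cpp(int model, NumericVector params, NumericVector state0,
                 double bcl, int n_beats, double stim_amp, double stim_dur,
                 double Ko, double dt_out, int record_from_beat,
                 NumericVector acc, double t_offset) {
  const int ns = model_nstate(model);
  if ((int)state0.size() != ns) stop("state length does not match model");
  if ((int)params.size() != model_npar(model))
    stop("parameter length does not match model");
  if (bcl <= stim_dur || stim_dur <= 0) stop("need bcl > stim_dur > 0");
  if (acc.size() != 4) stop("acc must have length 4");
  std::vector<double> y(state0.begin(), state0.end());
  const int cai = cai_index(model);

  NumericMatrix beats(n_beats, 10);
  colnames(beats) = CharacterVector::create(
      "beat", "t_stim", "v_rest", "v_peak", "dvdt_max", "apd", "captured",
      "cai_dia", "cai_amp", "cai_ttp");
  std::vector<double> trace;
  int status = 0;

  for (int b = 0; b < n_beats; ++b) {
    const double tb = b * bcl;
    const bool record = dt_out > 0 && (b + 1) >= record_from_beat;

    StepRecorder rec;
    rec.want_trace = record;
    rec.dt_out = dt_out;
    rec.next_out = 0.0;
    rec.t_end_out = bcl;
    rec.cai = cai;
    rec.t_acc.push_back(0.0);
    rec.v_acc.push_back(y[0]);
    if (cai >= 0) rec.cai_acc.push_back(y[cai]);
    if (record) {
      rec.trace.push_back(0.0);
      for (int i = 0; i < ns; ++i) rec.trace.push_back(y[i]);
      rec.trace.push_back(stim_amp);
      rec.next_out = dt_out;
    }
    const double hmax_rec = record ? dt_out : -1.0;
    const double v_rest = y[0];
    const double cai_dia = cai >= 0 ? y[cai] : NA_REAL;

    SpanResult r1 = integrate_span(model, REAL(params), Ko, stim_amp, y.data(),
                                   0.0, stim_dur, REAL(acc), hmax_rec, &rec);
    SpanResult r2;
    r2.status = r1.status;
    r2.dvdt_max = R_NegInf;
    r2.v_max = R_NegInf;
    r2.t_dvdt_max = r2.t_v_max = stim_dur;
    if (r1.status == 0)
      r2 = integrate_span(model, REAL(params), Ko, 0.0, y.data(), stim_dur,
                          bcl, REAL(acc), hmax_rec, &rec);
    const double dvdt_max = std::max(r1.dvdt_max, r2.dvdt_max);
    const double t_up = r1.dvdt_max >= r2.dvdt_max ? r1.t_dvdt_max : r2.t_dvdt_max;
    const double v_max = std::max(r1.v_max, r2.v_max);
    const double t_vmax = r1.v_max >= r2.v_max ? r1.t_v_max : r2.t_v_max;

    double apd = NA_REAL, cai_amp = NA_REAL, cai_ttp = NA_REAL;
    const bool captured = v_max > 0.0;
    if (captured) {
      const double thr = v_rest + 0.1 * (v_max - v_rest);
      const double c = apd_crossing(rec.t_acc, rec.v_acc, t_vmax, thr);
      if (R_finite(c)) apd = c - t_up;
      if (cai >= 0) {
        double cmax = R_NegInf, tcmax = NA_REAL;
        for (size_t i = 0; i < rec.cai_acc.size(); ++i) {
          if (rec.cai_acc[i] > cmax) { cmax = rec.cai_acc[i]; tcmax = rec.t_acc[i]; }
        }
        cai_amp = cmax - cai_dia;
        cai_ttp = tcmax;
      }
    }

    beats(b, 0) = b + 1;
    beats(b, 1) = tb + t_offset;
    beats(b, 2) = v_rest;
    beats(b, 3) = v_max;
    beats(b, 4) = dvdt_max;
    beats(b, 5) = apd;
    beats(b, 6) = captured ? 1.0 : 0.0;
    beats(b, 7) = cai_dia;
    beats(b, 8) = cai_amp;
    beats(b, 9) = cai_ttp;

    if (record) {
      const int ncolr = ns + 2;
      const int nrowr = rec.trace.size() / ncolr;
      for (int i = 0; i < nrowr; ++i) {
        trace.push_back(rec.trace[i * ncolr] + tb + t_offset);
        for (int jj = 1; jj < ncolr; ++jj)
          trace.push_back(rec.trace[i * ncolr + jj]);
      }
    }
    if (r2.status != 0) { status = r2.status; break; }
  }

  List out = List::create(_["status"] = status,
                          _["state"] = NumericVector(y.begin(), y.end()),
                          _["beats"] = beats);
  if (dt_out > 0 && !trace.empty()) {
    const int ncolr = ns + 2;
    const int nrowr = trace.size() / ncolr;
    NumericMatrix tr(nrowr, ncolr);
    for (int i = 0; i < nrowr; ++i)
      for (int jj = 0; jj < ncolr; ++jj) tr(i, jj) = trace[i * ncolr + jj];
    out["trace"] = tr;
  } else {
    out["trace"] = R_NilValue;
  }
  return out;
}
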
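// Human ventricular membrane kinetics (ten Tusscher & Panfilov 2006 formulation)
// and the monodomain tissue time loop.
//
// Units: mV, ms, mM; currents in pA/pF (== uA/uF).
// Gates are advanced with the Rush-Larsen exponential update; voltage and
// concentrations with forward Euler. Voltage-dependent rate expressions are
// tabulated on a 0.05 mV grid and linearly interpolated, the standard trick
// of cardiac tissue solvers; tables depend only on dt and the cell variant.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- fixed model constants -------------------------------------------------
static const double Rgas = 8314.472, Temp = 310.0, Frdy = 96485.3415;
static const double RTONF = Rgas * Temp / Frdy;
static const double Ko = 5.4, Cao = 2.0, Nao = 140.0;
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double CAPACITANCE = 0.185;
static const double pKNa = 0.03;
static const double KmK = 1.0, KmNa = 40.0, knak = 2.724;
static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, ncagamma = 0.35,
                    knaca = 1000.0;
static const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
static const double GbNa = 0.00029, GbCa = 0.000592;

static const double inverseVcF2 = 1.0 / (2.0 * Vc * Frdy);
static const double inverseVcF = 1.0 / (Vc * Frdy);
static const double inversevssF2 = 1.0 / (2.0 * Vss * Frdy);

// state vector layout (19 per node)
enum { iV = 0, iCai, iCaSR, iCaSS, iNai, iKi, iM, iH, iJ, iXr1, iXr2, iXs,
       iR, iS, iD, iF, iF2, iFCass, iRR, NSTATE };

// per-region maximal conductances, order matches R side
struct CellPar {
  double GNa, GCaL, GKr, GKs, GK1, Gto;
};

static CellPar parFromVec(const NumericVector& p) {
  CellPar c;
  c.GNa = p[0]; c.GCaL = p[1]; c.GKr = p[2];
  c.GKs = p[3]; c.GK1 = p[4]; c.Gto = p[5];
  return c;
}

// ---- voltage-dependent tables ----------------------------------------------
// the table range comfortably covers the +-200 mV instability guard so a
// diverging trajectory is caught by the guard, not by table overrun
static const double TAB_VMIN = -320.0, TAB_VMAX = 320.0, TAB_STEP = 0.05;
static const int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_STEP) + 2;
// IK1 rectifier is a function of V - EK
static const double K1_UMIN = -450.0, K1_UMAX = 450.0;
static const int K1_N = (int)((K1_UMAX - K1_UMIN) / TAB_STEP) + 2;

struct Tables {
  // Rush-Larsen coefficients per gate: g <- b + a*g
  std::vector<double> ma, mb, ha, hb, ja, jb, xr1a, xr1b, xr2a, xr2b,
      xsa, xsb, ra, rb, sa, sb, da, db, fa, fb, f2a, f2b;
  // current helpers
  std::vector<double> exn, exn1, naki, cale, calp, ipkr;
  std::vector<double> k1rec;
  double dt;
  int variant;
};

static void rl(std::vector<double>& a, std::vector<double>& b, int i,
               double inf, double tau, double dt) {
  double e = std::exp(-dt / tau);
  a[i] = e;
  b[i] = inf * (1.0 - e);
}

static void buildTables(Tables& tb, double dt, int variant) {
  tb.dt = dt; tb.variant = variant;
  std::vector<double>* all[] = { &tb.ma, &tb.mb, &tb.ha, &tb.hb, &tb.ja,
    &tb.jb, &tb.xr1a, &tb.xr1b, &tb.xr2a, &tb.xr2b, &tb.xsa, &tb.xsb,
    &tb.ra, &tb.rb, &tb.sa, &tb.sb, &tb.da, &tb.db, &tb.fa, &tb.fb,
    &tb.f2a, &tb.f2b, &tb.exn, &tb.exn1, &tb.naki, &tb.cale, &tb.calp,
    &tb.ipkr };
  for (auto v : all) v->assign(TAB_N, 0.0);
  tb.k1rec.assign(K1_N, 0.0);

  for (int i = 0; i < TAB_N; ++i) {
    double V = TAB_VMIN + i * TAB_STEP;
    // m
    double minf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
    rl(tb.ma, tb.mb, i, minf, am * bm, dt);
    // h
    double hinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    }
    rl(tb.ha, tb.hb, i, hinf, 1.0 / (ah + bh), dt);
    // j
    double jinf = hinf;
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = ((-2.5428e4 * std::exp(0.2444 * V) -
             6.948e-6 * std::exp(-0.04391 * V)) * (V + 37.78)) /
           (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    rl(tb.ja, tb.jb, i, jinf, 1.0 / (aj + bj), dt);
    // xr1
    double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    rl(tb.xr1a, tb.xr1b, i, xr1inf, axr1 * bxr1, dt);
    // xr2
    double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    rl(tb.xr2a, tb.xr2b, i, xr2inf, axr2 * bxr2, dt);
    // xs
    double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    rl(tb.xsa, tb.xsb, i, xsinf, axs * bxs + 80.0, dt);
    // r
    double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    double taur = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    rl(tb.ra, tb.rb, i, rinf, taur, dt);
    // s (variant dependent: 0 epi, 1 endo, 2 mid)
    double sinf, taus;
    if (variant == 1) {
      sinf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
      taus = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
    } else {
      sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      taus = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
             5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    }
    rl(tb.sa, tb.sb, i, sinf, taus, dt);
    // d
    double dinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    rl(tb.da, tb.db, i, dinf, ad * bd + gd, dt);
    // f
    double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    double tauf = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                  200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                  180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    rl(tb.fa, tb.fb, i, finf, tauf, dt);
    // f2
    double f2inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    double tauf2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                   31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                   80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    rl(tb.f2a, tb.f2b, i, f2inf, tauf2, dt);
    // current helpers
    tb.exn[i] = std::exp(ncagamma * V / RTONF);
    tb.exn1[i] = std::exp((ncagamma - 1.0) * V / RTONF);
    tb.naki[i] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
                        0.0353 * std::exp(-V / RTONF));
    double u = 2.0 * (V - 15.0) / RTONF;
    if (std::fabs(u) < 1e-6) {
      tb.cale[i] = 1.0 + u;
      tb.calp[i] = 2.0 * Frdy;  // limit of 4(V-15)F^2/RT / (e^u - 1)
    } else {
      tb.cale[i] = std::exp(u);
      tb.calp[i] = 4.0 * (V - 15.0) * (Frdy * Frdy / (Rgas * Temp)) /
                   (tb.cale[i] - 1.0);
    }
    tb.ipkr[i] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
  }
  for (int i = 0; i < K1_N; ++i) {
    double u = K1_UMIN + i * TAB_STEP;  // V - EK
    double ak1 = 0.1 / (1.0 + std::exp(0.06 * (u - 200.0)));
    double bk1 = (3.0 * std::exp(0.0002 * (u + 100.0)) +
                  std::exp(0.1 * (u - 10.0))) /
                 (1.0 + std::exp(-0.5 * u));
    tb.k1rec[i] = ak1 / (ak1 + bk1);
  }
}

static inline double lin(const std::vector<double>& t, double x, double xmin) {
  double s = (x - xmin) / TAB_STEP;
  if (s < 0.0) s = 0.0;
  double smax = (double)(t.size() - 2);
  if (s > smax) s = smax;
  int i = (int)s;
  double w = s - i;
  return t[i] * (1.0 - w) + t[i + 1] * w;
}

// published steady state of the paced epicardial variant
// [[Rcpp::export(name = ".tp06_initial_state")]]
NumericVector tp06InitialState() {
  NumericVector s(NSTATE);
  s[iV] = -85.23; s[iCai] = 0.000126; s[iCaSR] = 3.64; s[iCaSS] = 0.00036;
  s[iNai] = 8.604; s[iKi] = 136.89;
  s[iM] = 0.00172; s[iH] = 0.7444; s[iJ] = 0.7045;
  s[iXr1] = 0.00621; s[iXr2] = 0.4712; s[iXs] = 0.0095;
  s[iR] = 2.42e-8; s[iS] = 0.999998;
  s[iD] = 3.373e-5; s[iF] = 0.7888; s[iF2] = 0.9755; s[iFCass] = 0.9953;
  s[iRR] = 0.9073;
  return s;
}

// one forward step for a single node; istim > 0 depolarizes
static inline void stepNode(double* s, const CellPar& cp, const Tables& tb,
                            double dt, double istim) {
  double V = s[iV];
  double Cai = s[iCai], CaSR = s[iCaSR], CaSS = s[iCaSS];
  double Nai = s[iNai], Ki = s[iKi];

  double Ek = RTONF * std::log(Ko / Ki);
  double Ena = RTONF * std::log(Nao / Nai);
  double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  double INa = cp.GNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - Ena);
  double cale = lin(tb.cale, V, TAB_VMIN);
  double ICaL = cp.GCaL * s[iD] * s[iF] * s[iF2] * s[iFCass] *
                lin(tb.calp, V, TAB_VMIN) * (0.25 * cale * CaSS - Cao);
  double Ito = cp.Gto * s[iR] * s[iS] * (V - Ek);
  double IKr = cp.GKr * std::sqrt(Ko / 5.4) * s[iXr1] * s[iXr2] * (V - Ek);
  double IKs = cp.GKs * s[iXs] * s[iXs] * (V - Eks);
  double IK1 = cp.GK1 * lin(tb.k1rec, V - Ek, K1_UMIN) * (V - Ek);
  double INaCa = knaca *
      (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
      (1.0 / (KmCa + Cao)) *
      (1.0 / (1.0 + ksat * lin(tb.exn1, V, TAB_VMIN))) *
      (lin(tb.exn, V, TAB_VMIN) * Nai * Nai * Nai * Cao -
       lin(tb.exn1, V, TAB_VMIN) * Nao * Nao * Nao * Cai * 2.5);
  double INaK = knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) *
                lin(tb.naki, V, TAB_VMIN);
  double IpCa = GpCa * Cai / (KpCa + Cai);
  double IpK = GpK * lin(tb.ipkr, V, TAB_VMIN) * (V - Ek);
  double IbNa = GbNa * (V - Ena);
  double IbCa = GbCa * (V - Eca);

  double Itot = IKr + IKs + IK1 + Ito + INa + IbNa + ICaL + IbCa + INaK +
                INaCa + IpCa + IpK - istim;

  // calcium subsystem
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  double k1 = k1p / kCaSR;
  double k2 = k2p * kCaSR;
  double dRR = k4 * (1.0 - s[iRR]) - k2 * CaSS * s[iRR];
  s[iRR] += dt * dRR;
  double sOO = k1 * CaSS * CaSS * s[iRR] / (k3 + k1 * CaSS * CaSS);
  double Irel = Vrel * sOO * (CaSR - CaSS);
  double Ileak = Vleak * (CaSR - Cai);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double Ixfer = Vxfer * (CaSS - Cai);

  double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
  double dCaSR = dt * (Iup - Irel - Ileak);
  double bjsr = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
  double cjsr = Kbufsr * (CaCSQN + dCaSR + CaSR);
  s[iCaSR] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

  double CaSSBuf = Bufss * CaSS / (CaSS + Kbufss);
  double dCaSS = dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
                       (-ICaL * inversevssF2 * CAPACITANCE));
  double bcss = Bufss - CaSSBuf - dCaSS - CaSS + Kbufss;
  double ccss = Kbufss * (CaSSBuf + dCaSS + CaSS);
  s[iCaSS] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

  double CaBuf = Bufc * Cai / (Cai + Kbufc);
  double dCai = dt * ((-(IbCa + IpCa - 2.0 * INaCa) * inverseVcF2 *
                       CAPACITANCE) -
                      (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  double bc = Bufc - CaBuf - dCai - Cai + Kbufc;
  double cc = Kbufc * (CaBuf + dCai + Cai);
  s[iCai] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  s[iNai] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * inverseVcF *
                   CAPACITANCE);
  s[iKi] += dt * (-(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK - istim) *
                  inverseVcF * CAPACITANCE);

  // gates, Rush-Larsen via tables
  s[iM] = lin(tb.mb, V, TAB_VMIN) + lin(tb.ma, V, TAB_VMIN) * s[iM];
  s[iH] = lin(tb.hb, V, TAB_VMIN) + lin(tb.ha, V, TAB_VMIN) * s[iH];
  s[iJ] = lin(tb.jb, V, TAB_VMIN) + lin(tb.ja, V, TAB_VMIN) * s[iJ];
  s[iXr1] = lin(tb.xr1b, V, TAB_VMIN) + lin(tb.xr1a, V, TAB_VMIN) * s[iXr1];
  s[iXr2] = lin(tb.xr2b, V, TAB_VMIN) + lin(tb.xr2a, V, TAB_VMIN) * s[iXr2];
  s[iXs] = lin(tb.xsb, V, TAB_VMIN) + lin(tb.xsa, V, TAB_VMIN) * s[iXs];
  s[iR] = lin(tb.rb, V, TAB_VMIN) + lin(tb.ra, V, TAB_VMIN) * s[iR];
  s[iS] = lin(tb.sb, V, TAB_VMIN) + lin(tb.sa, V, TAB_VMIN) * s[iS];
  s[iD] = lin(tb.db, V, TAB_VMIN) + lin(tb.da, V, TAB_VMIN) * s[iD];
  s[iF] = lin(tb.fb, V, TAB_VMIN) + lin(tb.fa, V, TAB_VMIN) * s[iF];
  s[iF2] = lin(tb.f2b, V, TAB_VMIN) + lin(tb.f2a, V, TAB_VMIN) * s[iF2];
  // fCass depends on CaSS, computed directly (rational + one exp)
  double fci = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
  double tfc = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;
  double efc = std::exp(-dt / tfc);
  s[iFCass] = fci + (s[iFCass] - fci) * efc;

  s[iV] = V - dt * Itot;
}

// ---- single cell drivers ---------------------------------------------------

// Advance a single cell n steps under constant stimulus current.
// [[Rcpp::export(name = ".cell_steps")]]
NumericVector cellSteps(NumericVector state, NumericVector params, int variant,
                        double dt, int nSteps, double istim) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  Tables tb;
  buildTables(tb, dt, variant);
  CellPar cp = parFromVec(params);
  NumericVector out = clone(state);
  double* s = REAL(out);
  for (int k = 0; k < nSteps; ++k) {
    stepNode(s, cp, tb, dt, istim);
    if (!std::isfinite(s[iV]))
      stop("non-finite membrane potential at step %d", k + 1);
  }
  return out;
}

// Paced single-cell train; returns sampled Vm trace and final state.
// [[Rcpp::export(name = ".cell_train")]]
List cellTrain(NumericVector state, NumericVector params, int variant,
               double dt, double cl, int nBeats, double stimAmp,
               double stimDur, double sampleDt, double tailMs) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  Tables tb;
  buildTables(tb, dt, variant);
  CellPar cp = parFromVec(params);
  NumericVector st = clone(state);
  double* s = REAL(st);
  double duration = cl * nBeats + tailMs;
  int nSteps = (int)std::ceil(duration / dt);
  int every = std::max(1, (int)std::floor(sampleDt / dt + 0.5));
  int nOut = nSteps / every + 1;
  NumericVector tOut(nOut), vOut(nOut);
  int m = 0;
  tOut[m] = 0.0; vOut[m] = s[iV]; ++m;
  for (int k = 0; k < nSteps; ++k) {
    double t = k * dt;
    int beat = (int)(t / cl);
    double phase = t - beat * cl;
    double istim = (beat < nBeats && phase < stimDur) ? stimAmp : 0.0;
    stepNode(s, cp, tb, dt, istim);
    if (!std::isfinite(s[iV]))
      stop("non-finite membrane potential at t=%.3f ms", t);
    if ((k + 1) % every == 0 && m < nOut) {
      tOut[m] = (k + 1) * dt;
      vOut[m] = s[iV];
      ++m;
    }
  }
  return List::create(_["time"] = tOut[Range(0, m - 1)],
                      _["vm"] = vOut[Range(0, m - 1)],
                      _["state"] = st);
}

// ---- monodomain tissue loop ------------------------------------------------

// Operator A is the dt-scaled lumped-mass diffusion update in CSC form:
// V <- V + A V performs one explicit diffusion step.
// labels: 0 NORMAL, 1 GZ, 2 excluded (scar interior); excluded nodes hold rest.
// stimOnset/stimDur/stimAmp parallel stimNodes (1-based node index vectors).
// [[Rcpp::export(name = ".monodomain_run")]]
List monodomainRun(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                   int nSub,
                   NumericMatrix state0, IntegerVector labels,
                   NumericVector parNormal, NumericVector parGZ, int variant,
                   List stimNodes, NumericVector stimOnset,
                   NumericVector stimDur, NumericVector stimAmp,
                   double dt, double t0, double duration,
                   double outputInterval, double actThreshold,
                   double lockout, bool freezeIonic) {
  const int N = state0.ncol();
  if (state0.nrow() != NSTATE) stop("state matrix must be %d x N", NSTATE);
  if (labels.size() != N) stop("labels length mismatch");
  Tables tb;
  buildTables(tb, dt, variant);
  CellPar cpN = parFromVec(parNormal);
  CellPar cpG = parFromVec(parGZ);

  NumericMatrix state = clone(state0);
  double* S = REAL(state);

  std::vector<double> v(N), dv(N), ist(N, 0.0);
  for (int i = 0; i < N; ++i) v[i] = S[(size_t)i * NSTATE + iV];

  const int nStim = stimNodes.size();
  std::vector<std::vector<int>> stimIdx(nStim);
  for (int q = 0; q < nStim; ++q) {
    IntegerVector nd = stimNodes[q];
    stimIdx[q].assign(nd.begin(), nd.end());
    for (auto& z : stimIdx[q]) --z;  // to 0-based
  }

  int nSteps = (int)std::ceil(duration / dt - 1e-9);
  bool haveFrames = R_finite(outputInterval) && outputInterval > 0;
  int every = haveFrames
                  ? std::max(1, (int)std::floor(outputInterval / dt + 0.5))
                  : 0;
  int nFrames = haveFrames ? nSteps / every + 1 : 0;
  NumericMatrix frames(haveFrames ? N : 0, nFrames);
  NumericVector frameTimes(nFrames);
  int fm = 0;
  if (haveFrames) {
    for (int i = 0; i < N; ++i) frames(i, 0) = v[i];
    frameTimes[0] = t0;
    fm = 1;
  }

  std::vector<std::vector<double>> act(N);
  std::vector<double> lastAct(N, -1e30);

  std::vector<double> vPrev(N);
  for (int k = 0; k < nSteps; ++k) {
    double t = t0 + k * dt;
    vPrev = v;
    // diffusion: v <- (I + A)^nSub v (CSC scatter); the operator is
    // prescaled so nSub substeps make up one dt
    for (int sub = 0; sub < nSub; ++sub) {
      std::fill(dv.begin(), dv.end(), 0.0);
      for (int col = 0; col < N; ++col) {
        double vc = v[col];
        if (vc == 0.0) continue;
        for (int p = Ap[col]; p < Ap[col + 1]; ++p) dv[Ai[p]] += Ax[p] * vc;
      }
      if (sub < nSub - 1)
        for (int i = 0; i < N; ++i)
          if (labels[i] != 2) v[i] += dv[i];
    }

    // stimulus currents
    bool anyStim = false;
    for (int q = 0; q < nStim; ++q) {
      if (t >= stimOnset[q] - 1e-9 && t < stimOnset[q] + stimDur[q] - 1e-9) {
        if (!anyStim) { std::fill(ist.begin(), ist.end(), 0.0); anyStim = true; }
        for (int idx : stimIdx[q]) ist[idx] += stimAmp[q];
      }
    }

    double tNext = t + dt;
    for (int i = 0; i < N; ++i) {
      if (labels[i] == 2) continue;
      double* s = S + (size_t)i * NSTATE;
      s[iV] = v[i] + dv[i];
      double istim = anyStim ? ist[i] : 0.0;
      if (freezeIonic) {
        s[iV] += dt * istim;
      } else {
        stepNode(s, labels[i] == 1 ? cpG : cpN, tb, dt, istim);
      }
      double vn = s[iV];
      if (!std::isfinite(vn) || std::fabs(vn) > 200.0)
        stop("monodomain instability: |Vm| > 200 mV at t=%.3f ms, node %d",
             tNext, i + 1);
      if (vPrev[i] < actThreshold && vn >= actThreshold &&
          tNext - lastAct[i] >= lockout) {
        act[i].push_back(tNext);
        lastAct[i] = tNext;
      }
      v[i] = vn;
    }
    if (haveFrames && (k + 1) % every == 0 && fm < nFrames) {
      for (int i = 0; i < N; ++i) frames(i, fm) = v[i];
      frameTimes[fm] = t0 + (k + 1) * dt;
      ++fm;
    }
  }

  List actOut(N);
  for (int i = 0; i < N; ++i) actOut[i] = NumericVector(act[i].begin(),
                                                        act[i].end());
  if (haveFrames && fm < nFrames) {
    frames = frames(_, Range(0, fm - 1));
    frameTimes = frameTimes[Range(0, fm - 1)];
  }
  return List::create(_["frames"] = frames, _["frameTimes"] = frameTimes,
                      _["activations"] = actOut, _["state"] = state,
                      _["tEnd"] = t0 + nSteps * dt);
}
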
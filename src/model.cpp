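// Reduced paced ventricular cardiomyocyte model with nine scalable current
// magnitudes (fast/late Na, L-type Ca, transient outward, rapid/slow delayed
// rectifier, inward rectifier, Na/Ca exchange, Na/K pump).  Gating variables
// advance by the Rush-Larsen exponential update; membrane potential and
// intracellular calcium by forward Euler.  Voltage-dependent rate quantities
// are tabulated on a fixed voltage grid (rebuilt when the solver step
// changes) so that a 1000 ms beat at dt = 0.01 ms stays in the millisecond
// range.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- fixed ionic environment -------------------------------------------
static const double RTF   = 26.712;          // mV at 310 K
static const double Nai   = 10.0,  Nao = 140.0;
static const double Ki    = 145.0, Ko  = 5.4;
static const double Cao   = 1.8;
static const double ENa   = RTF * std::log(Nao / Nai);        //  70.5 mV
static const double EK    = RTF * std::log(Ko  / Ki);         // -87.9 mV
static const double EKs   = RTF * std::log((Ko + 0.03 * Nao) / (Ki + 0.03 * Nai));

// baseline current magnitudes (mS/uF resp. uA/uF scale constants); the nine
// user-facing scale factors multiply these.  Values tuned so the baseline
// beat satisfies the experimental biomarker ranges and strong IKr block with
// enhanced ICaL produces early afterdepolarizations.
static const double GNA_B   = 9.6;
static const double GNAL_B  = 0.0055;
static const double PCA_B   = 0.0815;
static const double GTO_B   = 0.14;
static const double GKR_B   = 0.588;
static const double GKS_B   = 0.055;
static const double GK1_B   = 0.6047;
static const double KNCX_B  = 262.5;
static const double PNAK_B  = 2.30;
static const double GKP    = 0.0183;         // fixed plateau K background

// state layout: V, m, h, j, d, f, x, xs, r, q, hL, Cai
#define NSTATE 12

// ---- rate helpers -------------------------------------------------------
static inline double safe_div(double num, double den, double lim) {
  return std::fabs(den) < 1e-9 ? lim : num / den;
}

struct Rates {
  // per-gate steady state and Rush-Larsen decay factor exp(-dt*(a+b))
  double minf, mrl, hinf, hrl, jinf, jrl, dinf, drl, finf, frl;
  double xinf, xrl, xsinf, xsrl, rinf, rrl, qinf, qrl, hLinf, hLrl;
  double Xi, K1inf, Kp, fNaK, ncx_out, ncx_in; // voltage-only current factors
};

static void fill_rates(double V, double dt, Rates &r) {
  // fast Na (m, h, j)
  double am = safe_div(0.32 * (V + 47.13), 1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V < -40.0) {
    ah = 0.135 * std::exp(-(80.0 + V) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  // L-type Ca (d, f)
  double ad = 0.095 * std::exp(-0.01 * (V - 5.0)) / (1.0 + std::exp(-0.072 * (V - 5.0)));
  double bd = 0.07 * std::exp(-0.017 * (V + 44.0)) / (1.0 + std::exp(0.05 * (V + 44.0)));
  double af = 0.012 * std::exp(-0.008 * (V + 28.0)) / (1.0 + std::exp(0.15 * (V + 28.0)));
  double bf = 0.0065 * std::exp(-0.02 * (V + 30.0)) / (1.0 + std::exp(-0.2 * (V + 30.0)));
  // rapid delayed rectifier activation (x) with inward rectification Xi
  double ax = 0.0005 * std::exp(0.083 * (V + 50.0)) / (1.0 + std::exp(0.057 * (V + 50.0)));
  double bx = 0.0013 * std::exp(-0.06 * (V + 20.0)) / (1.0 + std::exp(-0.04 * (V + 20.0)));
  // slow delayed rectifier activation (xs), tau in ms
  double xsinf = 1.0 / (1.0 + std::exp(-(V - 5.0) / 14.0));
  double txs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0)) /
               (1.0 + std::exp((V - 35.0) / 15.0)) + 80.0;
  // transient outward activation r / inactivation q
  double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  double tr   = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  double qinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  double tq   = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
                5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  // late Na inactivation
  double hLinf = 1.0 / (1.0 + std::exp((V + 91.0) / 6.1));
  double thL = 200.0;

  r.minf = am / (am + bm);   r.mrl = std::exp(-dt * (am + bm));
  r.hinf = ah / (ah + bh);   r.hrl = std::exp(-dt * (ah + bh));
  r.jinf = aj / (aj + bj);   r.jrl = std::exp(-dt * (aj + bj));
  r.dinf = ad / (ad + bd);   r.drl = std::exp(-dt * (ad + bd));
  r.finf = af / (af + bf);   r.frl = std::exp(-dt * (af + bf));
  r.xinf = ax / (ax + bx);   r.xrl = std::exp(-dt * (ax + bx));
  r.xsinf = xsinf;           r.xsrl = std::exp(-dt / txs);
  r.rinf = rinf;             r.rrl = std::exp(-dt / tr);
  r.qinf = qinf;             r.qrl = std::exp(-dt / tq);
  r.hLinf = hLinf;           r.hLrl = std::exp(-dt / thL);

  r.Xi = (V > -100.0)
    ? safe_div(2.837 * (std::exp(0.04 * (V + 77.0)) - 1.0),
               (V + 77.0) * std::exp(0.04 * (V + 35.0)),
               2.837 * 0.04 / std::exp(0.04 * (-77.0 + 35.0)))
    : 1.0;
  double aK1 = 1.02 / (1.0 + std::exp(0.2385 * (V - EK - 59.215)));
  double bK1 = (0.49124 * std::exp(0.08032 * (V - EK + 5.476)) +
                std::exp(0.06175 * (V - EK - 594.31))) /
               (1.0 + std::exp(-0.5143 * (V - EK + 4.753)));
  r.K1inf = aK1 / (aK1 + bK1);
  r.Kp = 1.0 / (1.0 + std::exp((7.488 - V) / 5.98));
  double vf = V / RTF;
  r.fNaK = (Ko / (Ko + 1.0)) * (Nai / (Nai + 40.0)) /
           (1.0 + 0.1245 * std::exp(-0.1 * vf) + 0.0353 * std::exp(-vf));
  // Na/Ca exchange split into the Cai-independent outward part and the
  // coefficient of Cai for the inward part (both per unit kNCX scale)
  double den = (87.5 * 87.5 * 87.5 + Nao * Nao * Nao) * (1.38 + Cao) *
               (1.0 + 0.1 * std::exp(-0.65 * vf));
  r.ncx_out = std::exp(0.35 * vf) * Nai * Nai * Nai * Cao / den;
  r.ncx_in  = std::exp(-0.65 * vf) * Nao * Nao * Nao * 2.5 / den;
}

// ---- voltage lookup table ----------------------------------------------
static const double VMIN = -150.0, VMAX = 90.0, VSTEP = 0.05;
static const int NTAB = (int)((VMAX - VMIN) / VSTEP) + 1;
static std::vector<Rates> g_tab;
static double g_tab_dt = -1.0;

static void ensure_table(double dt) {
  if (g_tab_dt == dt && (int)g_tab.size() == NTAB) return;
  g_tab.assign(NTAB, Rates());
  for (int i = 0; i < NTAB; ++i) fill_rates(VMIN + i * VSTEP, dt, g_tab[i]);
  g_tab_dt = dt;
}

static inline void lookup(double V, Rates &out) {
  double p = (V - VMIN) / VSTEP;
  if (p < 0.0) p = 0.0;
  if (p > NTAB - 1.001) p = NTAB - 1.001;
  int i = (int)p;
  double w = p - i;
  const Rates &a = g_tab[i], &b = g_tab[i + 1];
  const double *pa = (const double *)&a, *pb = (const double *)&b;
  double *po = (double *)&out;
  for (size_t k = 0; k < sizeof(Rates) / sizeof(double); ++k)
    po[k] = pa[k] + w * (pb[k] - pa[k]);
}

// [[Rcpp::export(name = ".cpp_run_beats")]]
List cpp_run_beats(NumericVector state0, NumericVector cond,
                   double cycle_length, double stim_duration,
                   double stim_amplitude, int n_beats,
                   double dt, double dt_sample, double ss_tol,
                   bool early_stop) {
  if (state0.size() != NSTATE) stop("state must have %d entries", NSTATE);
  if (cond.size() != 9) stop("conductance vector must have 9 entries");
  ensure_table(dt);

  const double gNa  = GNA_B  * cond[0], gNaL = GNAL_B * cond[1];
  const double pCa  = PCA_B  * cond[2], gto  = GTO_B  * cond[3];
  const double gKr  = GKR_B  * cond[4], gKs  = GKS_B  * cond[5];
  const double gK1  = GK1_B  * cond[6], kNCX = KNCX_B * cond[7];
  const double pNaK = PNAK_B * cond[8];

  double y[NSTATE], yprev[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = state0[i];

  const int steps_per_beat = (int)std::lround(cycle_length / dt);
  const int sample_every = (int)std::lround(dt_sample / dt);
  const int n_samp = steps_per_beat / sample_every + 1;
  NumericVector times(n_samp), vm(n_samp);
  NumericVector deltas(n_beats);
  Rates rt;
  int beats_run = 0;

  for (int beat = 0; beat < n_beats; ++beat) {
    for (int i = 0; i < NSTATE; ++i) yprev[i] = y[i];
    int isamp = 0;
    for (int s = 0; s <= steps_per_beat; ++s) {
      double t = s * dt;
      double V = y[0], Cai = y[11];
      if (s % sample_every == 0) {   // rewritten every beat; last beat survives
        times[isamp] = t; vm[isamp] = V; ++isamp;
      }
      if (s == steps_per_beat) break;
      lookup(V, rt);
      double Esi = 7.7 - 13.0287 * std::log(Cai);
      double m = y[1], h = y[2], j = y[3], d = y[4], f = y[5];
      double x = y[6], xs = y[7], rr = y[8], q = y[9], hL = y[10];
      double INa  = gNa  * m * m * m * h * j * (V - ENa);
      double INaL = gNaL * m * m * m * hL * (V - ENa);
      double ICaL = pCa  * d * f * (V - Esi);
      double Ito  = gto  * rr * q * (V - EK);
      double IKr  = gKr  * x * rt.Xi * (V - EK);
      double IKs  = gKs  * xs * xs * (V - EKs);
      double IK1  = gK1  * rt.K1inf * (V - EK);
      double IKp  = GKP  * rt.Kp * (V - EK);
      double INaCa = kNCX * (rt.ncx_out - rt.ncx_in * Cai);
      double INaK  = pNaK * rt.fNaK;
      double Istim = (t < stim_duration) ? -stim_amplitude : 0.0;
      double Iion = INa + INaL + ICaL + Ito + IKr + IKs + IK1 + IKp + INaCa + INaK;
      double Vn = V - dt * (Iion + Istim);
      if (!std::isfinite(Vn)) {
        return List::create(_["ok"] = false, _["fail_time"] = t,
                            _["fail_beat"] = beat + 1,
                            _["message"] = "non-finite membrane potential");
      }
      y[0]  = Vn;
      y[1]  = rt.minf + (m - rt.minf) * rt.mrl;
      y[2]  = rt.hinf + (h - rt.hinf) * rt.hrl;
      y[3]  = rt.jinf + (j - rt.jinf) * rt.jrl;
      y[4]  = rt.dinf + (d - rt.dinf) * rt.drl;
      y[5]  = rt.finf + (f - rt.finf) * rt.frl;
      y[6]  = rt.xinf + (x - rt.xinf) * rt.xrl;
      y[7]  = rt.xsinf + (xs - rt.xsinf) * rt.xsrl;
      y[8]  = rt.rinf + (rr - rt.rinf) * rt.rrl;
      y[9]  = rt.qinf + (q - rt.qinf) * rt.qrl;
      y[10] = rt.hLinf + (hL - rt.hLinf) * rt.hLrl;
      double dCai = -1e-4 * ICaL + 0.07 * (1e-4 - Cai);
      y[11] = Cai + dt * dCai;
      if (y[11] < 1e-7) y[11] = 1e-7;
    }
    double delta = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      double rel = std::fabs(y[i] - yprev[i]) / std::max(std::fabs(yprev[i]), 1e-6);
      if (rel > delta) delta = rel;
    }
    deltas[beat] = delta;
    beats_run = beat + 1;
    if (early_stop && delta < ss_tol) break;
  }

  NumericVector state_out(NSTATE);
  for (int i = 0; i < NSTATE; ++i) state_out[i] = y[i];
  return List::create(_["ok"] = true, _["times"] = times, _["vm"] = vm,
                      _["state"] = state_out,
                      _["beats_run"] = beats_run,
                      _["deltas"] = deltas[Rcpp::Range(0, beats_run - 1)]);
}
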
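// Fixed-step exponential-Euler integrator for the two-compartment
// soma/AIS model.  Works internally in deviations from rest (mV) with
// the unit system mV / ms / uS / nF / nA, so R*C is in ms and g*V in nA.
//
// Spike-generating currents live in compartment 2 (AIS): m^3 h sodium and
// n^2 high-threshold potassium with Rothman-Manis-style rate functions,
// temperature-scaled by dividing time constants by `q`.  Gate steady states
// and per-step decay factors are tabulated over voltage once per call.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double m_inf(double V) { return sig((V + 38.0) / 7.0); }
static inline double tau_m(double V, double q) {
  return (10.0 / (5.0 * std::exp((V + 60.0) / 18.0) +
                  36.0 * std::exp(-(V + 60.0) / 25.0)) + 0.04) / q;
}
static inline double h_inf(double V) { return sig(-(V + 65.0) / 6.0); }
static inline double tau_h(double V, double q) {
  return (100.0 / (7.0 * std::exp((V + 60.0) / 11.0) +
                   10.0 * std::exp(-(V + 60.0) / 25.0)) + 0.6) / q;
}
static inline double n_inf(double V) {
  return std::pow(1.0 + std::exp(-(V + 15.0) / 5.0), -0.5);
}
static inline double tau_n(double V, double q) {
  return (100.0 / (11.0 * std::exp((V + 60.0) / 24.0) +
                   21.0 * std::exp(-(V + 60.0) / 23.0)) + 0.7) / q;
}

struct GateTables {
  double vmin, vmax, dv;
  int n;
  std::vector<double> minf, hinf, ninf, fm, fh, fn;

  GateTables(double dt, double q) : vmin(-150.0), vmax(100.0), dv(0.05) {
    n = (int)std::floor((vmax - vmin) / dv) + 1;
    minf.resize(n); hinf.resize(n); ninf.resize(n);
    fm.resize(n); fh.resize(n); fn.resize(n);
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      minf[i] = m_inf(V); hinf[i] = h_inf(V); ninf[i] = n_inf(V);
      fm[i] = std::exp(-dt / tau_m(V, q));
      fh[i] = std::exp(-dt / tau_h(V, q));
      fn[i] = std::exp(-dt / tau_n(V, q));
    }
  }

  inline void lookup(double V, double &mi, double &hi, double &ni,
                     double &em, double &eh, double &en) const {
    double x = (V - vmin) / dv;
    if (x < 0.0) x = 0.0;
    if (x > n - 1.001) x = n - 1.001;
    int i = (int)x;
    double w = x - i;
    mi = minf[i] + w * (minf[i + 1] - minf[i]);
    hi = hinf[i] + w * (hinf[i + 1] - hinf[i]);
    ni = ninf[i] + w * (ninf[i + 1] - ninf[i]);
    em = fm[i] + w * (fm[i + 1] - fm[i]);
    eh = fh[i] + w * (fh[i + 1] - fh[i]);
    en = fn[i] + w * (fn[i + 1] - fn[i]);
  }
};

//' @noRd
// [[Rcpp::export]]
List cpp_run_batch(double g1, double g2, double gax, double c1, double c2,
                   double gNa, double gKHT, double E_Na, double E_K,
                   double q, double E_rest, double dt, int n_steps,
                   double v_thresh_rel,
                   NumericVector chan_on, NumericVector chan_tr,
                   NumericVector chan_td, NumericVector chan_Erel,
                   IntegerVector chan_comp, NumericMatrix amps,
                   bool record) {
  const int K = chan_on.size();
  const int n_combos = amps.nrow();
  if (amps.ncol() != K) stop("amps must have one column per synaptic channel");

  GateTables tab(dt, q);

  const double ENa_rel = E_Na - E_rest;
  const double EK_rel = E_K - E_rest;

  // gates at rest and the compensation current that pins U = 0 at rest
  const double m0 = m_inf(E_rest), h0 = h_inf(E_rest), n0 = n_inf(E_rest);
  const double I0 = gNa * m0 * m0 * m0 * h0 * (0.0 - ENa_rel) +
                    gKHT * n0 * n0 * (0.0 - EK_rel);

  std::vector<double> fd(K), fr(K);
  for (int k = 0; k < K; ++k) {
    fd[k] = std::exp(-dt / chan_td[k]);
    fr[k] = std::exp(-dt / chan_tr[k]);
  }

  LogicalVector spike(n_combos);
  NumericVector max1(n_combos), min1(n_combos), max2(n_combos),
      min2(n_combos), t_spike(n_combos);
  LogicalVector unstable(n_combos);
  NumericVector V1out, V2out;
  if (record) {
    if (n_combos != 1) stop("record = TRUE requires a single combination");
    V1out = NumericVector(n_steps + 1);
    V2out = NumericVector(n_steps + 1);
  }

  std::vector<double> D(K), R(K);
  std::vector<bool> started(K);

  for (int c = 0; c < n_combos; ++c) {
    double U1 = 0.0, U2 = 0.0, m = m0, h = h0, nn = n0;
    double mx1 = 0.0, mn1 = 0.0, mx2 = 0.0, mn2 = 0.0;
    bool sp = false, bad = false;
    double tsp = NA_REAL;
    for (int k = 0; k < K; ++k) { D[k] = R[k] = 0.0; started[k] = false; }
    if (record) { V1out[0] = 0.0; V2out[0] = 0.0; }

    for (int i = 0; i < n_steps; ++i) {
      double t = i * dt;

      double gs1 = 0.0, ge1 = 0.0, gs2 = 0.0, ge2 = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = amps(c, k);
        if (a == 0.0) continue;
        if (!started[k]) {
          if (t + 1e-12 >= chan_on[k]) {
            double el = t - chan_on[k];
            D[k] = std::exp(-el / chan_td[k]);
            R[k] = std::exp(-el / chan_tr[k]);
            started[k] = true;
          } else {
            continue;
          }
        }
        double g = a * (D[k] - R[k]);
        if (chan_comp[k] == 1) { gs1 += g; ge1 += g * chan_Erel[k]; }
        else                   { gs2 += g; ge2 += g * chan_Erel[k]; }
        D[k] *= fd[k];
        R[k] *= fr[k];
      }

      double gNa_eff = gNa * m * m * m * h;
      double gK_eff = gKHT * nn * nn;

      double a1 = (g1 + gax + gs1) / c1;
      double b1 = (gax * U2 + ge1) / c1;
      double a2 = (g2 + gax + gNa_eff + gK_eff + gs2) / c2;
      double b2 = (gax * U1 + gNa_eff * ENa_rel + gK_eff * EK_rel +
                   ge2 + I0) / c2;

      double e1 = std::exp(-a1 * dt);
      double e2 = std::exp(-a2 * dt);
      double U1n = U1 * e1 + (b1 / a1) * (1.0 - e1);
      double U2n = U2 * e2 + (b2 / a2) * (1.0 - e2);

      if (!sp && U2 < v_thresh_rel && U2n >= v_thresh_rel) {
        sp = true;
        tsp = t + dt;
      }
      U1 = U1n; U2 = U2n;

      double mi, hi, ni, em, eh, en;
      tab.lookup(U2 + E_rest, mi, hi, ni, em, eh, en);
      m = mi + (m - mi) * em;
      h = hi + (h - hi) * eh;
      nn = ni + (nn - ni) * en;

      if (U1 > mx1) mx1 = U1;
      if (U1 < mn1) mn1 = U1;
      if (U2 > mx2) mx2 = U2;
      if (U2 < mn2) mn2 = U2;
      if (record) { V1out[i + 1] = U1; V2out[i + 1] = U2; }

      if (std::fabs(U1) > 200.0 || std::fabs(U2) > 200.0) { bad = true; break; }
    }

    spike[c] = sp; unstable[c] = bad;
    max1[c] = mx1; min1[c] = mn1; max2[c] = mx2; min2[c] = mn2;
    t_spike[c] = tsp;
  }

  List out = List::create(
      _["spike"] = spike, _["max1"] = max1, _["min1"] = min1,
      _["max2"] = max2, _["min2"] = min2, _["t_spike"] = t_spike,
      _["unstable"] = unstable);
  if (record) {
    out["U1"] = V1out;
    out["U2"] = V2out;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_gate_rest(double E_rest, double q) {
  return List::create(_["m"] = m_inf(E_rest), _["h"] = h_inf(E_rest),
                      _["n"] = n_inf(E_rest),
                      _["tau_m"] = tau_m(E_rest, q),
                      _["tau_h"] = tau_h(E_rest, q),
                      _["tau_n"] = tau_n(E_rest, q));
}
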
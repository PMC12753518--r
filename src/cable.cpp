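// Implicit (backward Euler) integrator for the multi-compartment cable model
// under extracellular stimulation, with temperature-accelerated
// Hodgkin-Huxley kinetics updated by the Rush-Larsen exponential scheme.
//
// Reduced-voltage convention: V is the deviation of the transmembrane
// voltage from rest (mV). Units: capacitance uF, conductance mS, time ms,
// current uA.
//
// Always returns per-compartment summaries (running maximum, its time, and
// the first crossing of the spike criterion); the full voltage trace is
// recorded only when requested, which keeps threshold searches cheap.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the singularity removed
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

static inline double alpha_m(double v) { return 0.1 * vtrap(25.0 - v, 10.0); }
static inline double beta_m(double v)  { return 4.0 * std::exp(-v / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-v / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (std::exp((30.0 - v) / 10.0) + 1.0); }
static inline double alpha_n(double v) { return 0.01 * vtrap(10.0 - v, 10.0); }
static inline double beta_n(double v)  { return 0.125 * std::exp(-v / 80.0); }

// [[Rcpp::export]]
List cable_step_cpp(NumericVector C, NumericVector gna, NumericVector gk,
                    NumericVector gl, NumericVector gpass, NumericVector G,
                    NumericVector ve_unit, double amp, double onset,
                    double dur, double dt, double t_end, double k_temp,
                    double e_na, double e_k, double e_l,
                    double spike_mv, bool record, bool save_gating) {
  const int n = C.size();
  const int nt = (int)std::ceil(t_end / dt) + 1;
  std::vector<double> V(n, 0.0), m(n), h(n), nn(n);
  for (int i = 0; i < n; ++i) {
    m[i] = alpha_m(0) / (alpha_m(0) + beta_m(0));
    h[i] = alpha_h(0) / (alpha_h(0) + beta_h(0));
    nn[i] = alpha_n(0) / (alpha_n(0) + beta_n(0));
  }
  NumericMatrix Vout, Mout, Hout, Nout;
  if (record) Vout = NumericMatrix(n, nt);
  if (record && save_gating) {
    Mout = NumericMatrix(n, nt); Hout = NumericMatrix(n, nt);
    Nout = NumericMatrix(n, nt);
  }
  NumericVector tvec(record ? nt : 0);
  NumericVector vmax(n, 0.0), tmax(n, 0.0), tcross(n, NA_REAL);
  std::vector<double> bdia(n), rhs(n), cp(n), dp(n), ve(n, 0.0), Vprev(n, 0.0);

  for (int s = 0; s < nt; ++s) {
    double t = s * dt;
    if (record) {
      tvec[s] = t;
      for (int i = 0; i < n; ++i) Vout(i, s) = V[i];
      if (save_gating) {
        for (int i = 0; i < n; ++i) { Mout(i, s) = m[i]; Hout(i, s) = h[i]; Nout(i, s) = nn[i]; }
      }
    }
    for (int i = 0; i < n; ++i) {
      if (V[i] > vmax[i]) { vmax[i] = V[i]; tmax[i] = t; }
      if (NumericVector::is_na(tcross[i]) && V[i] >= spike_mv) tcross[i] = t;
    }
    if (s == nt - 1) break;

    double tn = t + dt;
    bool pulse_on = (tn > onset) && (tn <= onset + dur + 1e-12);
    for (int i = 0; i < n; ++i) ve[i] = pulse_on ? amp * ve_unit[i] : 0.0;

    // Rush-Larsen gating update at the current voltage
    for (int i = 0; i < n; ++i) {
      if (gna[i] > 0.0 || gk[i] > 0.0) {
        const double v = V[i];
        const double am = k_temp * alpha_m(v), bm = k_temp * beta_m(v);
        const double ah = k_temp * alpha_h(v), bh = k_temp * beta_h(v);
        const double an = k_temp * alpha_n(v), bn = k_temp * beta_n(v);
        double inf = am / (am + bm);
        m[i] = inf + (m[i] - inf) * std::exp(-dt * (am + bm));
        inf = ah / (ah + bh);
        h[i] = inf + (h[i] - inf) * std::exp(-dt * (ah + bh));
        inf = an / (an + bn);
        nn[i] = inf + (nn[i] - inf) * std::exp(-dt * (an + bn));
      }
    }

    // assemble tridiagonal backward-Euler system, ionic conductances frozen
    // at the updated gating
    for (int i = 0; i < n; ++i) {
      const double gna_i = gna[i] * m[i] * m[i] * m[i] * h[i];
      const double gk_i = gk[i] * nn[i] * nn[i] * nn[i] * nn[i];
      double diag = C[i] / dt + gna_i + gk_i + gl[i] + gpass[i];
      double b = C[i] / dt * V[i] + gna_i * e_na + gk_i * e_k + gl[i] * e_l;
      if (i > 0) { diag += G[i - 1]; b += G[i - 1] * (ve[i - 1] - ve[i]); }
      if (i < n - 1) { diag += G[i]; b += G[i] * (ve[i + 1] - ve[i]); }
      bdia[i] = diag;
      rhs[i] = b;
    }
    // Thomas algorithm (sub/super-diagonals are -G)
    cp[0] = -G[0] / bdia[0];
    dp[0] = rhs[0] / bdia[0];
    for (int i = 1; i < n; ++i) {
      const double a = -G[i - 1];
      const double mden = bdia[i] - a * cp[i - 1];
      cp[i] = (i < n - 1) ? -G[i] / mden : 0.0;
      dp[i] = (rhs[i] - a * dp[i - 1]) / mden;
    }
    Vprev = V;
    V[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(V[i])) {
        stop("cable integration diverged (non-finite voltage) at dt = %f ms", dt);
      }
    }
  }
  double dv_end = 0.0;
  NumericVector v_end(n);
  for (int i = 0; i < n; ++i) {
    v_end[i] = V[i];
    const double dv = V[i] - Vprev[i];
    if (dv > dv_end) dv_end = dv;
  }
  List out = List::create(_["vmax"] = vmax, _["tmax"] = tmax,
                          _["tcross"] = tcross, _["v_end"] = v_end,
                          _["dv_end"] = dv_end);
  if (record) { out["t"] = tvec; out["v"] = Vout; }
  if (record && save_gating) { out["m"] = Mout; out["h"] = Hout; out["n"] = Nout; }
  return out;
}
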
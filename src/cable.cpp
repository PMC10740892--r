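#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hodgkin-Huxley gating rates in displacement form (v = Vm - Vrest, mV).
// vtrap guards the removable singularities of the alpha functions.
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

static inline double alpha_m(double v) { return 0.1 * vtrap(25.0 - v, 10.0); }
static inline double beta_m(double v)  { return 4.0 * std::exp(-v / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-v / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (std::exp((30.0 - v) / 10.0) + 1.0); }
static inline double alpha_n(double v) { return 0.01 * vtrap(10.0 - v, 10.0); }
static inline double beta_n(double v)  { return 0.125 * std::exp(-v / 80.0); }

// Semi-implicit integration of a multicompartment myelinated axon driven by
// extracellular node potentials. Nodes of Ranvier carry HH kinetics;
// internodes are purely resistive (perfectly insulating myelin). Each step:
// (1) gates advance by exponential Euler at the previous membrane voltage,
// (2) the membrane voltage advances by backward Euler, which is linear in
// V_new once the gated conductances are frozen, giving one tridiagonal solve
// (Thomas algorithm) per step. Units: mV, ms, nF, uS, nA.
//
// ve:       nodes x nt extracellular potential (mV) at each sim time step
// dt_ms:    time step
// c_nF:     per-node capacitance
// gna/gk/gl_uS: per-node maximal conductances
// g_ax_uS:  axial conductance between adjacent nodes (length nodes-1)
// ena/ek/el_mV: absolute reversal potentials
// v_rest_mV: resting potential (absolute)
// rate_k:   temperature scaling of the gating rates
// v_spike_mV: spike detection level (absolute, upward crossing)
// v_limit_mV: |v_m| guard; exceeding it either aborts the run (clamp = false,
//   flagging divergence) or saturates the offending node (clamp = true) --
//   under supramaximal fields the flanking-node hyperpolarization genuinely
//   exceeds any physiological range and saturation keeps the spike-carrying
//   nodes integrating
// [[Rcpp::export]]
List cable_hh_run(const NumericMatrix& ve, double dt_ms,
                  const NumericVector& c_nF, const NumericVector& gna_uS,
                  const NumericVector& gk_uS, const NumericVector& gl_uS,
                  const NumericVector& g_ax_uS, double ena_mV, double ek_mV,
                  double el_mV, double v_rest_mV, double rate_k,
                  double v_spike_mV, bool keep_traces, double v_limit_mV,
                  bool clamp) {
  const int n = ve.nrow();
  const int nt = ve.ncol();
  if (n < 2) stop("fiber must have at least 2 nodes");

  std::vector<double> v(n, v_rest_mV), m(n), h(n), gn(n);
  {
    double v0 = 0.0;  // displacement at rest
    double m0 = alpha_m(v0) / (alpha_m(v0) + beta_m(v0));
    double h0 = alpha_h(v0) / (alpha_h(v0) + beta_h(v0));
    double n0 = alpha_n(v0) / (alpha_n(v0) + beta_n(v0));
    std::fill(m.begin(), m.end(), m0);
    std::fill(h.begin(), h.end(), h0);
    std::fill(gn.begin(), gn.end(), n0);
  }

  NumericMatrix v_out, im_out;
  if (keep_traces) {
    v_out = NumericMatrix(n, nt);
    im_out = NumericMatrix(n, nt);
  } else {
    v_out = NumericMatrix(n, 1);
    im_out = NumericMatrix(n, 1);
  }
  NumericVector spike_ms(n, NA_REAL);
  bool diverged = false;
  double diverge_ms = NA_REAL;

  std::vector<double> sub(n), diag(n), sup(n), rhs(n), cp(n), dp(n);

  for (int t = 0; t < nt && !diverged; ++t) {
    // (1) gates: exponential Euler at previous voltage
    for (int j = 0; j < n; ++j) {
      double vd = v[j] - v_rest_mV;
      double am = alpha_m(vd), bm = beta_m(vd);
      double ah = alpha_h(vd), bh = beta_h(vd);
      double an = alpha_n(vd), bn = beta_n(vd);
      double km = rate_k * (am + bm), kh = rate_k * (ah + bh),
             kn = rate_k * (an + bn);
      m[j] += (am / (am + bm) - m[j]) * (1.0 - std::exp(-dt_ms * km));
      h[j] += (ah / (ah + bh) - h[j]) * (1.0 - std::exp(-dt_ms * kh));
      gn[j] += (an / (an + bn) - gn[j]) * (1.0 - std::exp(-dt_ms * kn));
    }

    // (2) backward-Euler voltage step, tridiagonal in V_new
    for (int j = 0; j < n; ++j) {
      double gna_j = gna_uS[j] * m[j] * m[j] * m[j] * h[j];
      double gk_j = gk_uS[j] * gn[j] * gn[j] * gn[j] * gn[j];
      double gl = gl_uS[j];
      double gld = (j > 0) ? g_ax_uS[j - 1] : 0.0;
      double grd = (j < n - 1) ? g_ax_uS[j] : 0.0;
      double cdt = c_nF[j] / dt_ms;

      diag[j] = cdt + gna_j + gk_j + gl + gld + grd;
      sub[j] = (j > 0) ? -g_ax_uS[j - 1] : 0.0;
      sup[j] = (j < n - 1) ? -g_ax_uS[j] : 0.0;

      double drive = 0.0;  // axial coupling of the extracellular field
      if (j > 0) drive += gld * (ve(j - 1, t) - ve(j, t));
      if (j < n - 1) drive += grd * (ve(j + 1, t) - ve(j, t));
      rhs[j] = cdt * v[j] + gna_j * ena_mV + gk_j * ek_mV + gl * el_mV + drive;
    }

    // Thomas algorithm
    cp[0] = sup[0] / diag[0];
    dp[0] = rhs[0] / diag[0];
    for (int j = 1; j < n; ++j) {
      double denom = diag[j] - sub[j] * cp[j - 1];
      cp[j] = sup[j] / denom;
      dp[j] = (rhs[j] - sub[j] * dp[j - 1]) / denom;
    }
    std::vector<double> v_new(n);
    v_new[n - 1] = dp[n - 1];
    for (int j = n - 2; j >= 0; --j) v_new[j] = dp[j] - cp[j] * v_new[j + 1];

    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(v_new[j])) {
        stop("cable integration produced non-finite voltage; reduce dt (dt = %f ms)",
             dt_ms);
      }
      if (std::fabs(v_new[j] - v_rest_mV) > v_limit_mV) {
        if (clamp) {
          v_new[j] = v_rest_mV +
            (v_new[j] > v_rest_mV ? v_limit_mV : -v_limit_mV);
        } else {
          diverged = true;
          diverge_ms = (t + 1) * dt_ms;
        }
      }
      if (NumericVector::is_na(spike_ms[j]) && v[j] < v_spike_mV &&
          v_new[j] >= v_spike_mV) {
        spike_ms[j] = (t + 1) * dt_ms;
      }
    }

    if (keep_traces) {
      // transmembrane current from the axial side (telescopes to ~0 summed)
      for (int j = 0; j < n; ++j) {
        double im = 0.0;
        if (j > 0)
          im += g_ax_uS[j - 1] * (v_new[j - 1] - v_new[j] + ve(j - 1, t) - ve(j, t));
        if (j < n - 1)
          im += g_ax_uS[j] * (v_new[j + 1] - v_new[j] + ve(j + 1, t) - ve(j, t));
        im_out(j, t) = im;
        v_out(j, t) = v_new[j];
      }
    }
    v = v_new;
  }

  return List::create(_["v_mV"] = v_out, _["i_m_nA"] = im_out,
                      _["spike_ms"] = spike_ms, _["diverged"] = diverged,
                      _["diverge_ms"] = diverge_ms);
}
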
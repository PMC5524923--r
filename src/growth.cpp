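#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form log-volume solutions of the five growth laws, evaluated on the
// log scale so that extreme anchor offsets (t0 profiling scans +/- 3000 days)
// cannot overflow. Model codes: 1 exponential, 2 logistic, 3 mendelsohn,
// 4 gompertz, 5 von_bertalanffy. Returns NaN outside a model's time domain
// (Mendelsohn finite-time blow-up/extinction), -Inf where the volume hits zero.

static const double SSQ_BAD = 1e30;

static double log_sol(const int model, const double* th, const double dt,
                      const double logv0) {
  switch (model) {
  case 1:  // r
    return logv0 + th[0] * dt;
  case 2: {  // r, K
    const double lk = std::log(th[1]);
    const double a = std::exp(lk - logv0) - 1.0;  // K/V0 - 1
    const double denom = 1.0 + a * std::exp(-th[0] * dt);
    if (!(denom > 0.0)) return R_NaN;
    return lk - std::log(denom);
  }
  case 3: {  // r, b  (b != 1)
    const double om = 1.0 - th[1];
    const double base = om * th[0] * dt + std::exp(om * logv0);
    if (!(base > 0.0)) return R_NaN;
    return std::log(base) / om;
  }
  case 4: {  // r, rho
    return logv0 + (th[0] / th[1]) * (-std::expm1(-th[1] * dt));
  }
  case 5: {  // alpha, beta
    const double a = th[0] / th[1];
    const double inner = a - (a - std::exp(logv0 / 3.0)) * std::exp(-th[1] * dt / 3.0);
    if (inner <= 0.0) return R_NegInf;
    return 3.0 * std::log(inner);
  }
  }
  return R_NaN;
}

// [[Rcpp::export]]
NumericVector cpp_log_solution(int model, NumericVector theta, NumericVector dt,
                               double logv0) {
  const int n = dt.size();
  NumericVector out(n);
  const double* th = theta.begin();
  for (int i = 0; i < n; ++i) out[i] = log_sol(model, th, dt[i], logv0);
  return out;
}

// sum of squared log-residuals for one tumour at candidate anchor t0;
// invalid predictions contribute a large finite penalty so the 1-D search
// stays well ordered.
static double ssq_at(const int model, const double* th, const double* t,
                     const double* logv, const int n, const double t0,
                     const double logv0) {
  double ss = 0.0;
  for (int j = 0; j < n; ++j) {
    const double p = log_sol(model, th, t[j] - t0, logv0);
    if (!R_FINITE(p)) { ss += SSQ_BAD; continue; }
    const double r = logv[j] - p;
    if (!R_FINITE(r)) { ss += SSQ_BAD; continue; }
    ss += r * r;
  }
  return ss;
}

static double golden_t0(const int model, const double* th, const double* t,
                        const double* logv, const int n, double lo, double hi,
                        const double logv0, const double tol, double* fmin) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double c = hi - gr * (hi - lo), d = lo + gr * (hi - lo);
  double fc = ssq_at(model, th, t, logv, n, c, logv0);
  double fd = ssq_at(model, th, t, logv, n, d, logv0);
  while (hi - lo > tol) {
    if (fc < fd) {
      hi = d; d = c; fd = fc;
      c = hi - gr * (hi - lo);
      fc = ssq_at(model, th, t, logv, n, c, logv0);
    } else {
      lo = c; c = d; fc = fd;
      d = lo + gr * (hi - lo);
      fd = ssq_at(model, th, t, logv, n, d, logv0);
    }
  }
  const double mid = 0.5 * (lo + hi);
  *fmin = ssq_at(model, th, t, logv, n, mid, logv0);
  return mid;
}

// Profile the latent anchor time t0 of each tumour: coarse grid scan over
// [lo, hi] followed by golden-section refinement around the best grid point.
// t and logv are lists of per-tumour numeric vectors (times relative to each
// tumour's first observation, log volumes).
// [[Rcpp::export]]
List cpp_profile_t0(int model, NumericVector theta, List t, List logv,
                    double logv0, double lo, double hi,
                    double grid_step, double tol) {
  const int m = t.size();
  NumericVector t0(m), ssq(m);
  const double* th = theta.begin();
  for (int i = 0; i < m; ++i) {
    NumericVector ti = t[i], vi = logv[i];
    const int n = ti.size();
    const double* tp = ti.begin();
    const double* vp = vi.begin();
    double best = lo, fbest = R_PosInf;
    for (double g = lo; g <= hi + 1e-9; g += grid_step) {
      const double f = ssq_at(model, th, tp, vp, n, g, logv0);
      if (f < fbest) { fbest = f; best = g; }
    }
    double a = best - grid_step, b = best + grid_step;
    if (a < lo) a = lo;
    if (b > hi) b = hi;
    double fmin;
    const double tstar = golden_t0(model, th, tp, vp, n, a, b, logv0, tol, &fmin);
    if (fmin <= fbest) { t0[i] = tstar; ssq[i] = fmin; }
    else               { t0[i] = best;  ssq[i] = fbest; }
  }
  return List::create(_["t0"] = t0, _["ssq"] = ssq);
}
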
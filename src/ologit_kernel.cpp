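// Likelihood kernel for the proportional-odds imputation model:
// P(y <= k | x) = plogis(zeta_k - x'beta). Called once per Newton step,
// so it returns the negative log-likelihood and, on request, the analytic
// gradient and Hessian over (beta, zeta) in a single pass.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
List ologit_kernel(NumericVector beta, NumericVector zeta,
                   NumericMatrix X, IntegerVector yidx, int K,
                   bool derivs) {
  const int n = X.nrow(), p = X.ncol(), q = p + K - 1;
  double negll = 0.0;
  NumericVector grad(q);
  NumericMatrix hess(q, q);
  bool ok = true;

  for (int i = 0; i < n && ok; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * beta[j];
    const int y = yidx[i];            // 1-based category
    const int ku = y - 1;             // zeta index (0-based) of upper cut
    const int kl = y - 2;             // zeta index of lower cut
    const bool has_up = ku <= K - 2;
    const bool has_lo = kl >= 0;
    const double F1 = has_up ? sigmoid(zeta[ku] - eta) : 1.0;
    const double F0 = has_lo ? sigmoid(zeta[kl] - eta) : 0.0;
    const double pr = F1 - F0;
    if (!(pr > 0.0) || !R_finite(pr)) { ok = false; break; }
    negll -= std::log(pr);
    if (!derivs) continue;

    const double g1 = F1 * (1.0 - F1), g0 = F0 * (1.0 - F0);
    const double d1 = g1 * (1.0 - 2.0 * F1), d0 = g0 * (1.0 - 2.0 * F0);
    const double w = (g1 - g0) / pr;
    for (int j = 0; j < p; ++j) grad[j] += w * X(i, j);
    if (has_up) grad[p + ku] -= g1 / pr;
    if (has_lo) grad[p + kl] += g0 / pr;

    const double A = w * w - (d1 - d0) / pr;
    for (int j = 0; j < p; ++j) {
      const double xA = A * X(i, j);
      for (int l = j; l < p; ++l) hess(j, l) += xA * X(i, l);
    }
    const double inv2 = 1.0 / (pr * pr);
    if (has_up) {
      const double c_up = (d1 * pr + g1 * (g0 - g1)) * inv2;
      for (int j = 0; j < p; ++j) hess(j, p + ku) += c_up * X(i, j);
      hess(p + ku, p + ku) += (g1 * g1 - d1 * pr) * inv2;
    }
    if (has_lo) {
      const double c_lo = -(d0 * pr + g0 * (g0 - g1)) * inv2;
      for (int j = 0; j < p; ++j) hess(j, p + kl) += c_lo * X(i, j);
      hess(p + kl, p + kl) += (d0 * pr + g0 * g0) * inv2;
    }
    if (has_up && has_lo) {
      const double off = -g1 * g0 * inv2;
      hess(p + kl, p + ku) += off;       // kl < ku
    }
  }
  if (!ok) return List::create(_["negll"] = R_PosInf, _["ok"] = false);
  if (derivs) {                          // symmetrise upper triangle
    for (int j = 0; j < q; ++j)
      for (int l = j + 1; l < q; ++l) hess(l, j) = hess(j, l);
  }
  return List::create(_["negll"] = negll, _["ok"] = true,
                      _["gradient"] = grad, _["hessian"] = hess);
}
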
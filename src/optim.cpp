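#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// In-place Adadelta update. param, Eg (squared-gradient average) and Ed
// (squared-update average) are state owned by the optimizer and mutated
// directly; callers must not share these vectors.
// [[Rcpp::export(rng = false)]]
void adadelta_update_(NumericVector param, NumericVector grad,
                      NumericVector Eg, NumericVector Ed,
                      double lr, double rho, double eps) {
  R_xlen_t n = param.size();
  if (grad.size() != n || Eg.size() != n || Ed.size() != n)
    stop("adadelta_update_: length mismatch");
  double *p = param.begin(), *g = grad.begin(), *eg = Eg.begin(), *ed = Ed.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    eg[i] = rho * eg[i] + (1.0 - rho) * gi * gi;
    double delta = -std::sqrt((ed[i] + eps) / (eg[i] + eps)) * gi;
    ed[i] = rho * ed[i] + (1.0 - rho) * delta * delta;
    p[i] += lr * delta;
  }
}

// In-place Adam update with bias correction at step t.
// [[Rcpp::export(rng = false)]]
void adam_update_(NumericVector param, NumericVector grad,
                  NumericVector m, NumericVector v,
                  double lr, double beta1, double beta2, double eps, int t) {
  R_xlen_t n = param.size();
  if (grad.size() != n || m.size() != n || v.size() != n)
    stop("adam_update_: length mismatch");
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  double *p = param.begin(), *g = grad.begin(), *mm = m.begin(), *vv = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * gi;
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * gi * gi;
    p[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
  }
}
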
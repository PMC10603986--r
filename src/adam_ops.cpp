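#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update for one parameter array.  theta, m and v are owned
// exclusively by the training loop (never shared), so mutating them avoids
// re-allocating the large dense-layer matrices on every mini-batch.
// c1, c2 are the bias-correction factors 1 - beta^t.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector theta, const NumericVector& g,
                         NumericVector m, NumericVector v,
                         double lr, double beta1, double beta2,
                         double eps, double c1, double c2) {
  const R_xlen_t n = theta.size();
  double* th = theta.begin();
  const double* gr = g.begin();
  double* mm = m.begin();
  double* vv = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * gr[i];
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * gr[i] * gr[i];
    th[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
}
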
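// Warm-started cyclic coordinate descent for the Elastic Net loss
//   L = 1/(2n) ||y - Xw||^2 + alpha*rho*||w||_1 + alpha*(1-rho)/2*||w||^2
// over a decreasing penalty sequence. No intercept: callers center y and X.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix enet_cd_path_cpp(NumericMatrix X, NumericVector y,
                               NumericVector alphas, double rho,
                               double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), L = alphas.size();
  std::vector<double> xx(p);  // mean of x_j^2
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s / n;
  }
  NumericMatrix beta(p, L);
  std::vector<double> w(p, 0.0), r(y.begin(), y.end());
  for (int l = 0; l < L; ++l) {
    const double l1 = alphas[l] * rho;
    const double l2 = alphas[l] * (1.0 - rho);
    for (int it = 0; it < maxit; ++it) {
      double delta = 0.0;
      for (int j = 0; j < p; ++j) {
        if (xx[j] == 0.0) continue;  // constant (zeroed) column
        double g = 0.0;
        for (int i = 0; i < n; ++i) g += X(i, j) * r[i];
        g = g / n + xx[j] * w[j];
        double wn = 0.0;
        const double ag = std::fabs(g);
        if (ag > l1) wn = (g > 0 ? ag - l1 : l1 - ag) / (xx[j] + l2);
        if (wn != w[j]) {
          const double dw = wn - w[j];
          for (int i = 0; i < n; ++i) r[i] -= X(i, j) * dw;
          const double d = std::fabs(dw);
          if (d > delta) delta = d;
          w[j] = wn;
        }
      }
      if (delta < tol) break;
    }
    for (int j = 0; j < p; ++j) beta(j, l) = w[j];
  }
  return beta;
}
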
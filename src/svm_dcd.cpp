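#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Dual coordinate descent for the linear L2-regularized L1-loss (hinge) SVM:
//   min_w 1/2 w'w + C sum_i max(0, 1 - y_i w'x_i)
// solved in the dual with box constraints 0 <= a_i <= C (Hsieh et al. 2008).
// X is n x d with any bias column already appended; y in {-1, +1}.
// Deterministic for a fixed seed (per-epoch permutation from a private RNG).

// [[Rcpp::export]]
NumericVector svm_dcd_train(NumericMatrix X, NumericVector y, double C,
                            int max_epoch = 200, double tol = 1e-4,
                            int seed = 1) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector w(d), alpha(n), Qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 0;
    for (int j = 0; j < d; ++j) q += X(i, j) * X(i, j);
    Qii[i] = q;
  }
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epoch; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double max_viol = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      if (Qii[i] <= 0) continue;
      double wx = 0;
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G >= 0.0) PG = 0.0;
      else if (alpha[i] >= C && G <= 0.0) PG = 0.0;
      if (std::abs(PG) > max_viol) max_viol = std::abs(PG);
      if (std::abs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double delta = (a_new - a_old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
      }
    }
    if (max_viol < tol) break;
  }
  return w;
}
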
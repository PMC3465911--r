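#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact log of the intrinsic-prior mixture sum for a 2x2 confusion matrix y:
//
//   S(t) = sum over all 2x2 integer tables x with sum(x) = t of
//          t!/prod(x_ij!) * prod_i r_i(x)! * prod_j c_j(x)!
//          * prod_ij (x_ij + y_ij)! / x_ij!
//
// i.e. the sum the Monte Carlo estimator approximates via importance sampling
// from Multinomial(t, theta_hat). Computed by streaming log-sum-exp over the
// three free cells with a precomputed log-factorial table, so the whole
// evaluation stays in log space.
// [[Rcpp::export]]
double bf_exact_log_sum(IntegerMatrix y, int t) {
  if (y.nrow() != 2 || y.ncol() != 2)
    stop("exact enumeration is implemented for 2x2 tables only");
  if (t < 0) stop("t must be non-negative");
  const int m = y(0, 0) + y(0, 1) + y(1, 0) + y(1, 1);
  const int N = t + m + 2;
  std::vector<double> lf(N + 1); // lf[i] = log(i!)
  lf[0] = 0.0;
  for (int i = 1; i <= N; ++i) lf[i] = lf[i - 1] + std::log((double)i);

  const double lt = lf[t];
  double acc = 0.0, accmax = -std::numeric_limits<double>::infinity();
  for (int x11 = 0; x11 <= t; ++x11) {
    for (int x12 = 0; x11 + x12 <= t; ++x12) {
      const int rem = t - x11 - x12;
      const double base = lt + lf[x11 + x12] // row 1 sum
        + lf[x11 + y(0, 0)] - 2.0 * lf[x11]
        + lf[x12 + y(0, 1)] - 2.0 * lf[x12];
      for (int x21 = 0; x21 <= rem; ++x21) {
        const int x22 = rem - x21;
        const double s = base
          + lf[x21 + x22]  // row 2 sum
          + lf[x11 + x21]  // col 1 sum
          + lf[x12 + x22]  // col 2 sum
          + lf[x21 + y(1, 0)] - 2.0 * lf[x21]
          + lf[x22 + y(1, 1)] - 2.0 * lf[x22];
        if (s > accmax) {
          acc *= std::exp(accmax - s);
          accmax = s;
        }
        acc += std::exp(s - accmax);
      }
    }
  }
  return accmax + std::log(acc);
}
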
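#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Dynamic time warping with absolute scalar distance and the symmetric
// step pattern gamma(i,j) = d(i,j) + min(gamma(i-1,j-1), gamma(i-1,j),
// gamma(i,j-1)); unconstrained window.
// [[Rcpp::export]]
double cpp_dtw(NumericVector q, NumericVector c) {
  const int n = q.size(), m = c.size();
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double d = std::fabs(q[0] - c[j]);
    prev[j] = d + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    cur[0] = std::fabs(q[i] - c[0]) + prev[0];
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = std::fabs(q[i] - c[j]) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

static inline double ptdist(const NumericMatrix& P, int i,
                            const NumericMatrix& Q, int j) {
  double s = 0.0;
  for (int k = 0; k < P.ncol(); ++k) {
    double d = P(i, k) - Q(j, k);
    s += d * d;
  }
  return std::sqrt(s);
}

// Discrete Frechet distance between point sequences (rows are points):
// min over order-preserving couplings covering both curves of the
// maximum pairwise distance.
// [[Rcpp::export]]
double cpp_frechet(NumericMatrix P, NumericMatrix Q) {
  const int n = P.nrow(), m = Q.nrow();
  std::vector<double> prev(m), cur(m);
  prev[0] = ptdist(P, 0, Q, 0);
  for (int j = 1; j < m; ++j) {
    prev[j] = std::max(prev[j - 1], ptdist(P, 0, Q, j));
  }
  for (int i = 1; i < n; ++i) {
    cur[0] = std::max(prev[0], ptdist(P, i, Q, 0));
    for (int j = 1; j < m; ++j) {
      double reach = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = std::max(reach, ptdist(P, i, Q, j));
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
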
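#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Chebyshev (max-norm) distance to the k-th nearest neighbour of each row of X.
// Brute force O(N^2 d) with a small k-best buffer and early rejection;
// fine for the N <= ~2e4 used by the estimators.
// [[Rcpp::export]]
NumericVector cpp_knn_dist(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k >= n) stop("need 1 <= k < n");
  std::vector<const double*> col(d);
  for (int c = 0; c < d; ++c) col[c] = &X(0, c);
  NumericVector out(n);
  std::vector<double> best(k);
  for (int i = 0; i < n; ++i) {
    int filled = 0;
    double worst = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double m = std::fabs(col[0][i] - col[0][j]);
      for (int c = 1; c < d; ++c) {
        double v = std::fabs(col[c][i] - col[c][j]);
        if (v > m) m = v;
        if (m >= worst) break;
      }
      if (m >= worst) continue;
      if (filled < k) {
        best[filled++] = m;
        if (filled == k) worst = *std::max_element(best.begin(), best.end());
      } else {
        // replace the current worst
        int wi = 0;
        for (int b = 1; b < k; ++b) if (best[b] > best[wi]) wi = b;
        best[wi] = m;
        worst = *std::max_element(best.begin(), best.end());
      }
    }
    out[i] = worst;
  }
  return out;
}

// For each i, count points j != i with |x[j] - x[i]| < eps[i] (strict),
// x need not be sorted. O(N log N) via sorting.
// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericVector x, NumericVector eps) {
  const int n = x.size();
  if (eps.size() != n) stop("length mismatch");
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double lo = x[i] - eps[i], hi = x[i] + eps[i];
    // strict inequality on both sides
    int a = std::upper_bound(xs.begin(), xs.end(), lo) - xs.begin();
    int b = std::lower_bound(xs.begin(), xs.end(), hi) - xs.begin();
    int cnt = b - a - 1;  // remove the point itself (always inside)
    if (cnt < 0) cnt = 0;
    out[i] = cnt;
  }
  return out;
}
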
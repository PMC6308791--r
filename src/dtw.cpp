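#include <Rcpp.h>
using namespace Rcpp;

// Multi-dimensional DTW over two sequences of feature vectors (rows).
// Local cost = squared Euclidean distance between rows. Equal-length
// sequences are compared by the direct aligned sum (no warping); unequal
// lengths use the classic DP recurrence
//   D(i,j) = cost(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1)),  D(0,0) = 0.
// [[Rcpp::export(name = ".dtwCost")]]
double dtwCost(NumericMatrix a, NumericMatrix b, bool forceDP = false) {
  const int n = a.nrow(), m = b.nrow(), p = a.ncol();
  if (p != b.ncol()) stop("feature dimension mismatch");
  if (n == 0 || m == 0) stop("empty sequence");

  auto cost = [&](int i, int j) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) {
      const double d = a(i, k) - b(j, k);
      s += d * d;
    }
    return s;
  };

  if (n == m && !forceDP) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += cost(i, i);
    return s;
  }

  const double inf = R_PosInf;
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = inf;
    for (int j = 1; j <= m; ++j) {
      const double c = cost(i - 1, j - 1);
      const double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
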
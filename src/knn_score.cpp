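#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Summed k-nearest-neighbor label agreement within one locality:
// for each row of X, the fraction of its k nearest rows (Euclidean,
// ties broken by row index) sharing its label, summed over rows.
// [[Rcpp::export]]
double knn_agreement(NumericMatrix X, IntegerVector y, int k) {
  int n = X.nrow(), d = X.ncol();
  if (n < 2) return 0.0;
  int kx = std::min(k, n - 1);
  std::vector<double> D(n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double t = X(i, c) - X(j, c);
        s += t * t;
      }
      D[i * n + j] = s;
      D[j * n + i] = s;
    }
  }
  double total = 0;
  std::vector<std::pair<double, int> > row(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      row[m++] = std::make_pair(D[i * n + j], j);
    }
    std::partial_sort(row.begin(), row.begin() + kx, row.end());
    int match = 0;
    for (int q = 0; q < kx; ++q)
      if (y[row[q].second] == y[i]) ++match;
    total += (double)match / kx;
  }
  return total;
}
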
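#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Chebyshev distance,
// self-matches excluded). Returns c(A, B): A = (m+1)-template matches,
// B = m-template matches, over all pairs i < j of the n - m templates
// that admit an (m+1)-extension.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int N = n - m;
  long double A = 0, B = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double t = std::fabs(x[i + k] - x[j + k]);
        if (t > d) d = t;
        if (d > r) { ok = false; break; }
      }
      if (ok) {
        B += 1;
        double t = std::fabs(x[i + m] - x[j + m]);
        if (t <= r && d <= r) A += 1;
      }
    }
  }
  return NumericVector::create((double)A, (double)B);
}
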
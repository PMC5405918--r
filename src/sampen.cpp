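#include <Rcpp.h>
using namespace Rcpp;

// Template match counts for sample entropy under the Chebyshev metric.
// Returns B = #pairs (i<j) whose m-length templates match within r, and
// A = #pairs whose (m+1)-length templates match. Self-matches excluded by
// construction (i < j).
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  double A = 0.0, B = 0.0;
  int nm = n - m;  // number of m+1-length templates is n - m
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double ad = std::fabs(x[i + k] - x[j + k]);
        if (ad > d) d = ad;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double ad = std::fabs(x[i + m] - x[j + m]);
      if (ad <= r && d <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
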
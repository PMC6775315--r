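#include <Rcpp.h>
#include <cmath>

// Richman-Moorman sample entropy pair counts.
//
// Templates are the N - m vectors of length m starting at i = 0..N-m-1; each
// one extends to length m + 1 inside the series, so the same template set is
// used for both counts.  B counts ordered pairs i < j whose length-m
// templates are within Chebyshev distance r (inclusive); A counts those that
// remain within r at length m + 1.  Self-matches are excluded by i < j.
// [[Rcpp::export]]
Rcpp::List sampen_counts(Rcpp::NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;           // number of templates
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = (double)A,
                            Rcpp::Named("B") = (double)B);
}
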
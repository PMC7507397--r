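// Small compiled helpers.  The wavelet transforms themselves run on R's
// FFT (which outperforms Armadillo's fallback FFT for these sizes); only
// loops with no vectorised R equivalent live here.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// rolling (centred) min and max over a window of w samples
// [[Rcpp::export]]
Rcpp::List rolling_range_cpp(const arma::vec& x, int w) {
  const int n = x.n_elem;
  const int half = w / 2;
  arma::vec mn(n), mx(n);
  for (int i = 0; i < n; ++i) {
    int a = std::max(0, i - half);
    int b = std::min(n - 1, i + half);
    double lo = x[a], hi = x[a];
    for (int j = a + 1; j <= b; ++j) {
      if (x[j] < lo) lo = x[j];
      if (x[j] > hi) hi = x[j];
    }
    mn[i] = lo;
    mx[i] = hi;
  }
  return Rcpp::List::create(Rcpp::Named("min") = mn,
                            Rcpp::Named("max") = mx);
}
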
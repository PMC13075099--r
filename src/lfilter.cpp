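// Direct-form II transposed IIR filter with explicit initial state,
// the primitive behind the zero-phase (forward-backward) filtering chain.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector lfilter_cpp(const NumericVector &b, const NumericVector &a,
                          const NumericVector &x, const NumericVector &zi) {
  const int n = x.size(), m = b.size();
  std::vector<double> z(m - 1, 0.0);
  for (int i = 0; i < std::min((int)zi.size(), m - 1); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + (m > 1 ? z[0] : 0.0);
    for (int k = 0; k < m - 2; ++k)
      z[k] = b[k + 1] * xt + z[k + 1] - a[k + 1] * yt;
    if (m > 1) z[m - 2] = b[m - 1] * xt - a[m - 1] * yt;
    y[t] = yt;
  }
  return y;
}
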
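// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Direct-form II transposed IIR filter with initial state zi (length
// max(length(a), length(b)) - 1). a is assumed normalized so a[0] = 1.
// [[Rcpp::export]]
arma::vec iir_filter_cpp(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  const uword n = std::max(a.n_elem, b.n_elem);
  vec bb = zeros<vec>(n), aa = zeros<vec>(n);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  vec z = zi;
  vec y(x.n_elem);
  for (uword m = 0; m < x.n_elem; ++m) {
    const double xm = x[m];
    const double ym = bb[0] * xm + z[0];
    for (uword i = 0; i + 1 < n - 1; ++i) {
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    }
    z[n - 2] = bb[n - 1] * xm - aa[n - 1] * ym;
    y[m] = ym;
  }
  return y;
}
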
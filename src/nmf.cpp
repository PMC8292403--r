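// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Lee-Seung multiplicative updates for min ||M - WC||_F^2 s.t. W, C >= 0.
// A 1e-12 floor in the denominators guards against zero rows/columns in
// sparse training folds. The loss trace is monotone non-increasing; tests
// assert this on fixtures.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& M, arma::mat W, arma::mat C,
                      const int max_iter, const double tol,
                      const bool trace) {
  const double eps = 1e-12;
  std::vector<double> losses;
  double loss = accu(square(M - W * C));
  double prev = loss;
  if (trace) losses.push_back(loss);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    C %= (W.t() * M) / (W.t() * W * C + eps);
    W %= (M * C.t()) / (W * (C * C.t()) + eps);
    loss = accu(square(M - W * C));
    if (trace) losses.push_back(loss);
    const double rel = std::fabs(prev - loss) / std::max(prev, eps);
    prev = loss;
    if (rel < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("C") = C,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("iterations") = std::min(it, max_iter),
                            Rcpp::Named("trace") = losses);
}

// C-only multiplicative updates with W held fixed: used to fit held-out
// partitions during cross-validation.
// [[Rcpp::export]]
Rcpp::List nmf_update_c_cpp(const arma::mat& M, const arma::mat& W,
                            arma::mat C, const int max_iter,
                            const double tol) {
  const double eps = 1e-12;
  const mat WtW = W.t() * W;
  const mat WtM = W.t() * M;
  double prev = accu(square(M - W * C));
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    C %= WtM / (WtW * C + eps);
    const double loss = accu(square(M - W * C));
    const double rel = std::fabs(prev - loss) / std::max(prev, eps);
    prev = loss;
    if (rel < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("C") = C,
                            Rcpp::Named("loss") = prev,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}
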
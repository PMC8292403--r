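// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Column-wise Khatri-Rao product: (U kr V) has row index v + nV*u mapping
// to V(v, n) * U(u, n) for column n, i.e. column n = kron(U.col(n), V.col(n)).
static mat khatri_rao(const mat& U, const mat& V) {
  const uword N = U.n_cols;
  mat out(U.n_rows * V.n_rows, N);
  for (uword n = 0; n < N; ++n) {
    out.col(n) = vectorise(V.col(n) * U.col(n).t());
  }
  return out;
}

// Nonnegative CP (CANDECOMP/PARAFAC) by multiplicative updates on the
// squared-error loss, one factor matrix per mode. X enters as a cube
// I x J x K; the mode-n unfoldings are built once per call. The 1e-12
// denominator floor prevents division by zero for dead components.
// [[Rcpp::export]]
Rcpp::List ncp_mu_cpp(const arma::cube& X, arma::mat A, arma::mat B,
                      arma::mat C, const int max_iter, const double tol) {
  const double eps = 1e-12;
  const uword I = X.n_rows, J = X.n_cols, K = X.n_slices;

  // Mode-1 unfolding: I x JK, column index j + J*k (cube memory order).
  const mat X1(const_cast<double*>(X.memptr()), I, J * K, false, true);
  // Mode-2 unfolding: J x IK, column index i + I*k.
  mat X2(J, I * K);
  // Mode-3 unfolding: K x IJ, column index i + I*j.
  mat X3(K, I * J);
  for (uword k = 0; k < K; ++k) {
    X2.cols(k * I, k * I + I - 1) = X.slice(k).t();
    X3.row(k) = vectorise(X.slice(k)).t();
  }

  const double xnorm2 = accu(square(X1));
  double prev = datum::inf;
  double loss = prev;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    A %= (X1 * khatri_rao(C, B)) / (A * ((C.t() * C) % (B.t() * B)) + eps);
    B %= (X2 * khatri_rao(C, A)) / (B * ((C.t() * C) % (A.t() * A)) + eps);
    C %= (X3 * khatri_rao(B, A)) / (C * ((B.t() * B) % (A.t() * A)) + eps);
    // ||X - Xhat||^2 via the mode-1 view, without forming Xhat:
    // ||X||^2 - 2<X1, A Z'> + ||A Z'||^2 with Z = kr(C, B).
    const mat Z = khatri_rao(C, B);
    const mat G = (A.t() * A) % ((B.t() * B) % (C.t() * C));
    loss = xnorm2 - 2.0 * accu((X1 * Z) % A) + accu(G);
    if (loss < 0) loss = 0;  // numerical guard
    if (prev < datum::inf) {
      const double rel = std::fabs(prev - loss) / std::max(prev, eps);
      prev = loss;
      if (rel < tol) break;
    } else {
      prev = loss;
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("C") = C,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}
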
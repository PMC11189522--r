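// Elementwise/rowwise layer kernels: layer norm, GELU (sigmoid
// approximation) and bias addition. These are memory-bandwidth bound in R
// because of intermediate allocations; the C++ versions fuse the loops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List ln_fwd_cpp(const arma::mat& x, const arma::vec& g,
                      const arma::vec& b, const double eps) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec inv = 1.0 / sqrt(mean(xc % xc, 1) + eps);
  xc.each_col() %= inv;                       // xc is now xhat
  mat y = xc.each_row() % g.t();
  y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xc,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List ln_bwd_cpp(const arma::mat& dy, const arma::mat& xhat,
                      const arma::vec& inv, const arma::vec& g) {
  mat dxhat = dy.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  rowvec dg = sum(dy % xhat, 0);
  rowvec db = sum(dy, 0);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dg") = dg.t(),
                            Rcpp::Named("db") = db.t());
}

// In-place bias add. Only ever called on a freshly allocated matmul
// result, so mutating the input is safe and avoids a full copy.
// [[Rcpp::export]]
Rcpp::NumericMatrix add_bias_cpp(Rcpp::NumericMatrix y,
                                 const Rcpp::NumericVector& b) {
  const int n = y.nrow(), k = y.ncol();
  double* p = y.begin();
  for (int j = 0; j < k; ++j) {
    const double bj = b[j];
    for (int i = 0; i < n; ++i) p[j * (size_t)n + i] += bj;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List gelu_fwd_cpp(const arma::mat& x) {
  mat s = 1.0 / (1.0 + exp(-1.702 * x));
  return Rcpp::List::create(Rcpp::Named("y") = x % s,
                            Rcpp::Named("s") = s);
}

// [[Rcpp::export]]
arma::mat gelu_bwd_cpp(const arma::mat& dy, const arma::mat& x,
                       const arma::mat& s) {
  return dy % (s + 1.702 * x % s % (1.0 - s));
}
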
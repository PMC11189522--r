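// Batched multi-head self-attention kernels.
//
// Hidden states are (B*L) x d matrices in batch-major row order; `real`
// lists, per batch item, the 1-based row indices of non-padding positions
// (always a contiguous prefix in this package, which the kernels exploit).
// The forward kernel returns the softmax attention weights so the backward
// kernel does not recompute them.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List attn_fwd_cpp(const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V, const Rcpp::List& real,
                        const int n_heads, const double scale) {
  const uword d = Q.n_cols, dk = d / n_heads;
  const int B = real.size();
  mat O(Q.n_rows, d, fill::zeros);
  Rcpp::List Pout(B * n_heads);
  for (int b = 0; b < B; ++b) {
    uvec idx = Rcpp::as<arma::uvec>(real[b]) - 1;
    const uword r0 = idx(0), r1 = idx(idx.n_elem - 1);
    mat Qb = Q.rows(r0, r1), Kb = K.rows(r0, r1), Vb = V.rows(r0, r1);
    mat Ob(Qb.n_rows, d);
    for (int h = 0; h < n_heads; ++h) {
      const uword c0 = h * dk, c1 = (h + 1) * dk - 1;
      mat S = Qb.cols(c0, c1) * Kb.cols(c0, c1).t();
      S *= scale;
      S.each_col() -= max(S, 1);
      S = exp(S);
      S.each_col() /= sum(S, 1);
      Ob.cols(c0, c1) = S * Vb.cols(c0, c1);
      Pout[b * n_heads + h] = S;
    }
    O.rows(r0, r1) = Ob;
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("P") = Pout);
}

// [[Rcpp::export]]
Rcpp::List attn_bwd_cpp(const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V, const arma::mat& dO,
                        const Rcpp::List& P, const Rcpp::List& real,
                        const int n_heads, const double scale) {
  const uword d = Q.n_cols, dk = d / n_heads;
  const int B = real.size();
  mat dQ(Q.n_rows, d, fill::zeros), dK(Q.n_rows, d, fill::zeros),
      dV(Q.n_rows, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    uvec idx = Rcpp::as<arma::uvec>(real[b]) - 1;
    const uword r0 = idx(0), r1 = idx(idx.n_elem - 1);
    mat Qb = Q.rows(r0, r1), Kb = K.rows(r0, r1), Vb = V.rows(r0, r1),
        dOb = dO.rows(r0, r1);
    mat dQb(Qb.n_rows, d), dKb(Qb.n_rows, d), dVb(Qb.n_rows, d);
    for (int h = 0; h < n_heads; ++h) {
      const uword c0 = h * dk, c1 = (h + 1) * dk - 1;
      const mat Ph = Rcpp::as<arma::mat>(P[b * n_heads + h]);
      mat dOh = dOb.cols(c0, c1);
      mat dP = dOh * Vb.cols(c0, c1).t();
      dVb.cols(c0, c1) = Ph.t() * dOh;
      vec rs = sum(Ph % dP, 1);
      dP.each_col() -= rs;
      dP %= Ph;
      dQb.cols(c0, c1) = dP * Kb.cols(c0, c1) * scale;
      dKb.cols(c0, c1) = dP.t() * Qb.cols(c0, c1) * scale;
    }
    dQ.rows(r0, r1) = dQb;
    dK.rows(r0, r1) = dKb;
    dV.rows(r0, r1) = dVb;
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
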
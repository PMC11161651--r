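// Strided 1D convolution primitives for small CNNs.
//
// Layout conventions:
//   signals  : cube (channels x length x batch)
//   weights  : matrix (out_channels x in_channels*kernel), column-major over
//              (in_channel, tap) so that an input window [c, t..t+k-1]
//              flattens to a contiguous column of the im2col buffer.
//
// "Valid" convolution only: padding is applied explicitly by the caller
// (edge replication congruent with the receptive field), never implicitly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline void im2col(const mat& X, mat& col, int k, int s, int Lout) {
  const int Cin = X.n_rows;
  for (int t = 0; t < Lout; ++t)
    std::memcpy(col.colptr(t), X.colptr(t * s), sizeof(double) * Cin * k);
}

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b, int k, int s) {
  const int Cin = X.n_rows, L = X.n_cols, B = X.n_slices;
  if ((int)W.n_cols != Cin * k) Rcpp::stop("weight/kernel shape mismatch");
  const int Lout = (L - k) / s + 1;
  if (Lout < 1) Rcpp::stop("input shorter than kernel");
  const int Cout = W.n_rows;
  cube Y(Cout, Lout, B);
  mat col(Cin * k, Lout);
  for (int r = 0; r < B; ++r) {
    im2col(X.slice(r), col, k, s, Lout);
    Y.slice(r) = W * col;
    Y.slice(r).each_col() += b;
  }
  return Y;
}

// Full backward pass: gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube& X, const arma::cube& dY,
                      const arma::mat& W, int k, int s) {
  const int Cin = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lout = dY.n_cols, Cout = dY.n_rows;
  cube dX(Cin, L, B, fill::zeros);
  mat dW(Cout, Cin * k, fill::zeros);
  vec db(Cout, fill::zeros);
  mat col(Cin * k, Lout);
  for (int r = 0; r < B; ++r) {
    im2col(X.slice(r), col, k, s, Lout);
    const mat& dYr = dY.slice(r);
    dW += dYr * col.t();
    db += sum(dYr, 1);
    mat dcol = W.t() * dYr;
    mat& dXr = dX.slice(r);
    for (int t = 0; t < Lout; ++t) {
      double* dst = dXr.colptr(t * s);
      const double* src = dcol.colptr(t);
      for (int q = 0; q < Cin * k; ++q) dst[q] += src[q];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Input gradient only (transposed convolution); used by attribution rules
// where weight gradients are not needed.
// [[Rcpp::export]]
arma::cube conv1d_bwd_input(const arma::cube& dY, const arma::mat& W,
                            int Cin, int L, int k, int s) {
  const int Lout = dY.n_cols, B = dY.n_slices;
  cube dX(Cin, L, B, fill::zeros);
  for (int r = 0; r < B; ++r) {
    mat dcol = W.t() * dY.slice(r);
    mat& dXr = dX.slice(r);
    for (int t = 0; t < Lout; ++t) {
      double* dst = dXr.colptr(t * s);
      const double* src = dcol.colptr(t);
      for (int q = 0; q < Cin * k; ++q) dst[q] += src[q];
    }
  }
  return dX;
}
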
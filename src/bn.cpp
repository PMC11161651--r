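// Fused batch-normalization + ReLU kernels and the global-average-pooling
// head. Cubes are (channels x length x batch); normalization statistics
// are per channel over (length, batch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List channel_stats(const arma::cube& Z) {
  const uword C = Z.n_rows;
  const double n = (double)Z.n_cols * Z.n_slices;
  vec m(C, fill::zeros), m2(C, fill::zeros);
  for (uword b = 0; b < Z.n_slices; ++b) {
    const mat& s = Z.slice(b);
    for (uword t = 0; t < Z.n_cols; ++t)
      for (uword c = 0; c < C; ++c) {
        const double v = s(c, t);
        m[c] += v; m2[c] += v * v;
      }
  }
  m /= n;
  vec v = m2 / n - m % m;
  return Rcpp::List::create(Rcpp::Named("mean") = m, Rcpp::Named("var") = v);
}

// [[Rcpp::export]]
Rcpp::List bn_relu_fwd(const arma::cube& Z, const arma::vec& gamma,
                       const arma::vec& beta, const arma::vec& mu,
                       const arma::vec& sd) {
  cube xhat(Z.n_rows, Z.n_cols, Z.n_slices);
  cube a(Z.n_rows, Z.n_cols, Z.n_slices);
  const uword C = Z.n_rows;
  for (uword b = 0; b < Z.n_slices; ++b)
    for (uword t = 0; t < Z.n_cols; ++t)
      for (uword c = 0; c < C; ++c) {
        const double xh = (Z(c, t, b) - mu[c]) / sd[c];
        xhat(c, t, b) = xh;
        const double y = gamma[c] * xh + beta[c];
        a(c, t, b) = y > 0 ? y : 0.0;
      }
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat, Rcpp::Named("a") = a);
}

// Backward through ReLU and batch norm. With train = TRUE the full
// batch-statistics Jacobian is used; otherwise the evaluation-mode affine
// shortcut. guided implements the guided-backpropagation ReLU rule
// (upstream negatives zeroed as well).
// [[Rcpp::export]]
Rcpp::List bn_relu_bwd(const arma::cube& dA, const arma::cube& a,
                       const arma::cube& xhat, const arma::vec& gamma,
                       const arma::vec& sd, bool train, bool guided) {
  const uword C = dA.n_rows;
  const double n = (double)dA.n_cols * dA.n_slices;
  cube dm(dA.n_rows, dA.n_cols, dA.n_slices);
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  vec s1(C, fill::zeros), s2(C, fill::zeros);
  for (uword b = 0; b < dA.n_slices; ++b)
    for (uword t = 0; t < dA.n_cols; ++t)
      for (uword c = 0; c < C; ++c) {
        double d = a(c, t, b) > 0 ? dA(c, t, b) : 0.0;
        if (guided && d < 0) d = 0.0;
        dm(c, t, b) = d;
        dgamma[c] += d * xhat(c, t, b);
        dbeta[c] += d;
        const double dxh = d * gamma[c];
        s1[c] += dxh;
        s2[c] += dxh * xhat(c, t, b);
      }
  cube dz(dA.n_rows, dA.n_cols, dA.n_slices);
  if (train) {
    const vec m1 = s1 / n, m2 = s2 / n;
    for (uword b = 0; b < dA.n_slices; ++b)
      for (uword t = 0; t < dA.n_cols; ++t)
        for (uword c = 0; c < C; ++c)
          dz(c, t, b) = (dm(c, t, b) * gamma[c] - m1[c] -
                         xhat(c, t, b) * m2[c]) / sd[c];
  } else {
    for (uword b = 0; b < dA.n_slices; ++b)
      for (uword t = 0; t < dA.n_cols; ++t)
        for (uword c = 0; c < C; ++c)
          dz(c, t, b) = dm(c, t, b) * gamma[c] / sd[c];
  }
  return Rcpp::List::create(Rcpp::Named("dz") = dz,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
arma::mat gap_fwd(const arma::cube& A) {
  mat G(A.n_rows, A.n_slices);
  for (uword b = 0; b < A.n_slices; ++b)
    G.col(b) = mean(A.slice(b), 1);
  return G;
}

// [[Rcpp::export]]
arma::cube gap_bwd(const arma::mat& dG, int Lout) {
  cube dA(dG.n_rows, Lout, dG.n_cols);
  for (uword b = 0; b < dG.n_cols; ++b) {
    const vec v = dG.col(b) / (double)Lout;
    for (int t = 0; t < Lout; ++t) dA.slice(b).col(t) = v;
  }
  return dA;
}
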
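// 1D convolution kernels (im2col + GEMM) for the classifier.
//
// Activations are (C*L) x B matrices, channel-fastest: element
// ((l)*C + c, b) is channel c at position l. Convolutions use zero
// 'same' padding and stride 1; weights are F x (C*K) with the same
// (c fast, k) layout as the im2col rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// build the im2col matrix (C*K) x (L*B); column index is p + L*b
static arma::mat im2col(const arma::mat& X, int C, int K) {
  const int L = X.n_rows / C, B = X.n_cols, P = (K - 1) / 2;
  arma::mat M(C * K, (arma::uword)L * B);
  for (int bi = 0; bi < B; ++bi) {
    const double* xc = X.colptr(bi);
    for (int p = 0; p < L; ++p) {
      double* mc = M.colptr((arma::uword)p + (arma::uword)L * bi);
      for (int k = 0; k < K; ++k) {
        const int l = p + k - P;
        if (l < 0 || l >= L)
          std::fill(mc + k * C, mc + (k + 1) * C, 0.0);
        else
          std::copy(xc + (size_t)l * C, xc + (size_t)(l + 1) * C,
                    mc + k * C);
      }
    }
  }
  return M;
}

// forward: returns (F*L) x B
// [[Rcpp::export(.cpp_conv1d_fw)]]
arma::mat cpp_conv1d_fw(const arma::mat& X, int C, int K,
                        const arma::mat& W, const arma::vec& b) {
  const int L = X.n_rows / C, B = X.n_cols, F = W.n_rows;
  arma::mat M = im2col(X, C, K);
  arma::mat Z = W * M;
  Z.each_col() += b;
  Z.reshape((arma::uword)F * L, B);  // column-major: (f fast, p, b)
  return Z;
}

// backward: dZ is (F*L) x B; returns dW, db, dX
// [[Rcpp::export(.cpp_conv1d_bw)]]
Rcpp::List cpp_conv1d_bw(const arma::mat& X, arma::mat dZ, int C, int K,
                         const arma::mat& W) {
  const int L = X.n_rows / C, B = X.n_cols, F = W.n_rows,
            P = (K - 1) / 2;
  dZ.reshape(F, (arma::uword)L * B);
  arma::mat M = im2col(X, C, K);
  arma::mat dW = dZ * M.t();
  arma::vec db = arma::sum(dZ, 1);
  arma::mat dM = W.t() * dZ;  // (C*K) x (L*B)
  arma::mat dX(X.n_rows, B, arma::fill::zeros);
  for (int bi = 0; bi < B; ++bi) {
    double* xc = dX.colptr(bi);
    for (int p = 0; p < L; ++p) {
      const double* mc = dM.colptr((arma::uword)p + (arma::uword)L * bi);
      for (int k = 0; k < K; ++k) {
        const int l = p + k - P;
        if (l < 0 || l >= L) continue;
        double* dst = xc + (size_t)l * C;
        const double* src = mc + k * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dX);
}
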
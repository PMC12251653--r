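// Depthwise 1-D convolution kernels used by the network layers.
// Tensors use the (channels, length, batch) layout, matching R arrays
// with dim = c(C, L, N); arma::cube maps onto that layout directly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_len(int L, int k, int stride, int pad) {
  return (L + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".dwconv_fw")]]
arma::cube dwconv_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b, int stride, int pad) {
  const int C = X.n_rows, L = X.n_cols, N = X.n_slices, k = W.n_cols;
  const int Lo = out_len(L, k, stride, pad);
  cube Y(C, Lo, N);
  for (int n = 0; n < N; ++n) {
    mat& Ys = Y.slice(n);
    Ys.each_col() = b;
    const mat& Xs = X.slice(n);
    for (int j = 0; j < k; ++j) {
      // output position l reads input column l*stride + j - pad
      int l0 = 0, l1 = Lo - 1;
      int off = j - pad;
      while (l0 * stride + off < 0) ++l0;
      while (l1 * stride + off > L - 1) --l1;
      if (l0 > l1) continue;
      const vec wj = W.col(j);
      if (stride == 1) {
        mat Xsub = Xs.cols(l0 + off, l1 + off);
        Ys.cols(l0, l1) += Xsub.each_col() % wj;
      } else {
        for (int l = l0; l <= l1; ++l)
          Ys.col(l) += wj % Xs.col(l * stride + off);
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".dwconv_bw")]]
Rcpp::List dwconv_bw(const arma::cube& X, const arma::mat& W,
                     const arma::cube& G, int stride, int pad) {
  const int C = X.n_rows, L = X.n_cols, N = X.n_slices, k = W.n_cols;
  const int Lo = G.n_cols;
  cube dX(C, L, N, fill::zeros);
  mat dW(C, k, fill::zeros);
  vec db(C, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const mat& Xs = X.slice(n);
    const mat& Gs = G.slice(n);
    db += sum(Gs, 1);
    for (int j = 0; j < k; ++j) {
      int l0 = 0, l1 = Lo - 1;
      const int off = j - pad;
      while (l0 * stride + off < 0) ++l0;
      while (l1 * stride + off > L - 1) --l1;
      if (l0 > l1) continue;
      const vec wj = W.col(j);
      if (stride == 1) {
        const mat Gsub = Gs.cols(l0, l1);
        dX.slice(n).cols(l0 + off, l1 + off) += Gsub.each_col() % wj;
        dW.col(j) += sum(Gsub % Xs.cols(l0 + off, l1 + off), 1);
      } else {
        for (int l = l0; l <= l1; ++l) {
          const int src = l * stride + off;
          dX.slice(n).col(src) += wj % Gs.col(l);
          dW.col(j) += Gs.col(l) % Xs.col(src);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
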
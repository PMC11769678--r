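// Compiled kernels for the CNN engine: shift-GEMM convolutions and batch
// normalization. Matrices arrive in the package's batch-fastest row layout
// ((B*T) x features); temporal shifts are therefore contiguous row offsets
// and every heavy product maps onto BLAS through Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#ifdef __GLIBC__
#include <malloc.h>
#endif

using namespace Rcpp;

// The engine allocates many multi-megabyte temporaries per minibatch. With
// glibc's default mmap/trim thresholds each becomes a fresh mmap plus a
// page-fault storm; raising the thresholds lets the heap reuse freed
// blocks, which speeds training several-fold. No-op on other libcs.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// Valid 1D convolution, kernel spanning all input columns, stride 1.
// W holds k column blocks of size F x C (block dt = weights of temporal
// offset dt).
// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, int T_in, int B,
                       const arma::mat& W, const arma::vec& bias, int k) {
  const int C = W.n_cols / k;
  const int n = (T_in - k + 1) * B;
  arma::mat Z = X * W;
  arma::mat Y = Z.submat(0, 0, n - 1, C - 1);
  for (int dt = 1; dt < k; ++dt) {
    Y += Z.submat(dt * B, dt * C, dt * B + n - 1, dt * C + C - 1);
  }
  Y.each_row() += bias.t();
  return Y;
}

// Gradients of the convolution: weight block dt is the product of the
// dt-shifted input rows with dY; the input gradient scatters dY * W_dt^T
// back onto the shifted rows.
// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& X, const arma::mat& W,
                  const arma::mat& dY, int B, int k, bool need_dx) {
  const int C = dY.n_cols;
  const int n = dY.n_rows;
  const int F = X.n_cols;
  arma::mat dW(F, k * C);
  for (int dt = 0; dt < k; ++dt) {
    dW.cols(dt * C, dt * C + C - 1) =
      X.rows(dt * B, dt * B + n - 1).t() * dY;
  }
  arma::rowvec db = arma::sum(dY, 0);
  if (!need_dx) {
    return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = R_NilValue);
  }
  arma::mat dX(X.n_rows, F, arma::fill::zeros);
  for (int dt = 0; dt < k; ++dt) {
    dX.rows(dt * B, dt * B + n - 1) +=
      dY * W.cols(dt * C, dt * C + C - 1).t();
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// Batch normalization over columns (channels). Training mode uses batch
// statistics and updates running statistics with the given momentum; eval
// mode applies the running statistics.
// [[Rcpp::export]]
List cpp_bn_fwd(const arma::mat& Y, const arma::vec& gamma,
                const arma::vec& beta, const arma::vec& rm,
                const arma::vec& rv, bool train, double momentum,
                double eps) {
  const int n = Y.n_rows;
  arma::rowvec mu, invstd;
  arma::vec rm_new(rm), rv_new(rv);
  arma::mat xhat;
  if (train) {
    mu = arma::mean(Y, 0);
    xhat = Y.each_row() - mu;
    arma::rowvec v = arma::sum(arma::square(xhat), 0) / n;
    invstd = 1.0 / arma::sqrt(v + eps);
    xhat.each_row() %= invstd;
    double corr = n > 1 ? double(n) / (n - 1) : 1.0;
    rm_new = (1 - momentum) * rm + momentum * mu.t();
    rv_new = (1 - momentum) * rv + momentum * corr * v.t();
  } else {
    invstd = 1.0 / arma::sqrt(rv.t() + eps);
    xhat = (Y.each_row() - rm.t()).each_row() % invstd;
  }
  arma::mat out = (xhat.each_row() % gamma.t()).each_row() + beta.t();
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["invstd"] = arma::vec(invstd.t()),
                      _["rm"] = rm_new, _["rv"] = rv_new);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::mat& xhat, const arma::vec& invstd,
                const arma::vec& gamma, const arma::mat& dY, bool train) {
  const int n = dY.n_rows;
  arma::rowvec dgamma = arma::sum(dY % xhat, 0);
  arma::rowvec dbeta = arma::sum(dY, 0);
  arma::mat dxhat = dY.each_row() % gamma.t();
  arma::mat dX;
  if (train) {
    arma::rowvec s1 = arma::sum(dxhat, 0);
    arma::rowvec s2 = arma::sum(dxhat % xhat, 0);
    dX = n * dxhat;
    dX.each_row() -= s1;
    dX -= xhat.each_row() % s2;
    dX.each_row() %= invstd.t() / n;
  } else {
    dX = dxhat.each_row() % invstd.t();
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
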
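// Compiled kernels for the hot loops of network training: dilated 1-D
// convolution (forward/backward) and batch normalization. Activations
// are (channels x positions*batch) matrices, clips laid out
// contiguously, zero padding implied at clip edges.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

// W: (cout x cin*k), tap-major column blocks; X: (cin x L*B)
// [[Rcpp::export]]
arma::mat cpp_conv1d_fwd(const arma::mat& W, const arma::vec& b,
                         const arma::mat& X, int L, int B, int d, int k) {
  const int cin = X.n_rows;
  const int cout = W.n_rows;
  mat Y(cout, X.n_cols);
  Y.each_col() = b;
  const int half = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int o = (j - half) * d;
    const int lo = std::max(0, -o);
    const int hi = std::min(L, L - o);  // dst positions [lo, hi)
    if (hi <= lo) continue;
    const mat Wj = W.cols(j * cin, (j + 1) * cin - 1);
    for (int bb = 0; bb < B; ++bb) {
      const int base = bb * L;
      Y.cols(base + lo, base + hi - 1) +=
        Wj * X.cols(base + lo + o, base + hi - 1 + o);
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv1d_bwd(const arma::mat& W, const arma::mat& X,
                    const arma::mat& dY, int L, int B, int d, int k) {
  const int cin = X.n_rows;
  const int cout = W.n_rows;
  mat dW(cout, cin * k, arma::fill::zeros);
  vec db = arma::sum(dY, 1);
  mat dX(cin, X.n_cols, arma::fill::zeros);
  const int half = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int o = (j - half) * d;
    const int lo = std::max(0, -o);
    const int hi = std::min(L, L - o);
    if (hi <= lo) continue;
    const mat Wj = W.cols(j * cin, (j + 1) * cin - 1);
    mat dWj(cout, cin, arma::fill::zeros);
    for (int bb = 0; bb < B; ++bb) {
      const int base = bb * L;
      const mat dYs = dY.cols(base + lo, base + hi - 1);
      dWj += dYs * X.cols(base + lo + o, base + hi - 1 + o).t();
      dX.cols(base + lo + o, base + hi - 1 + o) += Wj.t() * dYs;
    }
    dW.cols(j * cin, (j + 1) * cin - 1) = dWj;
  }
  return List::create(_["W"] = dW, _["b"] = db, _["dX"] = dX);
}

// returns out, xhat, mu, invstd (batch statistics)
// [[Rcpp::export]]
List cpp_bn_fwd(const arma::mat& X, const arma::vec& gamma,
                const arma::vec& beta, double eps) {
  const double N = double(X.n_cols);
  vec mu = arma::mean(X, 1);
  vec ss = arma::sum(arma::square(X), 1) / N - arma::square(mu);
  vec invstd = 1.0 / arma::sqrt(ss + eps);
  mat xhat = X;
  xhat.each_col() -= mu;
  xhat.each_col() %= invstd;
  mat out = xhat;
  out.each_col() %= gamma;
  out.each_col() += beta;
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::mat& dY, const arma::mat& xhat,
                const arma::vec& gamma, const arma::vec& invstd) {
  const double N = double(dY.n_cols);
  vec dgamma = arma::sum(dY % xhat, 1);
  vec dbeta = arma::sum(dY, 1);
  // dx = dY*(g*inv) - xhat*(g*dgamma*inv/N) - (g*dbeta*inv/N)
  mat dx = dY;
  dx.each_col() %= gamma % invstd;
  mat t2 = xhat;
  t2.each_col() %= gamma % dgamma % invstd / N;
  dx -= t2;
  dx.each_col() -= gamma % dbeta % invstd / N;
  return List::create(_["dx"] = dx, _["gamma"] = dgamma, _["beta"] = dbeta);
}

// leaky ReLU; backward recovers the sign mask from the forward output
// [[Rcpp::export]]
arma::mat cpp_lrelu_fwd(const arma::mat& X, double slope) {
  mat out(X.n_rows, X.n_cols);
  const double* xi = X.memptr();
  double* oi = out.memptr();
  const arma::uword n = X.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    oi[i] = xi[i] > 0 ? xi[i] : slope * xi[i];
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_lrelu_bwd(const arma::mat& dY, const arma::mat& out,
                        double slope) {
  mat dx(dY.n_rows, dY.n_cols);
  const double* di = dY.memptr();
  const double* oi = out.memptr();
  double* xi = dx.memptr();
  const arma::uword n = dY.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    xi[i] = oi[i] > 0 ? di[i] : slope * di[i];
  return dx;
}

// ---- strided 2-D convolution via C++ im2col + GEMM ----
// X: (cin, H*W*B) matrix, spatial column-major (h fastest), clips last.

static arma::mat im2col2d(const arma::mat& X, int cin, int H, int W, int B,
                          int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat M(cin * k * k, (arma::uword)Ho * Wo * B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    const arma::uword xoff = (arma::uword)bb * H * W;
    const arma::uword moff = (arma::uword)bb * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword mcol = moff + (arma::uword)wo * Ho + ho;
        double* mptr = M.colptr(mcol);
        int r = 0;
        for (int kw = 0; kw < k; ++kw) {
          const int wsrc = wo * stride + kw - pad;
          for (int kh = 0; kh < k; ++kh, r += cin) {
            const int hsrc = ho * stride + kh - pad;
            if (hsrc < 0 || hsrc >= H || wsrc < 0 || wsrc >= W) continue;
            const double* xptr = X.colptr(xoff + (arma::uword)wsrc * H + hsrc);
            std::copy(xptr, xptr + cin, mptr + r);
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::mat cpp_conv2d_fwd(const arma::mat& W, const arma::vec& b,
                         const arma::mat& X, int cin, int H, int Wd, int B,
                         int k, int stride, int pad) {
  arma::mat M = im2col2d(X, cin, H, Wd, B, k, stride, pad);
  arma::mat Y = W * M;
  Y.each_col() += b;
  return Y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::mat& W, const arma::mat& X,
                    const arma::mat& dY, int cin, int H, int Wd, int B,
                    int k, int stride, int pad) {
  arma::mat M = im2col2d(X, cin, H, Wd, B, k, stride, pad);
  arma::mat dW = dY * M.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dM = W.t() * dY;
  // col2im scatter-add
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  arma::mat dX(cin, (arma::uword)H * Wd * B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    const arma::uword xoff = (arma::uword)bb * H * Wd;
    const arma::uword moff = (arma::uword)bb * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const arma::uword mcol = moff + (arma::uword)wo * Ho + ho;
        const double* mptr = dM.colptr(mcol);
        int r = 0;
        for (int kw = 0; kw < k; ++kw) {
          const int wsrc = wo * stride + kw - pad;
          for (int kh = 0; kh < k; ++kh, r += cin) {
            const int hsrc = ho * stride + kh - pad;
            if (hsrc < 0 || hsrc >= H || wsrc < 0 || wsrc >= Wd) continue;
            double* xptr = dX.colptr(xoff + (arma::uword)wsrc * H + hsrc);
            for (int c = 0; c < cin; ++c) xptr[c] += mptr[r + c];
          }
        }
      }
    }
  }
  return List::create(_["W"] = dW, _["b"] = db, _["dX"] = dX);
}
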
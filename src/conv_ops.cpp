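// im2col/col2im convolution kernels for the slice-synthesis networks.
// Feature maps are arma::cube with dimensions (H, W, C); conv weights are
// (k*k*Cin) x Cout matrices with row order ki + kj*k + c*k*k; transposed
// conv weights are (k*k*Cout) x Cin.  Padding is (p0 before, p1 after) on
// both spatial axes, which lets 4x4 stride-1 convolutions preserve size
// (p0 = 1, p1 = 2).  The unfolded patch matrix is kept transposed
// (positions x patch-elements) so inner loops run down contiguous columns.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static int out_size(int n, int k, int s, int p0, int p1) {
  return (n + p0 + p1 - k) / s + 1;
}

// valid output range [o0, o1] with  0 <= o*s + koff - p0 <= n-1
static inline void valid_range(int n, int no, int s, int koff, int p0,
                               int& o0, int& o1) {
  o0 = (p0 > koff) ? (p0 - koff + s - 1) / s : 0;
  const int hi = n - 1 + p0 - koff;
  o1 = hi < 0 ? -1 : std::min(no - 1, hi / s);
}

// (Ho*Wo) x (k*k*C) unfolded patch matrix
static mat im2col_t(const cube& x, int k, int s, int p0, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(static_cast<uword>(Ho) * Wo, static_cast<uword>(k) * k * C,
          fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      int oj0, oj1;
      valid_range(W, Wo, s, kj, p0, oj0, oj1);
      for (int ki = 0; ki < k; ++ki) {
        int oi0, oi1;
        valid_range(H, Ho, s, ki, p0, oi0, oi1);
        if (oi1 < oi0 || oj1 < oj0) continue;
        const int cnt = oi1 - oi0 + 1;
        double* dst0 = out.colptr(ki + kj * k + static_cast<uword>(c) * k * k);
        for (int oj = oj0; oj <= oj1; ++oj) {
          const int j = oj * s + kj - p0;
          const double* src = xc.colptr(j) + (oi0 * s + ki - p0);
          double* dst = dst0 + static_cast<uword>(oj) * Ho + oi0;
          if (s == 1) {
            std::memcpy(dst, src, cnt * sizeof(double));
          } else {
            for (int t = 0; t < cnt; ++t) dst[t] = src[t * s];
          }
        }
      }
    }
  }
  return out;
}

// adjoint of im2col_t: scatter-add patch columns back onto the image grid
static cube col2im_t(const mat& colsT, int H, int W, int C, int k, int s,
                     int p0, int Ho, int Wo) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      int oj0, oj1;
      valid_range(W, Wo, s, kj, p0, oj0, oj1);
      for (int ki = 0; ki < k; ++ki) {
        int oi0, oi1;
        valid_range(H, Ho, s, ki, p0, oi0, oi1);
        if (oi1 < oi0 || oj1 < oj0) continue;
        const int cnt = oi1 - oi0 + 1;
        const double* src0 =
          colsT.colptr(ki + kj * k + static_cast<uword>(c) * k * k);
        for (int oj = oj0; oj <= oj1; ++oj) {
          const int j = oj * s + kj - p0;
          double* dst = xc.colptr(j) + (oi0 * s + ki - p0);
          const double* src = src0 + static_cast<uword>(oj) * Ho + oi0;
          if (s == 1) {
            for (int t = 0; t < cnt; ++t) dst[t] += src[t];
          } else {
            for (int t = 0; t < cnt; ++t) dst[t * s] += src[t];
          }
        }
      }
    }
  }
  return x;
}

// flatten cube slices into a (H*W) x C matrix (column per channel)
static mat flatten_t(const cube& x) {
  const uword n = static_cast<uword>(x.n_rows) * x.n_cols;
  mat out(n, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) {
    std::memcpy(out.colptr(c), x.slice(c).memptr(), n * sizeof(double));
  }
  return out;
}

static cube unflatten_t(const mat& m, int H, int W) {
  cube out(H, W, m.n_cols);
  const uword n = static_cast<uword>(H) * W;
  for (uword c = 0; c < m.n_cols; ++c) {
    std::memcpy(out.slice(c).memptr(), m.colptr(c), n * sizeof(double));
  }
  return out;
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, int k, int s, int p0, int p1) {
  const int Ho = out_size(x.n_rows, k, s, p0, p1);
  const int Wo = out_size(x.n_cols, k, s, p0, p1);
  if (Ho < 1 || Wo < 1)
    Rcpp::stop("convolution output would be empty (input %dx%d, kernel %d)",
               x.n_rows, x.n_cols, k);
  mat Mt = im2col_t(x, k, s, p0, Ho, Wo);
  mat Yt = Mt * w;              // (Ho*Wo) x Cout
  Yt.each_row() += b.t();
  return unflatten_t(Yt, Ho, Wo);
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube& x, const arma::mat& w,
                       const arma::cube& dy, int k, int s, int p0, int p1) {
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  mat Gt = flatten_t(dy);       // (Ho*Wo) x Cout
  mat Mt = im2col_t(x, k, s, p0, Ho, Wo);
  mat dW = Mt.t() * Gt;
  vec db = sum(Gt, 0).t();
  mat dMt = Gt * w.t();         // (Ho*Wo) x (k*k*Cin)
  cube dx = col2im_t(dMt, x.n_rows, x.n_cols, x.n_slices, k, s, p0, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// Transposed convolution: the adjoint of a stride-s convolution mapping the
// (Ho, Wo) output grid back onto the (H, W) input grid.  Caller supplies the
// target size; it must satisfy the stride arithmetic exactly.
// [[Rcpp::export]]
arma::cube nn_convt_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, int k, int s, int p0, int p1,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols;
  if (out_size(Ho, k, s, p0, p1) != H || out_size(Wo, k, s, p0, p1) != W)
    Rcpp::stop("transposed convolution target size %dx%d inconsistent with input %dx%d",
               Ho, Wo, H, W);
  mat Xt = flatten_t(x);        // (H*W) x Cin
  mat colsT = Xt * w.t();       // (H*W) x (k*k*Cout)
  cube y = col2im_t(colsT, Ho, Wo, w.n_rows / (k * k), k, s, p0, H, W);
  for (uword c = 0; c < y.n_slices; ++c) y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_convt_bwd(const arma::cube& x, const arma::mat& w,
                        const arma::cube& dy, int k, int s, int p0, int p1) {
  const int H = x.n_rows, W = x.n_cols;
  mat Xt = flatten_t(x);
  mat dcolsT = im2col_t(dy, k, s, p0, H, W);  // (H*W) x (k*k*Cout)
  mat dW = dcolsT.t() * Xt;
  mat dXt = dcolsT * w;         // (H*W) x Cin
  cube dx = unflatten_t(dXt, H, W);
  vec db(dy.n_slices);
  for (uword c = 0; c < dy.n_slices; ++c) db(c) = accu(dy.slice(c));
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// Instance normalization: per-channel standardization over the spatial grid.
// [[Rcpp::export]]
Rcpp::List nn_inorm_fwd(const arma::cube& x, const arma::vec& gamma,
                        const arma::vec& beta, double eps) {
  cube xhat(x.n_rows, x.n_cols, x.n_slices);
  cube y(x.n_rows, x.n_cols, x.n_slices);
  vec istd(x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) {
    const mat& xc = x.slice(c);
    const double m = accu(xc) / xc.n_elem;
    const double v = accu(square(xc)) / xc.n_elem - m * m;
    istd(c) = 1.0 / std::sqrt(v + eps);
    xhat.slice(c) = (xc - m) * istd(c);
    y.slice(c) = xhat.slice(c) * gamma(c) + beta(c);
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List nn_inorm_bwd(const arma::cube& xhat, const arma::vec& istd,
                        const arma::vec& gamma, const arma::cube& dy) {
  cube dx(dy.n_rows, dy.n_cols, dy.n_slices);
  vec g_gamma(dy.n_slices), g_beta(dy.n_slices);
  for (uword c = 0; c < dy.n_slices; ++c) {
    const mat& h = xhat.slice(c);
    const mat& g = dy.slice(c);
    const double n = g.n_elem;
    const mat dxhat = g * gamma(c);
    const double m1 = accu(dxhat) / n;
    const double m2 = accu(dxhat % h) / n;
    dx.slice(c) = istd(c) * (dxhat - m1 - h * m2);
    g_gamma(c) = accu(g % h);
    g_beta(c) = accu(g);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("g_gamma") = g_gamma,
                            Rcpp::Named("g_beta") = g_beta);
}
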
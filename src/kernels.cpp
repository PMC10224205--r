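// Low-level image kernels: im2col/col2im for the detector's convolutions,
// 3x3 median filtering and disc-structuring-element grayscale morphology
// with edge-replication borders (the documented border policy).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold an H x W x C array into a (C*k*k) x (Ho*Wo) matrix (zero padding).
// Column j indexes output position (ho, wo) with ho fastest (column-major,
// matching R's array(, c(Ho, Wo, .)) layout); row indexes (ki, kj, c) with
// ki fastest.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat out(C * k * k, Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int r0 = ho * stride - pad;
      const int c0 = wo * stride - pad;
      double* dst = out.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          const int cc = c0 + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int rr = r0 + ki;
            double v = 0.0;
            if (rr >= 0 && rr < H && cc >= 0 && cc < W) v = x(rr, cc, c);
            dst[c * k * k + kj * k + ki] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: fold a (C*k*k) x (Ho*Wo) gradient matrix back onto
// the H x W x C input, accumulating overlaps.
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int r0 = ho * stride - pad;
      const int c0 = wo * stride - pad;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          const int cc = c0 + kj;
          if (cc < 0 || cc >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int rr = r0 + ki;
            if (rr < 0 || rr >= H) continue;
            out(rr, cc, c) += src[c * k * k + kj * k + ki];
          }
        }
      }
    }
  }
  return out;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 3x3 median filter with edge replication.
// [[Rcpp::export]]
arma::mat cpp_median3(const arma::mat& x) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat out(H, W);
  double win[9];
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          win[n++] = x(clampi(i + di, 0, H - 1), clampi(j + dj, 0, W - 1));
      std::nth_element(win, win + 4, win + 9);
      out(i, j) = win[4];
    }
  }
  return out;
}

// Grayscale erosion (min) or dilation (max) over a flat structuring element
// given as a two-column matrix of (row, col) offsets; edge replication.
// [[Rcpp::export]]
arma::mat cpp_morph(const arma::mat& x, const arma::imat& offsets, bool dilate) {
  const int H = x.n_rows, W = x.n_cols;
  const int n = offsets.n_rows;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = dilate ? -arma::datum::inf : arma::datum::inf;
      for (int t = 0; t < n; ++t) {
        const double p = x(clampi(i + offsets(t, 0), 0, H - 1),
                           clampi(j + offsets(t, 1), 0, W - 1));
        if (dilate) { if (p > v) v = p; } else { if (p < v) v = p; }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Mish with a single exp: tanh(softplus(x)) = (E^2 + 2E) / (E^2 + 2E + 2)
// for E = exp(x); exact, and clamped where the limit is reached in double
// precision.
static inline double act_f(double x, int act) {
  if (act == 0) return x;                       // linear
  if (act == 1) return x > 0 ? x : 0.1 * x;     // leaky
  if (x > 20.0) return x;                       // mish
  const double E = std::exp(x);
  const double q = E * E + 2.0 * E;
  return x * (q / (q + 2.0));
}

static inline double act_g(double x, int act) {
  if (act == 0) return 1.0;
  if (act == 1) return x > 0 ? 1.0 : 0.1;
  if (x > 20.0) return 1.0;
  const double E = std::exp(x);
  const double q = E * E + 2.0 * E;
  const double t = q / (q + 2.0);
  const double s = E / (1.0 + E);
  return t + x * (1.0 - t * t) * s;
}

// Fused convolution forward pass: im2col + GEMM + bias + activation.
// Returns the activated output and the pre-activation cube (for backward).
// act: 0 = linear, 1 = leaky ReLU (0.1), 2 = Mish.
// [[Rcpp::export]]
List cpp_conv_fwd(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                  int k, int stride, int pad, int act) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  const int Cout = W.n_rows;
  arma::mat col = cpp_im2col(x, k, stride, pad);
  arma::mat pre_mat = W * col;
  pre_mat.each_col() += b;
  arma::cube pre(Ho, Wo, Cout), out(Ho, Wo, Cout);
  const int n = Ho * Wo;
  const double* pm = pre_mat.memptr();          // Cout x n, column-major
  double* pp = pre.memptr();                    // n x Cout layout
  double* po = out.memptr();
  for (int c = 0; c < Cout; ++c) {
    for (int j = 0; j < n; ++j) {
      const double v = pm[c + (arma::uword)Cout * j];
      pp[j + (arma::uword)n * c] = v;
      po[j + (arma::uword)n * c] = act_f(v, act);
    }
  }
  return List::create(Named("out") = out, Named("pre") = pre);
}

// Matching backward pass: given d(loss)/d(out), the cached pre-activation
// and the layer input, returns gradients for the input, weights and bias.
// need_dx = false skips the input gradient (first layer).
// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& dout, const arma::cube& pre,
                  const arma::cube& x, const arma::mat& W,
                  int k, int stride, int pad, int act, bool need_dx = true) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  const int n = Ho * Wo;
  arma::mat dpre_mat(Cout, n);
  double* dp = dpre_mat.memptr();
  const double* pd = dout.memptr();
  const double* pp = pre.memptr();
  for (int c = 0; c < Cout; ++c) {
    for (int j = 0; j < n; ++j) {
      dp[c + (arma::uword)Cout * j] =
        pd[j + (arma::uword)n * c] * act_g(pp[j + (arma::uword)n * c], act);
    }
  }
  arma::mat col = cpp_im2col(x, k, stride, pad);
  arma::mat dW = dpre_mat * col.t();
  arma::vec db = arma::sum(dpre_mat, 1);
  arma::cube dx;
  if (need_dx) {
    arma::mat dcol = W.t() * dpre_mat;
    dx = cpp_col2im(dcol, H, Wd, C, k, stride, pad);
  }
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}
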
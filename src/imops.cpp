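// Low-level image/tensor kernels backing the network stack.
//
// Layout convention: a C x H x W tensor is an R array with dim c(C, H, W),
// i.e. element (c, h, w) sits at linear index c + C*h + C*H*w (0-based).
// Coordinates are 0-based pixel centres, x = column, y = row.

#include <Rcpp.h>
using namespace Rcpp;

// Unfold a zero-padded C x H x W tensor into a (C*k*k) x (Ho*Wo) matrix so a
// convolution becomes one matrix product. Row index r = c + C*(p + k*q) for
// kernel offset (p, q) along (H, W); column index n = oh + Ho*ow.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(C * k * k, Ho * Wo);
  const double *xp = x.begin();
  double *cp = cols.begin();
  const int nrow = C * k * k;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int n = oh + Ho * ow;
      double *col = cp + (size_t)n * nrow;
      for (int q = 0; q < k; ++q) {
        const int w = ow * stride - pad + q;
        for (int p = 0; p < k; ++p) {
          const int h = oh * stride - pad + p;
          double *dst = col + C * (p + k * q);
          if (h < 0 || h >= H || w < 0 || w >= W) {
            for (int c = 0; c < C; ++c) dst[c] = 0.0;
          } else {
            const double *src = xp + C * (h + (size_t)H * w);
            for (int c = 0; c < C; ++c) dst[c] = src[c];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add columns back into a C x H x W tensor.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int H, int W,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((size_t)C * H * W);
  double *xp = x.begin();
  const double *cp = cols.begin();
  const int nrow = C * k * k;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int n = oh + Ho * ow;
      const double *col = cp + (size_t)n * nrow;
      for (int q = 0; q < k; ++q) {
        const int w = ow * stride - pad + q;
        if (w < 0 || w >= W) continue;
        for (int p = 0; p < k; ++p) {
          const int h = oh * stride - pad + p;
          if (h < 0 || h >= H) continue;
          const double *src = col + C * (p + k * q);
          double *dst = xp + C * (h + (size_t)H * w);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, H, W);
  return x;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sampling of a C x H x W tensor at M positions (sx, sy), given in
// input-pixel units. Positions outside the image are clamped to the border
// before interpolation. Returns a C x M matrix.
// [[Rcpp::export]]
NumericMatrix cpp_grid_sample(NumericVector x, int C, int H, int W,
                              NumericVector sx, NumericVector sy) {
  const int M = sx.size();
  NumericMatrix out(C, M);
  const double *xp = x.begin();
  for (int m = 0; m < M; ++m) {
    const double px = clampd(sx[m], 0.0, W - 1.0);
    const double py = clampd(sy[m], 0.0, H - 1.0);
    const int x0 = (int)std::floor(px);
    const int y0 = (int)std::floor(py);
    const int x1 = x0 + 1 > W - 1 ? W - 1 : x0 + 1;
    const int y1 = y0 + 1 > H - 1 ? H - 1 : y0 + 1;
    const double wx = px - x0, wy = py - y0;
    const double w00 = (1 - wy) * (1 - wx), w01 = (1 - wy) * wx;
    const double w10 = wy * (1 - wx), w11 = wy * wx;
    const double *p00 = xp + C * (y0 + (size_t)H * x0);
    const double *p01 = xp + C * (y0 + (size_t)H * x1);
    const double *p10 = xp + C * (y1 + (size_t)H * x0);
    const double *p11 = xp + C * (y1 + (size_t)H * x1);
    double *o = out.begin() + (size_t)m * C;
    for (int c = 0; c < C; ++c)
      o[c] = w00 * p00[c] + w01 * p01[c] + w10 * p10[c] + w11 * p11[c];
  }
  return out;
}

// Gradients of bilinear sampling w.r.t. the input tensor and the sampling
// positions. dy is C x M. Positions clamped to the border get zero position
// gradient (the clamp is flat there).
// [[Rcpp::export]]
List cpp_grid_sample_backward(NumericVector x, int C, int H, int W,
                              NumericVector sx, NumericVector sy,
                              NumericMatrix dy) {
  const int M = sx.size();
  NumericVector dx((size_t)C * H * W);
  NumericVector dsx(M), dsy(M);
  const double *xp = x.begin();
  double *dxp = dx.begin();
  for (int m = 0; m < M; ++m) {
    const bool cx = sx[m] < 0.0 || sx[m] > W - 1.0;
    const bool cy = sy[m] < 0.0 || sy[m] > H - 1.0;
    const double px = clampd(sx[m], 0.0, W - 1.0);
    const double py = clampd(sy[m], 0.0, H - 1.0);
    const int x0 = (int)std::floor(px);
    const int y0 = (int)std::floor(py);
    const int x1 = x0 + 1 > W - 1 ? W - 1 : x0 + 1;
    const int y1 = y0 + 1 > H - 1 ? H - 1 : y0 + 1;
    const double wx = px - x0, wy = py - y0;
    const double w00 = (1 - wy) * (1 - wx), w01 = (1 - wy) * wx;
    const double w10 = wy * (1 - wx), w11 = wy * wx;
    const size_t i00 = C * (y0 + (size_t)H * x0);
    const size_t i01 = C * (y0 + (size_t)H * x1);
    const size_t i10 = C * (y1 + (size_t)H * x0);
    const size_t i11 = C * (y1 + (size_t)H * x1);
    const double *g = dy.begin() + (size_t)m * C;
    double gx = 0.0, gy = 0.0;
    for (int c = 0; c < C; ++c) {
      const double gc = g[c];
      dxp[i00 + c] += w00 * gc;
      dxp[i01 + c] += w01 * gc;
      dxp[i10 + c] += w10 * gc;
      dxp[i11 + c] += w11 * gc;
      gx += gc * ((1 - wy) * (xp[i01 + c] - xp[i00 + c]) +
                  wy * (xp[i11 + c] - xp[i10 + c]));
      gy += gc * ((1 - wx) * (xp[i10 + c] - xp[i00 + c]) +
                  wx * (xp[i11 + c] - xp[i01 + c]));
    }
    dsx[m] = cx ? 0.0 : gx;
    dsy[m] = cy ? 0.0 : gy;
  }
  dx.attr("dim") = IntegerVector::create(C, H, W);
  return List::create(_["dx"] = dx, _["dsx"] = dsx, _["dsy"] = dsy);
}

// 2x2 stride-2 max pooling. Returns pooled values plus the 1-based linear
// index of each argmax (ties -> first in column-major order), so the
// backward pass is a plain scatter in R.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, int C, int H, int W) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)C * Ho * Wo);
  IntegerVector idx((size_t)C * Ho * Wo);
  const double *xp = x.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int c = 0; c < C; ++c) {
        double best = -1e300;
        size_t bi = 0;
        for (int q = 0; q < 2; ++q) {
          for (int p = 0; p < 2; ++p) {
            const size_t i = c + C * ((size_t)(2 * oh + p) +
                                      (size_t)H * (2 * ow + q));
            if (xp[i] > best) { best = xp[i]; bi = i; }
          }
        }
        const size_t o = c + C * ((size_t)oh + (size_t)Ho * ow);
        y[o] = best;
        idx[o] = (int)(bi + 1);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo);
  return List::create(_["y"] = y, _["idx"] = idx);
}

#include <R_ext/BLAS.h>

// Fill the im2col buffer (column-major (C k^2) x (Ho Wo)); contiguous
// channel runs are memcpy'd.
static void fill_cols(const double *xp, double *cp, int C, int H, int W,
                      int k, int stride, int pad, int Ho, int Wo) {
  const int nrow = C * k * k;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      double *col = cp + (size_t)(oh + Ho * ow) * nrow;
      for (int q = 0; q < k; ++q) {
        const int w = ow * stride - pad + q;
        for (int p = 0; p < k; ++p) {
          const int h = oh * stride - pad + p;
          double *dst = col + C * (p + k * q);
          if (h < 0 || h >= H || w < 0 || w >= W)
            std::memset(dst, 0, C * sizeof(double));
          else
            std::memcpy(dst, xp + C * (h + (size_t)H * w), C * sizeof(double));
        }
      }
    }
  }
}

// Convolution forward. act: 0 = linear, 1 = ReLU, 2 = LeakyReLU with
// slope 0.2, applied in place. Wm is (C k^2) x Cout. The im2col buffer is
// internal; the backward pass rebuilds it from the cached input (cheaper
// than keeping every buffer alive across a whole network pass).
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, int C, int H, int W,
                           NumericMatrix Wm, NumericVector b,
                           int k, int stride, int pad, int act) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.ncol();
  const int K = C * k * k;
  const int N = Ho * Wo;
  std::vector<double> cols((size_t)K * N);
  fill_cols(x.begin(), cols.data(), C, H, W, k, stride, pad, Ho, Wo);
  NumericVector y((size_t)Cout * N);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &Cout, &N, &K, &one, Wm.begin(), &K,
                  cols.data(), &K, &zero, y.begin(), &Cout FCONE FCONE);
  double *yp = y.begin();
  const double *bp = b.begin();
  const size_t tot = (size_t)Cout * N;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) yp[(size_t)n * Cout + c] += bp[c];
  if (act == 1) {
    for (size_t i = 0; i < tot; ++i) if (yp[i] < 0) yp[i] = 0;
  } else if (act == 2) {
    for (size_t i = 0; i < tot; ++i) if (yp[i] < 0) yp[i] *= 0.2;
  }
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo);
  return y;
}

// Convolution backward; rebuilds the im2col buffer from the cached input.
// y is the post-activation output (the activation mask is reconstructed
// from its sign).
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, int C, int H, int W,
                  NumericMatrix Wm, NumericVector y, NumericVector dy,
                  int k, int stride, int pad, int act) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.ncol();
  const int K = C * k * k;
  const int N = Ho * Wo;
  const size_t tot = (size_t)Cout * N;
  std::vector<double> cols((size_t)K * N);
  fill_cols(x.begin(), cols.data(), C, H, W, k, stride, pad, Ho, Wo);
  std::vector<double> g(dy.begin(), dy.end());
  const double *yp = y.begin();
  if (act == 1) {
    for (size_t i = 0; i < tot; ++i) if (yp[i] <= 0) g[i] = 0;
  } else if (act == 2) {
    for (size_t i = 0; i < tot; ++i) if (yp[i] < 0) g[i] *= 0.2;
  }
  NumericMatrix dW(K, Cout);
  NumericVector db(Cout);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "T", &K, &Cout, &N, &one, cols.data(), &K,
                  g.data(), &Cout, &zero, dW.begin(), &K FCONE FCONE);
  double *dbp = db.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) dbp[c] += g[(size_t)n * Cout + c];
  std::vector<double> dcols((size_t)K * N);
  F77_CALL(dgemm)("N", "N", &K, &N, &Cout, &one, Wm.begin(), &K,
                  g.data(), &Cout, &zero, dcols.data(), &K FCONE FCONE);
  NumericVector dx((size_t)C * H * W);
  double *dxp = dx.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const double *col = dcols.data() + (size_t)(oh + Ho * ow) * K;
      for (int q = 0; q < k; ++q) {
        const int w = ow * stride - pad + q;
        if (w < 0 || w >= W) continue;
        for (int p = 0; p < k; ++p) {
          const int h = oh * stride - pad + p;
          if (h < 0 || h >= H) continue;
          const double *src = col + C * (p + k * q);
          double *dst = dxp + C * (h + (size_t)H * w);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---- single-precision convolution path -------------------------------
// Training uses float32 convolution arithmetic (the norm for GPU-trained
// translation networks); all exposed operators default to the double
// kernels above. Same layout and semantics, sgemm instead of dgemm.

static void fill_cols_f(const double *xp, float *cp, int C, int H, int W,
                        int k, int stride, int pad, int Ho, int Wo) {
  const int nrow = C * k * k;
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      float *col = cp + (size_t)(oh + Ho * ow) * nrow;
      for (int q = 0; q < k; ++q) {
        const int w = ow * stride - pad + q;
        for (int p = 0; p < k; ++p) {
          const int h = oh * stride - pad + p;
          float *dst = col + C * (p + k * q);
          if (h < 0 || h >= H || w < 0 || w >= W) {
            for (int c = 0; c < C; ++c) dst[c] = 0.0f;
          } else {
            const double *src = xp + C * (h + (size_t)H * w);
            for (int c = 0; c < C; ++c) dst[c] = (float)src[c];
          }
        }
      }
    }
  }
}

extern "C" void sgemm_(const char *transa, const char *transb,
                       const int *m, const int *n, const int *k,
                       const float *alpha, const float *a, const int *lda,
                       const float *b, const int *ldb, const float *beta,
                       float *c, const int *ldc);

// [[Rcpp::export]]
NumericVector cpp_conv_fwd_f(NumericVector x, int C, int H, int W,
                             NumericMatrix Wm, NumericVector b,
                             int k, int stride, int pad, int act) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.ncol();
  const int K = C * k * k;
  const int N = Ho * Wo;
  std::vector<float> cols((size_t)K * N);
  fill_cols_f(x.begin(), cols.data(), C, H, W, k, stride, pad, Ho, Wo);
  std::vector<float> Wf(Wm.begin(), Wm.end());
  std::vector<float> yf((size_t)Cout * N);
  const float one = 1.0f, zero = 0.0f;
  sgemm_("T", "N", &Cout, &N, &K, &one, Wf.data(), &K,
         cols.data(), &K, &zero, yf.data(), &Cout);
  NumericVector y((size_t)Cout * N);
  double *yp = y.begin();
  const double *bp = b.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      double v = (double)yf[(size_t)n * Cout + c] + bp[c];
      if (act == 1) { if (v < 0) v = 0; }
      else if (act == 2) { if (v < 0) v *= 0.2; }
      yp[(size_t)n * Cout + c] = v;
    }
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd_f(NumericVector x, int C, int H, int W,
                    NumericMatrix Wm, NumericVector y, NumericVector dy,
                    int k, int stride, int pad, int act) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.ncol();
  const int K = C * k * k;
  const int N = Ho * Wo;
  const size_t tot = (size_t)Cout * N;
  std::vector<float> cols((size_t)K * N);
  fill_cols_f(x.begin(), cols.data(), C, H, W, k, stride, pad, Ho, Wo);
  std::vector<float> g(tot);
  const double *yp = y.begin();
  const double *dyp = dy.begin();
  for (size_t i = 0; i < tot; ++i) {
    double v = dyp[i];
    if (act == 1) { if (yp[i] <= 0) v = 0; }
    else if (act == 2) { if (yp[i] < 0) v *= 0.2; }
    g[i] = (float)v;
  }
  std::vector<float> Wf(Wm.begin(), Wm.end());
  std::vector<float> dWf((size_t)K * Cout);
  NumericVector db(Cout);
  const float one = 1.0f, zero = 0.0f;
  sgemm_("N", "T", &K, &Cout, &N, &one, cols.data(), &K,
         g.data(), &Cout, &zero, dWf.data(), &K);
  double *dbp = db.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) dbp[c] += (double)g[(size_t)n * Cout + c];
  std::vector<float> dcols((size_t)K * N);
  sgemm_("N", "N", &K, &N, &Cout, &one, Wf.data(), &K,
         g.data(), &Cout, &zero, dcols.data(), &K);
  NumericMatrix dW(K, Cout);
  std::copy(dWf.begin(), dWf.end(), dW.begin());
  NumericVector dx((size_t)C * H * W);
  double *dxp = dx.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const float *col = dcols.data() + (size_t)(oh + Ho * ow) * K;
      for (int q = 0; q < k; ++q) {
        const int w = ow * stride - pad + q;
        if (w < 0 || w >= W) continue;
        for (int p = 0; p < k; ++p) {
          const int h = oh * stride - pad + p;
          if (h < 0 || h >= H) continue;
          const float *src = col + C * (p + k * q);
          double *dst = dxp + C * (h + (size_t)H * w);
          for (int c = 0; c < C; ++c) dst[c] += (double)src[c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
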
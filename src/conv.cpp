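// Batched 2-D convolution forward/backward via im2col + BLAS gemm.
// Layouts follow R column-major conventions:
//   x    : (H, W, C, N)   input batch
//   w    : (kh, kw, C, F) filter bank
//   out  : (Ho, Wo, F, N)
// Padding is zero padding; stride identical in both spatial dims.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill col (K x L) for image n of x. K = kh*kw*C, L = Ho*Wo,
// column index l = ho + Ho*wo, row index k = i + kh*(j + kw*c).
static void im2col(const double* x, int H, int W, int C, int n,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  const double* xn = x + (size_t)H * W * C * n;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      double* cl = col.colptr(l);
      for (int c = 0; c < C; ++c) {
        const double* xc = xn + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          const int wi = wo * stride - pad + j;
          const bool win = (wi >= 0 && wi < W);
          for (int i = 0; i < kh; ++i) {
            const int hi = ho * stride - pad + i;
            const int k = i + kh * (j + kw * c);
            cl[k] = (win && hi >= 0 && hi < H) ? xc[hi + (size_t)H * wi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add dcol (K x L) back into dx for image n (col2im).
static void col2im(const arma::mat& dcol, int H, int W, int C, int n,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  double* dxn = dx + (size_t)H * W * C * n;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      const double* cl = dcol.colptr(l);
      for (int c = 0; c < C; ++c) {
        double* dxc = dxn + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          const int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            dxc[hi + (size_t)H * wi] += cl[i + kh * (j + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_forward")]]
NumericVector conv_forward_cpp(NumericVector x, NumericVector w,
                               NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("filter channel count does not match input");
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  const int K = kh * kw * C, L = Ho * Wo;

  // Wmat(f, k) = w(i, j, c, f): reshape of w with filter index last.
  arma::mat Wm(F, K);
  for (int k = 0; k < K; ++k)
    for (int f = 0; f < F; ++f)
      Wm(f, k) = w[k + (size_t)K * f];

  NumericVector out(Ho * Wo * (size_t)F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat col(K, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat on = Wm * col;           // F x L
    double* op = out.begin() + (size_t)Ho * Wo * F * n;
    for (int l = 0; l < L; ++l) {
      const int ho = l % Ho, wo = l / Ho;
      for (int f = 0; f < F; ++f)
        op[ho + (size_t)Ho * (wo + (size_t)Wo * f)] = on(f, l) + b[f];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward_cpp(NumericVector x, NumericVector w, NumericVector dout,
                       int stride, int pad, bool need_dx, bool need_dw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  const int K = kh * kw * C, L = Ho * Wo;

  arma::mat Wm(F, K);
  for (int k = 0; k < K; ++k)
    for (int f = 0; f < F; ++f)
      Wm(f, k) = w[k + (size_t)K * f];

  arma::mat dWm(F, K, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;

  arma::mat col(K, L), G(F, L);
  for (int n = 0; n < N; ++n) {
    const double* dp = dout.begin() + (size_t)Ho * Wo * F * n;
    for (int l = 0; l < L; ++l) {
      const int ho = l % Ho, wo = l / Ho;
      for (int f = 0; f < F; ++f)
        G(f, l) = dp[ho + (size_t)Ho * (wo + (size_t)Wo * f)];
    }
    if (need_dw) {
      im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, Ho, Wo, col);
      dWm += G * col.t();
      db += arma::sum(G, 1);
    }
    if (need_dx) {
      arma::mat dcol = Wm.t() * G;   // K x L
      col2im(dcol, H, W, C, n, kh, kw, stride, pad, Ho, Wo, dx.begin());
    }
  }

  NumericVector dw(need_dw ? w.size() : 0);
  if (need_dw) {
    dw.attr("dim") = wd;
    for (int k = 0; k < K; ++k)
      for (int f = 0; f < F; ++f)
        dw[k + (size_t)K * f] = dWm(f, k);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
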
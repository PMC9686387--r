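#include <Rcpp.h>
using namespace Rcpp;

// Activation layout: matrix of dim C x (H*W*N), column index = h + H*(w + W*n)
// (h fastest). Patch-matrix layout: row index = c + C*(ki + k*kj) where ki/kj
// are the kernel offsets along h/w; column index = ho + Ho*(wo + Wo*n).

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  NumericMatrix cols(C * k * k, Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int q = ho + Ho * (wo + Wo * n);
        for (int kj = 0; kj < k; ++kj) {
          const int w = wo * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H || w < 0 || w >= W) continue;
            const int src = h + H * (w + W * n);
            const int rbase = C * (ki + k * kj);
            for (int c = 0; c < C; ++c)
              cols(c + rbase, q) = x(c, src);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  NumericMatrix x(C, H * W * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int q = ho + Ho * (wo + Wo * n);
        for (int kj = 0; kj < k; ++kj) {
          const int w = wo * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H || w < 0 || w >= W) continue;
            const int dst = h + H * (w + W * n);
            const int rbase = C * (ki + k * kj);
            for (int c = 0; c < C; ++c)
              x(c, dst) += cols(c + rbase, q);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& x, int C, int H, int W, int N,
                     int k, int stride, int pad) {
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  NumericMatrix out(C, Ho * Wo * N);
  IntegerMatrix idx(C, Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int q = ho + Ho * (wo + Wo * n);
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          int best_at = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              const int src = h + H * (w + W * n);
              const double v = x(c, src);
              if (v > best) { best = v; best_at = src; }
            }
          }
          out(c, q) = best;
          idx(c, q) = best_at;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx,
                      _["H"] = Ho, _["W"] = Wo);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dout,
                              const IntegerMatrix& idx, int C, int in_cols) {
  NumericMatrix dx(C, in_cols);
  const int Q = dout.ncol();
  for (int q = 0; q < Q; ++q)
    for (int c = 0; c < C; ++c)
      dx(c, idx(c, q)) += dout(c, q);
  return dx;
}

// Global average + max pooling per (channel, sample); argmax recorded as the
// spatial offset (0..HW-1) within each sample block for gradient routing.
// [[Rcpp::export]]
List cpp_avgmax_pool(const NumericMatrix& x, int C, int HW, int N) {
  NumericMatrix avg(C, N), mx(C, N);
  IntegerMatrix amax(C, N);
  for (int n = 0; n < N; ++n) {
    const int base = HW * n;
    for (int c = 0; c < C; ++c) {
      double s = 0.0, best = R_NegInf;
      int at = 0;
      for (int p = 0; p < HW; ++p) {
        const double v = x(c, base + p);
        s += v;
        if (v > best) { best = v; at = p; }
      }
      avg(c, n) = s / HW;
      mx(c, n) = best;
      amax(c, n) = at;
    }
  }
  return List::create(_["avg"] = avg, _["max"] = mx, _["argmax"] = amax);
}

// y[c, p + HW*n] = x[c, p + HW*n] * omega[c, n]
// [[Rcpp::export]]
NumericMatrix cpp_scale_channels(const NumericMatrix& x,
                                 const NumericMatrix& omega, int HW) {
  const int C = x.nrow();
  const int N = omega.ncol();
  NumericMatrix y(C, x.ncol());
  for (int n = 0; n < N; ++n) {
    const int base = HW * n;
    for (int p = 0; p < HW; ++p)
      for (int c = 0; c < C; ++c)
        y(c, base + p) = x(c, base + p) * omega(c, n);
  }
  return y;
}

// d[c, n] = sum_p a[c, p + HW*n] * b[c, p + HW*n]
// [[Rcpp::export]]
NumericMatrix cpp_channel_dot(const NumericMatrix& a, const NumericMatrix& b,
                              int HW, int N) {
  const int C = a.nrow();
  NumericMatrix d(C, N);
  for (int n = 0; n < N; ++n) {
    const int base = HW * n;
    for (int p = 0; p < HW; ++p)
      for (int c = 0; c < C; ++c)
        d(c, n) += a(c, base + p) * b(c, base + p);
  }
  return d;
}
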
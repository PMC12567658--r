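#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are numeric arrays with dim c(H, W, C), column-major, so the
// element (h, w, c) lives at h + H*w + H*W*c (zero-based). im2col emits one row
// per output pixel (ho + Ho*wo) and one column per (ky, kx, c) with ky fastest,
// matching the (k*k*cin) x cout weight matrices used by the conv layers.

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int k, int s, int p) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  const int P = Ho * Wo, Q = k * k * C;
  NumericMatrix cols(P, Q);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int q = ky + k * kx + k * k * c;
        double* col = cp + (size_t)P * q;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kx;
          if (wi < 0 || wi >= W) continue;
          const double* xw = xc + (size_t)H * wi;
          double* colw = col + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + ky;
            if (hi >= 0 && hi < H) colw[ho] = xw[hi];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int k, int s, int p) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  const int P = Ho * Wo;
  NumericVector x((size_t)H * W * C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)H * W * c;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int q = ky + k * kx + k * k * c;
        const double* col = cp + (size_t)P * q;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kx;
          if (wi < 0 || wi >= W) continue;
          double* xw = xc + (size_t)H * wi;
          const double* colw = col + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + ky;
            if (hi >= 0 && hi < H) xw[hi] += colw[ho];
          }
        }
      }
    }
  }
  return x;
}

// Depthwise k x k convolution, weights dim c(k, k, C), no bias (added in R).
// [[Rcpp::export]]
NumericVector cpp_dwconv(NumericVector x, NumericVector w,
                         int H, int W, int C, int k, int s, int p) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector y((size_t)Ho * Wo * C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    const double* wc = wp + (size_t)k * k * c;
    double* yc = yp + (size_t)Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int kx = 0; kx < k; ++kx) {
          const int wi = wo * s - p + kx;
          if (wi < 0 || wi >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int hi = ho * s - p + ky;
            if (hi < 0 || hi >= H) continue;
            acc += xc[hi + (size_t)H * wi] * wc[ky + k * kx];
          }
        }
        yc[ho + (size_t)Ho * wo] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector dy, NumericVector x, NumericVector w,
                    int H, int W, int C, int k, int s, int p) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector dx((size_t)H * W * C), dw((size_t)k * k * C);
  const double* dyp = dy.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int c = 0; c < C; ++c) {
    const double* dyc = dyp + (size_t)Ho * Wo * c;
    const double* xc = xp + (size_t)H * W * c;
    const double* wc = wp + (size_t)k * k * c;
    double* dxc = dxp + (size_t)H * W * c;
    double* dwc = dwp + (size_t)k * k * c;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dyc[ho + (size_t)Ho * wo];
        if (g == 0.0) continue;
        for (int kx = 0; kx < k; ++kx) {
          const int wi = wo * s - p + kx;
          if (wi < 0 || wi >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int hi = ho * s - p + ky;
            if (hi < 0 || hi >= H) continue;
            dxc[hi + (size_t)H * wi] += g * wc[ky + k * kx];
            dwc[ky + k * kx] += g * xc[hi + (size_t)H * wi];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling with -Inf padding; argmax indices (1-based into x) for backward.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C, int k, int s, int p) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector y((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    const size_t off = (size_t)Ho * Wo * c;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int bi = -1;
        for (int kx = 0; kx < k; ++kx) {
          const int wi = wo * s - p + kx;
          if (wi < 0 || wi >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int hi = ho * s - p + ky;
            if (hi < 0 || hi >= H) continue;
            const double v = xc[hi + (size_t)H * wi];
            if (v > best) { best = v; bi = hi + H * wi; }
          }
        }
        y[off + ho + (size_t)Ho * wo] = best;
        idx[off + ho + (size_t)Ho * wo] = bi + H * W * c + 1;  // 1-based
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}
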
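#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are C x (H*W) matrices; spatial index s = x*H + y (0-based),
// i.e. the column-major order of an H x W matrix, so matrix(x[c, ], H, W)
// recovers the per-channel image in R.

static inline int reflect_idx(int i, int n) {
  // mirror without repeating the edge sample (-1 -> 1, n -> n-2)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int k,
                         int stride, int pad, int pad_mode) {
  const int C = x.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int nrow = C * k * k;
  NumericMatrix out(nrow, Ho * Wo);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int xo = 0; xo < Wo; ++xo) {
    for (int yo = 0; yo < Ho; ++yo) {
      double* ocol = op + (R_xlen_t)(xo * Ho + yo) * nrow;
      for (int kj = 0; kj < k; ++kj) {
        int xi = xo * stride - pad + kj;
        bool xin = (xi >= 0 && xi < W);
        int xr = pad_mode == 1 ? reflect_idx(xi, W) : xi;
        for (int ki = 0; ki < k; ++ki) {
          int yi = yo * stride - pad + ki;
          bool yin = (yi >= 0 && yi < H);
          int yr = pad_mode == 1 ? reflect_idx(yi, H) : yi;
          double* od = ocol + (kj * k + ki) * C;
          if ((xin && yin) || pad_mode == 1) {
            const double* xs = xp + (R_xlen_t)(xr * H + yr) * C;
            for (int c = 0; c < C; ++c) od[c] = xs[c];
          }
          // zero padding: leave zeros
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int C, int H, int W,
                         int k, int stride, int pad, int pad_mode) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int nrow = C * k * k;
  NumericMatrix out(C, H * W);
  const double* cp = REAL(cols);
  double* op = REAL(out);
  for (int xo = 0; xo < Wo; ++xo) {
    for (int yo = 0; yo < Ho; ++yo) {
      const double* ccol = cp + (R_xlen_t)(xo * Ho + yo) * nrow;
      for (int kj = 0; kj < k; ++kj) {
        int xi = xo * stride - pad + kj;
        bool xin = (xi >= 0 && xi < W);
        if (!xin && pad_mode != 1) continue;
        int xr = pad_mode == 1 ? reflect_idx(xi, W) : xi;
        for (int ki = 0; ki < k; ++ki) {
          int yi = yo * stride - pad + ki;
          bool yin = (yi >= 0 && yi < H);
          if (!yin && pad_mode != 1) continue;
          int yr = pad_mode == 1 ? reflect_idx(yi, H) : yi;
          const double* cd = ccol + (kj * k + ki) * C;
          double* od = op + (R_xlen_t)(xr * H + yr) * C;
          for (int c = 0; c < C; ++c) od[c] += cd[c];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample2(const NumericMatrix& x, int H, int W) {
  const int C = x.nrow();
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix out(C, H2 * W2);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int x2 = 0; x2 < W2; ++x2) {
    const int xi = x2 / 2;
    for (int y2 = 0; y2 < H2; ++y2) {
      const double* xs = xp + (R_xlen_t)(xi * H + y2 / 2) * C;
      double* od = op + (R_xlen_t)(x2 * H2 + y2) * C;
      for (int c = 0; c < C; ++c) od[c] = xs[c];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample2_back(const NumericMatrix& g, int H, int W) {
  // H, W are the *input* (pre-upsampling) dims
  const int C = g.nrow();
  const int H2 = 2 * H, W2 = 2 * W;
  NumericMatrix out(C, H * W);
  const double* gp = REAL(g);
  double* op = REAL(out);
  for (int x2 = 0; x2 < W2; ++x2) {
    const int xi = x2 / 2;
    for (int y2 = 0; y2 < H2; ++y2) {
      const double* gd = gp + (R_xlen_t)(x2 * H2 + y2) * C;
      double* od = op + (R_xlen_t)(xi * H + y2 / 2) * C;
      for (int c = 0; c < C; ++c) od[c] += gd[c];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_warp_bilinear(const NumericVector& img, int H, int W, int C,
                                const NumericMatrix& Hinv, int outH, int outW,
                                const NumericVector& fill) {
  // img: H x W x C array (R column-major). Output pixel (x, y) samples the
  // source at Hinv %*% (x, y, 1), pixel centres at integer 0-based coords.
  NumericVector out(outH * outW * C);
  for (int x = 0; x < outW; ++x) {
    for (int y = 0; y < outH; ++y) {
      double xs = Hinv(0, 0) * x + Hinv(0, 1) * y + Hinv(0, 2);
      double ys = Hinv(1, 0) * x + Hinv(1, 1) * y + Hinv(1, 2);
      double w  = Hinv(2, 0) * x + Hinv(2, 1) * y + Hinv(2, 2);
      xs /= w; ys /= w;
      if (xs >= 0.0 && xs <= W - 1.0 && ys >= 0.0 && ys <= H - 1.0) {
        int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
        double fx = xs - x0, fy = ys - y0;
        for (int c = 0; c < C; ++c) {
          const double* pc = &img[(R_xlen_t)c * H * W];
          double v00 = pc[x0 * H + y0], v10 = pc[x1 * H + y0];
          double v01 = pc[x0 * H + y1], v11 = pc[x1 * H + y1];
          double v = (1 - fy) * ((1 - fx) * v00 + fx * v10) +
                     fy * ((1 - fx) * v01 + fx * v11);
          out[(R_xlen_t)c * outH * outW + x * outH + y] = v;
        }
      } else {
        for (int c = 0; c < C; ++c)
          out[(R_xlen_t)c * outH * outW + x * outH + y] =
            fill[c % fill.size()];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(outH, outW, C);
  return out;
}

// y = (x - rowmean) / sqrt(rowvar + eps), returned with the scale so the
// backward pass can reuse it: list(y, inv_sd)
// [[Rcpp::export]]
List cpp_instance_norm(const NumericMatrix& x, double eps) {
  const int C = x.nrow();
  const R_xlen_t S = x.ncol();
  NumericMatrix y(C, S);
  NumericVector inv_sd(C), mu(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) { mu[c] = 0.0; }
  for (R_xlen_t s = 0; s < S; ++s) {
    const double* xc = xp + s * C;
    for (int c = 0; c < C; ++c) mu[c] += xc[c];
  }
  for (int c = 0; c < C; ++c) mu[c] /= (double)S;
  std::vector<double> var(C, 0.0);
  for (R_xlen_t s = 0; s < S; ++s) {
    const double* xc = xp + s * C;
    for (int c = 0; c < C; ++c) {
      double d = xc[c] - mu[c];
      var[c] += d * d;
    }
  }
  for (int c = 0; c < C; ++c) inv_sd[c] = 1.0 / std::sqrt(var[c] / S + eps);
  for (R_xlen_t s = 0; s < S; ++s) {
    const double* xc = xp + s * C;
    double* yc = yp + s * C;
    for (int c = 0; c < C; ++c) yc[c] = (xc[c] - mu[c]) * inv_sd[c];
  }
  return List::create(_["y"] = y, _["inv_sd"] = inv_sd);
}

// gradient of instance norm: (g - rowmean(g) - y * rowmean(g*y)) * inv_sd
// [[Rcpp::export]]
NumericMatrix cpp_instance_norm_back(const NumericMatrix& g,
                                     const NumericMatrix& y,
                                     const NumericVector& inv_sd) {
  const int C = g.nrow();
  const R_xlen_t S = g.ncol();
  NumericMatrix out(C, S);
  const double* gp = REAL(g);
  const double* yp = REAL(y);
  double* op = REAL(out);
  std::vector<double> mg(C, 0.0), mgy(C, 0.0);
  for (R_xlen_t s = 0; s < S; ++s) {
    const double* gc = gp + s * C;
    const double* yc = yp + s * C;
    for (int c = 0; c < C; ++c) {
      mg[c] += gc[c];
      mgy[c] += gc[c] * yc[c];
    }
  }
  for (int c = 0; c < C; ++c) { mg[c] /= (double)S; mgy[c] /= (double)S; }
  for (R_xlen_t s = 0; s < S; ++s) {
    const double* gc = gp + s * C;
    const double* yc = yp + s * C;
    double* oc = op + s * C;
    for (int c = 0; c < C; ++c)
      oc[c] = (gc[c] - mg[c] - yc[c] * mgy[c]) * inv_sd[c];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu(const NumericMatrix& x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0.0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_back(const NumericMatrix& g, const NumericMatrix& y) {
  NumericMatrix out(g.nrow(), g.ncol());
  const double* gp = REAL(g);
  const double* yp = REAL(y);
  double* op = REAL(out);
  const R_xlen_t n = (R_xlen_t)g.nrow() * g.ncol();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = yp[i] > 0.0 ? gp[i] : 0.0;
  return out;
}
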
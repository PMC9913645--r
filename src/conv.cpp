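// Compiled kernels for the convolutional backbone: tiled direct convolution
// (im2col tiles stay cache-resident, matrix products via BLAS dgemm), layout
// conversion, and fused batch-norm (+ReLU) passes.
//
// Layout contract (shared with the R side):
//  - "tall":  (C*H*W) x B, channel fastest, then row, then column
//             (inter-layer format on the forward path);
//  - "pbc":   (P*B) x C, rows = (image-major, position row-fastest),
//             columns = channels (format of conv outputs / batch-norm and
//             of inter-layer gradients on the backward path);
//  - conv weights: (C*k*k) x C_out, patch elements channel-fastest then
//    kernel row then kernel column.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>
using namespace Rcpp;

// columns of the im2col matrix for output grid columns [wo0, wo1), all rows
static void im2col_tile(const double* xb, int C, int H, int W, int k,
                        int stride, int pad, int Ho, int wo0, int wo1,
                        double* cols) {
  const int ck2 = C * k * k;
  double* oc = cols;
  for (int wo = wo0; wo < wo1; ++wo) {
    const int c0 = wo * stride - pad;
    for (int ro = 0; ro < Ho; ++ro, oc += ck2) {
      const int r0 = ro * stride - pad;
      for (int kc = 0; kc < k; ++kc) {
        const int cc = c0 + kc;
        for (int kr = 0; kr < k; ++kr) {
          const int rr = r0 + kr;
          double* dst = oc + (size_t)(kc * k + kr) * C;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W)
            std::memset(dst, 0, C * sizeof(double));
          else
            std::memcpy(dst, xb + ((size_t)cc * H + rr) * C, C * sizeof(double));
        }
      }
    }
  }
}

static int strip_cols(int Ho) {
  int s = 1024 / Ho;
  if (s < 1) s = 1;
  return s;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& x, const NumericMatrix& Wm,
                           int C, int H, int W, int k, int stride, int pad) {
  const int B = x.ncol();
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  const int P = Ho * Wo, ck2 = C * k * k, Cout = Wm.ncol();
  const size_t PB = (size_t)P * B;
  NumericMatrix out(PB, Cout);
  const int strip = strip_cols(Ho), Tmax = strip * Ho;
  std::vector<double> cols((size_t)ck2 * Tmax), otile((size_t)Tmax * Cout);
  const double one = 1.0, zero = 0.0;
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)b * C * H * W;
    for (int wo0 = 0; wo0 < Wo; wo0 += strip) {
      const int wo1 = wo0 + strip > Wo ? Wo : wo0 + strip;
      const int T = (wo1 - wo0) * Ho;
      im2col_tile(xb, C, H, W, k, stride, pad, Ho, wo0, wo1, cols.data());
      F77_CALL(dgemm)("T", "N", &T, &Cout, &ck2, &one, cols.data(), &ck2,
                      Wm.begin(), &ck2, &zero, otile.data(), &T FCONE FCONE);
      for (int co = 0; co < Cout; ++co)
        std::memcpy(out.begin() + (size_t)co * PB + (size_t)b * P +
                        (size_t)wo0 * Ho,
                    otile.data() + (size_t)co * T, (size_t)T * sizeof(double));
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const NumericMatrix& x, const NumericMatrix& Wm,
                  const NumericMatrix& dout, int C, int H, int W, int k,
                  int stride, int pad, bool want_dx) {
  const int B = x.ncol();
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  const int P = Ho * Wo, ck2 = C * k * k, Cout = Wm.ncol();
  const size_t PB = (size_t)P * B;
  const size_t Pin = (size_t)H * W;
  NumericMatrix dW(ck2, Cout);
  NumericMatrix dx(want_dx ? Pin * B : 1, want_dx ? C : 1);
  const int strip = strip_cols(Ho), Tmax = strip * Ho;
  std::vector<double> cols((size_t)ck2 * Tmax), dtile((size_t)Tmax * Cout),
      dcols((size_t)ck2 * Tmax);
  const double one = 1.0, zero = 0.0;
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)b * C * H * W;
    double* dxb = want_dx ? dx.begin() + (size_t)b * Pin : (double*)0;
    for (int wo0 = 0; wo0 < Wo; wo0 += strip) {
      const int wo1 = wo0 + strip > Wo ? Wo : wo0 + strip;
      const int T = (wo1 - wo0) * Ho;
      im2col_tile(xb, C, H, W, k, stride, pad, Ho, wo0, wo1, cols.data());
      for (int co = 0; co < Cout; ++co)
        std::memcpy(dtile.data() + (size_t)co * T,
                    dout.begin() + (size_t)co * PB + (size_t)b * P +
                        (size_t)wo0 * Ho,
                    (size_t)T * sizeof(double));
      F77_CALL(dgemm)("N", "N", &ck2, &Cout, &T, &one, cols.data(), &ck2,
                      dtile.data(), &T, &one, dW.begin(), &ck2 FCONE FCONE);
      if (want_dx) {
        F77_CALL(dgemm)("N", "T", &ck2, &T, &Cout, &one, Wm.begin(), &ck2,
                        dtile.data(), &T, &zero, dcols.data(), &ck2 FCONE FCONE);
        const double* dc = dcols.data();
        for (int wo = wo0; wo < wo1; ++wo) {
          const int c0 = wo * stride - pad;
          for (int ro = 0; ro < Ho; ++ro, dc += ck2) {
            const int r0 = ro * stride - pad;
            for (int kc = 0; kc < k; ++kc) {
              const int cc = c0 + kc;
              if (cc < 0 || cc >= W) continue;
              for (int kr = 0; kr < k; ++kr) {
                const int rr = r0 + kr;
                if (rr < 0 || rr >= H) continue;
                const double* src = dc + (size_t)(kc * k + kr) * C;
                const size_t base = (size_t)cc * H + rr;
                for (int c = 0; c < C; ++c)
                  dxb[(size_t)c * Pin * B + base] += src[c];
              }
            }
          }
        }
      }
    }
  }
  if (want_dx) return List::create(_["dW"] = dW, _["dx"] = dx);
  return List::create(_["dW"] = dW, _["dx"] = R_NilValue);
}

// Loop order keeps one contiguous stream on the tall side and C parallel
// sequential streams on the pbc side.

// [[Rcpp::export]]
NumericMatrix cpp_pbc2tall(const NumericMatrix& x, int C, int P, int B) {
  NumericMatrix out((size_t)C * P, B);
  const double* xp = x.begin();
  double* op = out.begin();
  const size_t PB = (size_t)P * B;
  for (int b = 0; b < B; ++b) {
    const double* sb = xp + (size_t)b * P;
    double* ob = op + (size_t)b * C * P;
    for (int p = 0; p < P; ++p) {
      double* dst = ob + (size_t)p * C;
      const double* src = sb + p;
      for (int c = 0; c < C; ++c) dst[c] = src[(size_t)c * PB];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_tall2pbc(const NumericMatrix& x, int C, int P, int B) {
  NumericMatrix out((size_t)P * B, C);
  const double* xp = x.begin();
  double* op = out.begin();
  const size_t PB = (size_t)P * B;
  for (int b = 0; b < B; ++b) {
    const double* sb = xp + (size_t)b * C * P;
    double* ob = op + (size_t)b * P;
    for (int p = 0; p < P; ++p) {
      const double* src = sb + (size_t)p * C;
      double* dst = ob + p;
      for (int c = 0; c < C; ++c) dst[(size_t)c * PB] = src[c];
    }
  }
  return out;
}

// per-column mean and biased variance, single pass
// [[Rcpp::export]]
NumericMatrix cpp_colstats(const NumericMatrix& x) {
  const int N = x.nrow(), C = x.ncol();
  NumericMatrix out(2, C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* col = xp + (size_t)c * N;
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < N; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    const double m = s / N;
    double v = s2 / N - m * m;
    out(0, c) = m;
    out(1, c) = v > 0 ? v : 0.0;
  }
  return out;
}

// y = g * (x - m) * istd + b, optionally ReLU-ed; xhat returned for backward
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericMatrix& x, const NumericVector& g,
                const NumericVector& b, const NumericVector& m,
                const NumericVector& istd, bool relu) {
  const int N = x.nrow(), C = x.ncol();
  NumericMatrix y(N, C), xhat(N, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double mc = m[c], ic = istd[c], gc = g[c], bc = b[c];
    const double* col = xp + (size_t)c * N;
    double* yc = yp + (size_t)c * N;
    double* hc = hp + (size_t)c * N;
    for (int i = 0; i < N; ++i) {
      const double h = (col[i] - mc) * ic;
      hc[i] = h;
      double v = gc * h + bc;
      if (relu && v < 0) v = 0.0;
      yc[i] = v;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// fused batch-norm backward (training statistics); if y is given, dy is
// first gated by the ReLU mask (y > 0)
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dy, const NumericMatrix& xhat,
                Nullable<NumericMatrix> y, const NumericVector& g,
                const NumericVector& istd) {
  const int N = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(N, C);
  NumericVector dg(C), db(C);
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  const double* yp = y.isNotNull() ? NumericMatrix(y).begin() : (double*)0;
  double* xp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* dc = dp + (size_t)c * N;
    const double* hc = hp + (size_t)c * N;
    const double* yc = yp ? yp + (size_t)c * N : (double*)0;
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < N; ++i) {
      const double d = yc ? (yc[i] > 0 ? dc[i] : 0.0) : dc[i];
      s1 += d;
      s2 += d * hc[i];
    }
    db[c] = s1;
    dg[c] = s2;
    const double gc = g[c], ic = istd[c];
    const double m1 = s1 / N, m2 = s2 / N;
    double* xc = xp + (size_t)c * N;
    for (int i = 0; i < N; ++i) {
      const double d = yc ? (yc[i] > 0 ? dc[i] : 0.0) : dc[i];
      xc[i] = ic * (gc * d - gc * m1 - hc[i] * gc * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}
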
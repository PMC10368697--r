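// Dense compute kernels for the 3D U-Net: same-padded k^3 convolution via
// im2col + single-precision GEMM, 2x2x2 max pooling and nearest
// up-sampling. Tensor layout throughout: column-major R arrays [X, Y, Z, C, N].
// im2col runs over a zero-padded staging copy so the inner loops are
// branch-free contiguous copies; large scratch buffers are reused across
// calls.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static std::vector<float> buf_col, buf_gcol, buf_pad, buf_go, buf_w;

static float* grow(std::vector<float>& b, size_t n) {
  if (b.size() < n) b.resize(n);
  return b.data();
}

// Convert [X,Y,Z,C,N] doubles into a zero-padded float staging buffer of
// shape [Xp,Yp,Zp] per (c,n) plane, Xp = X + 2*pad.
static float* pad_convert(const double* x, int X, int Y, int Z, int C, int N,
                          int pad) {
  const int Xp = X + 2 * pad, Yp = Y + 2 * pad, Zp = Z + 2 * pad;
  const size_t plane = (size_t)Xp * Yp * Zp;
  float* P = grow(buf_pad, plane * C * N);
  if (pad > 0) std::fill(P, P + plane * C * N, 0.0f);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x + (size_t)X * Y * Z * (c + (size_t)C * n);
      float* dstp = P + plane * (c + (size_t)C * n);
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y) {
          float* d = dstp + pad + (size_t)Xp * ((y + pad) + (size_t)Yp * (z + pad));
          const double* s = src + (size_t)X * (y + (size_t)Y * z);
          for (int xx = 0; xx < X; ++xx) d[xx] = (float)s[xx];
        }
    }
  return P;
}

// Fill the im2col matrix (V rows, k^3*C columns) from the padded buffer.
static float* fill_col(const float* P, int X, int Y, int Z, int C, int N,
                       int k, int pad) {
  const int Xp = X + 2 * pad, Yp = Y + 2 * pad, Zp = Z + 2 * pad;
  const size_t plane = (size_t)Xp * Yp * Zp;
  const size_t V = (size_t)X * Y * Z * N;
  const size_t K = (size_t)k * k * k * C;
  float* col = grow(buf_col, V * K);
  for (int c = 0; c < C; ++c)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const size_t ci = kx + (size_t)k * (ky + (size_t)k * (kz + (size_t)k * c));
          float* dst = col + ci * V;
          for (int n = 0; n < N; ++n) {
            const float* Pp = P + plane * (c + (size_t)C * n);
            for (int z = 0; z < Z; ++z)
              for (int y = 0; y < Y; ++y) {
                const float* s = Pp + kx +
                  (size_t)Xp * ((y + ky) + (size_t)Yp * (z + kz));
                std::copy(s, s + X, dst);
                dst += X;
              }
          }
        }
  return col;
}

// [[Rcpp::export]]
List conv3d_fw(NumericVector x, IntegerVector dims, NumericMatrix w,
               NumericVector b, int k, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], N = dims[4];
  const int Cout = w.ncol();
  const size_t XYZ = (size_t)X * Y * Z;
  const size_t V = XYZ * N;
  const size_t K = (size_t)k * k * k * C;
  const float* P = pad_convert(REAL(x), X, Y, Z, C, N, pad);
  float* colp = fill_col(P, X, Y, Z, C, N, k, pad);
  arma::fmat col(colp, V, K, false, true);
  float* wp = grow(buf_w, K * Cout);
  for (size_t i = 0; i < K * Cout; ++i) wp[i] = (float)w[i];
  arma::fmat Wf(wp, K, Cout, false, true);
  arma::fmat out = col * Wf;
  NumericVector res((R_xlen_t)(XYZ * Cout * N));
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const float* src = out.colptr(co) + XYZ * n;
      double* dst = REAL(res) + XYZ * (co + (size_t)Cout * n);
      const double bb = b[co];
      for (size_t i = 0; i < XYZ; ++i) dst[i] = (double)src[i] + bb;
    }
  res.attr("dim") = IntegerVector::create(X, Y, Z, Cout, N);
  return List::create(_["out"] = res);
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, IntegerVector dims, NumericVector grad_out,
               NumericMatrix w, int k, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], N = dims[4];
  const int Cout = w.ncol();
  const size_t XYZ = (size_t)X * Y * Z;
  const size_t V = XYZ * N;
  const size_t K = (size_t)k * k * k * C;
  float* gop = grow(buf_go, V * Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = REAL(grad_out) + XYZ * (co + (size_t)Cout * n);
      float* dst = gop + co * V + XYZ * n;
      for (size_t i = 0; i < XYZ; ++i) dst[i] = (float)src[i];
    }
  arma::fmat go(gop, V, Cout, false, true);
  const float* P = pad_convert(REAL(x), X, Y, Z, C, N, pad);
  float* colp = fill_col(P, X, Y, Z, C, N, k, pad);
  arma::fmat col(colp, V, K, false, true);
  float* wp = grow(buf_w, K * Cout);
  for (size_t i = 0; i < K * Cout; ++i) wp[i] = (float)w[i];
  arma::fmat Wf(wp, K, Cout, false, true);
  arma::fmat gw = col.t() * go;
  float* gcp = grow(buf_gcol, V * K);
  arma::fmat gcol(gcp, V, K, false, true);
  gcol = go * Wf.t();
  NumericMatrix gwR(w.nrow(), w.ncol());
  for (size_t j = 0; j < (size_t)Cout; ++j)
    for (size_t i = 0; i < K; ++i) gwR(i, j) = gw(i, j);
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(go.col(co));
  // col2im: accumulate gcol into a padded float buffer, then strip padding
  const int Xp = X + 2 * pad, Yp = Y + 2 * pad, Zp = Z + 2 * pad;
  const size_t plane = (size_t)Xp * Yp * Zp;
  float* acc = grow(buf_pad, plane * C * N);
  std::fill(acc, acc + plane * C * N, 0.0f);
  for (int c = 0; c < C; ++c)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const size_t ci = kx + (size_t)k * (ky + (size_t)k * (kz + (size_t)k * c));
          const float* src = gcp + ci * V;
          for (int n = 0; n < N; ++n) {
            float* Pp = acc + plane * (c + (size_t)C * n);
            for (int z = 0; z < Z; ++z)
              for (int y = 0; y < Y; ++y) {
                float* d = Pp + kx +
                  (size_t)Xp * ((y + ky) + (size_t)Yp * (z + kz));
                for (int xx = 0; xx < X; ++xx) d[xx] += src[xx];
                src += X;
              }
          }
        }
  NumericVector gx((R_xlen_t)(XYZ * C * N));
  double* gxp = REAL(gx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* Pp = acc + plane * (c + (size_t)C * n);
      double* dst = gxp + XYZ * (c + (size_t)C * n);
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y) {
          const float* s = Pp + pad + (size_t)Xp * ((y + pad) + (size_t)Yp * (z + pad));
          double* dd = dst + (size_t)X * (y + (size_t)Y * z);
          for (int xx = 0; xx < X; ++xx) dd[xx] = (double)s[xx];
        }
    }
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gw"] = gwR, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], N = dims[4];
  const int X2 = X / 2, Y2 = Y / 2, Z2 = Z / 2;
  const size_t XYZ = (size_t)X * Y * Z;
  NumericVector out((R_xlen_t)((size_t)X2 * Y2 * Z2 * C * N));
  IntegerVector idx(out.size());
  const double* xp = REAL(x);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = XYZ * (c + (size_t)C * n);
      for (int z = 0; z < Z2; ++z)
        for (int y = 0; y < Y2; ++y)
          for (int xx = 0; xx < X2; ++xx, ++o) {
            double best = -1e300;
            size_t bi = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const size_t li = off + (2 * xx + dx) +
                    (size_t)X * ((2 * y + dy) + (size_t)Y * (2 * z + dz));
                  if (xp[li] > best) { best = xp[li]; bi = li; }
                }
            out[o] = best;
            idx[o] = (int)bi;
          }
    }
  out.attr("dim") = IntegerVector::create(X2, Y2, Z2, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(NumericVector grad_out, IntegerVector idx,
                           IntegerVector in_dims) {
  size_t n = 1;
  for (int i = 0; i < in_dims.size(); ++i) n *= in_dims[i];
  NumericVector gx((R_xlen_t)n);
  double* g = REAL(gx);
  const double* go = REAL(grad_out);
  const int* ip = INTEGER(idx);
  for (R_xlen_t i = 0; i < idx.size(); ++i) g[ip[i]] += go[i];
  gx.attr("dim") = in_dims;
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample3d_fw(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3], N = dims[4];
  NumericVector out((R_xlen_t)(8 * (size_t)X * Y * Z * C * N));
  const double* xp = REAL(x);
  double* op = REAL(out);
  const size_t X2 = 2 * (size_t)X, Y2 = 2 * (size_t)Y;
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t ooff = X2 * Y2 * 2 * (size_t)Z * (c + (size_t)C * n);
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          for (int xx = 0; xx < X; ++xx, ++i) {
            const double v = xp[i];
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy) {
                size_t base = ooff + 2 * (size_t)xx +
                  X2 * ((2 * y + dy) + Y2 * (2 * z + dz));
                op[base] = v;
                op[base + 1] = v;
              }
          }
    }
  out.attr("dim") = IntegerVector::create(2 * X, 2 * Y, 2 * Z, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample3d_bw(NumericVector grad_out, IntegerVector in_dims) {
  const int X = in_dims[0], Y = in_dims[1], Z = in_dims[2], C = in_dims[3],
            N = in_dims[4];
  NumericVector gx((R_xlen_t)((size_t)X * Y * Z * C * N));
  const double* go = REAL(grad_out);
  double* g = REAL(gx);
  const size_t X2 = 2 * (size_t)X, Y2 = 2 * (size_t)Y;
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t ooff = X2 * Y2 * 2 * (size_t)Z * (c + (size_t)C * n);
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          for (int xx = 0; xx < X; ++xx, ++i) {
            double s = 0.0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy) {
                size_t base = ooff + 2 * (size_t)xx +
                  X2 * ((2 * y + dy) + Y2 * (2 * z + dz));
                s += go[base] + go[base + 1];
              }
            g[i] = s;
          }
    }
  gx.attr("dim") = in_dims;
  return gx;
}

// ---- per-channel elementwise helpers (batch norm, PReLU) -----------------

// out = a[c] * x + b[c]
// [[Rcpp::export]]
NumericVector chan_affine(NumericVector x, IntegerVector dims,
                          NumericVector a, NumericVector b) {
  const size_t sp = (size_t)dims[0] * dims[1] * dims[2];
  const int C = dims[3], N = dims[4];
  NumericVector out(x.size());
  const double* xp = REAL(x);
  double* op = REAL(out);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      for (size_t s = 0; s < sp; ++s, ++i) op[i] = ac * xp[i] + bc;
    }
  out.attr("dim") = dims;
  return out;
}

// out = a[c] * g + b[c] + cc[c] * h   (batch-norm backward combination)
// [[Rcpp::export]]
NumericVector chan_lincomb(NumericVector g, NumericVector h,
                           IntegerVector dims, NumericVector a,
                           NumericVector b, NumericVector cc) {
  const size_t sp = (size_t)dims[0] * dims[1] * dims[2];
  const int C = dims[3], N = dims[4];
  NumericVector out(g.size());
  const double* gp = REAL(g);
  const double* hp = REAL(h);
  double* op = REAL(out);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c], ccc = cc[c];
      for (size_t s = 0; s < sp; ++s, ++i)
        op[i] = ac * gp[i] + bc + ccc * hp[i];
    }
  out.attr("dim") = dims;
  return out;
}

// per-channel sums of x and of x*y (y optional)
// [[Rcpp::export]]
List chan_moments(NumericVector x, IntegerVector dims) {
  const size_t sp = (size_t)dims[0] * dims[1] * dims[2];
  const int C = dims[3], N = dims[4];
  NumericVector s1(C), s2(C);
  const double* xp = REAL(x);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double a = 0, b = 0;
      for (size_t s = 0; s < sp; ++s, ++i) { a += xp[i]; b += xp[i] * xp[i]; }
      s1[c] += a;
      s2[c] += b;
    }
  return List::create(_["sum"] = s1, _["sumsq"] = s2);
}

// [[Rcpp::export]]
NumericVector chan_dot(NumericVector x, NumericVector y, IntegerVector dims) {
  const size_t sp = (size_t)dims[0] * dims[1] * dims[2];
  const int C = dims[3], N = dims[4];
  NumericVector s(C);
  const double* xp = REAL(x);
  const double* yp = REAL(y);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double a = 0;
      for (size_t ss = 0; ss < sp; ++ss, ++i) a += xp[i] * yp[i];
      s[c] += a;
    }
  return s;
}

// [[Rcpp::export]]
NumericVector prelu_fw(NumericVector x, IntegerVector dims, NumericVector a) {
  const size_t sp = (size_t)dims[0] * dims[1] * dims[2];
  const int C = dims[3], N = dims[4];
  NumericVector out(x.size());
  const double* xp = REAL(x);
  double* op = REAL(out);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c];
      for (size_t s = 0; s < sp; ++s, ++i)
        op[i] = xp[i] > 0 ? xp[i] : ac * xp[i];
    }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List prelu_bw(NumericVector x, NumericVector g, IntegerVector dims,
              NumericVector a) {
  const size_t sp = (size_t)dims[0] * dims[1] * dims[2];
  const int C = dims[3], N = dims[4];
  NumericVector gx(x.size()), ga(C);
  const double* xp = REAL(x);
  const double* gp = REAL(g);
  double* op = REAL(gx);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c];
      double acc = 0;
      for (size_t s = 0; s < sp; ++s, ++i) {
        if (xp[i] > 0) op[i] = gp[i];
        else { op[i] = ac * gp[i]; acc += gp[i] * xp[i]; }
      }
      ga[c] += acc;
    }
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["ga"] = ga);
}
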
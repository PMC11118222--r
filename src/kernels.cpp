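#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <cstring>
#include <vector>
#include <memory>
using namespace Rcpp;

// Feature maps are S x C matrices, S = X*Y*Z voxels in column-major
// (x fastest) order. A 3x3x3 convolution (zero padding 1, stride 1 or 2) is
// one GEMM on the im2col-unrolled input: out = cols %*% W + b, with W of
// shape (27*C_in) x C_out and column index k + 27*c_in for kernel offset k
// (x fastest within the 3x3x3 block).

static inline void out_dims(const int* d, int stride, int* o) {
  for (int i = 0; i < 3; ++i) o[i] = (d[i] - 1) / stride + 1;
}

// fill the im2col buffer (So x 27*C, column-major) from x (S x C)
static void im2col_fill(const double* xp, const int* d, int C, int stride,
                        double* cp) {
  const int X = d[0], Y = d[1], Z = d[2];
  int od[3]; out_dims(d, stride, od);
  const int Xo = od[0], Yo = od[1], Zo = od[2];
  const size_t So = (size_t)Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * X * Y * Z;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int k = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          double* col = cp + (size_t)(k + 27 * c) * So;
          // valid xo range: 0 <= xo*stride + kx < X
          int x0 = (kx < 0) ? ((stride == 1) ? 1 : (1 + stride - 1) / stride) : 0;
          int x1 = Xo;
          while (x1 > 0 && (size_t)(x1 - 1) * stride + kx >= (size_t)X) --x1;
          size_t r = 0;
          for (int zo = 0; zo < Zo; ++zo) {
            const int z = zo * stride + kz;
            const bool zok = (z >= 0 && z < Z);
            for (int yo = 0; yo < Yo; ++yo) {
              const int y = yo * stride + ky;
              if (!zok || y < 0 || y >= Y) {
                std::memset(col + r, 0, sizeof(double) * Xo);
                r += Xo;
                continue;
              }
              const double* src = xc + ((size_t)z * Y + y) * X + kx;
              for (int xo = 0; xo < x0; ++xo) col[r + xo] = 0.0;
              if (stride == 1) {
                std::memcpy(col + r + x0, src + x0,
                            sizeof(double) * (size_t)(x1 - x0));
              } else {
                for (int xo = x0; xo < x1; ++xo)
                  col[r + xo] = src[(size_t)xo * stride];
              }
              for (int xo = x1; xo < Xo; ++xo) col[r + xo] = 0.0;
              r += Xo;
            }
          }
        }
  }
}

// scatter-add of the unrolled gradient back onto the input grid (adjoint)
static void col2im_add(const double* cp, const int* d, int C, int stride,
                       double* xp) {
  const int X = d[0], Y = d[1], Z = d[2];
  int od[3]; out_dims(d, stride, od);
  const int Xo = od[0], Yo = od[1], Zo = od[2];
  const size_t So = (size_t)Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)c * X * Y * Z;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int k = (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1);
          const double* col = cp + (size_t)(k + 27 * c) * So;
          int x0 = (kx < 0) ? 1 : 0;
          if (stride != 1 && kx < 0) x0 = 1; // first in-bounds output index
          int x1 = Xo;
          while (x1 > 0 && (size_t)(x1 - 1) * stride + kx >= (size_t)X) --x1;
          size_t r = 0;
          for (int zo = 0; zo < Zo; ++zo) {
            const int z = zo * stride + kz;
            const bool zok = (z >= 0 && z < Z);
            for (int yo = 0; yo < Yo; ++yo, r += Xo) {
              const int y = yo * stride + ky;
              if (!zok || y < 0 || y >= Y) continue;
              double* dst = xc + ((size_t)z * Y + y) * X + kx;
              if (stride == 1) {
                for (int xo = x0; xo < x1; ++xo) dst[xo] += col[r + xo];
              } else {
                for (int xo = x0; xo < x1; ++xo)
                  dst[(size_t)xo * stride] += col[r + xo];
              }
            }
          }
        }
  }
}

// one reusable scratch buffer for the im2col unrolling: R is
// single-threaded, and reusing the allocation avoids repeated large mmaps
static std::vector<double>& cols_buffer(size_t need) {
  static std::vector<double> buf;
  if (buf.size() < need) buf.resize(need);
  return buf;
}

// forward 3x3x3 convolution; the unrolled matrix lives in the scratch
// buffer, so the backward pass recomputes it from the cached input
// [[Rcpp::export]]
NumericMatrix conv3_gemm_fw(const NumericMatrix& x, const IntegerVector& dims,
                            const int stride, const NumericMatrix& W,
                            const NumericVector& b) {
  const int C = x.ncol();
  int d[3] = {dims[0], dims[1], dims[2]};
  int od[3]; out_dims(d, stride, od);
  const int So = od[0] * od[1] * od[2];
  const int K = 27 * C, Cout = W.ncol();
  std::vector<double>& cols = cols_buffer((size_t)So * K);
  im2col_fill(x.begin(), d, C, stride, cols.data());
  NumericMatrix out(no_init(So, Cout));
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &So, &Cout, &K, &one, cols.data(), &So,
                  W.begin(), &K, &zero, out.begin(), &So FCONE FCONE);
  double* op = out.begin();
  for (int j = 0; j < Cout; ++j) {
    const double bj = b[j];
    double* oc = op + (size_t)j * So;
    for (int i = 0; i < So; ++i) oc[i] += bj;
  }
  return out;
}

// backward: recompute the unrolling from the cached input x, then return
// gW, gb and (optionally) the input gradient gx
// [[Rcpp::export]]
List conv3_gemm_bw(const NumericMatrix& x, const IntegerVector& dims,
                   const int stride, const NumericMatrix& W,
                   const NumericMatrix& gout, const bool need_gx) {
  const int So = gout.nrow(), Cout = gout.ncol();
  const int C = x.ncol();
  const int K = 27 * C;
  int d[3] = {dims[0], dims[1], dims[2]};
  const double one = 1.0, zero = 0.0;
  std::vector<double>& cols = cols_buffer((size_t)So * K);
  im2col_fill(x.begin(), d, C, stride, cols.data());
  NumericMatrix gW(no_init(K, Cout));
  F77_CALL(dgemm)("T", "N", &K, &Cout, &So, &one, cols.data(), &So,
                  gout.begin(), &So, &zero, gW.begin(), &K FCONE FCONE);
  NumericVector gb(Cout);
  for (int j = 0; j < Cout; ++j) {
    const double* gc = gout.begin() + (size_t)j * So;
    double s = 0.0;
    for (int i = 0; i < So; ++i) s += gc[i];
    gb[j] = s;
  }
  if (!need_gx)
    return List::create(_["gW"] = gW, _["gb"] = gb);
  // reuse the scratch buffer for the unrolled input gradient
  F77_CALL(dgemm)("N", "T", &So, &K, &Cout, &one, gout.begin(), &So,
                  W.begin(), &K, &zero, cols.data(), &So FCONE FCONE);
  const size_t S = (size_t)d[0] * d[1] * d[2];
  NumericMatrix gx(S, C);
  std::memset(gx.begin(), 0, sizeof(double) * S * C);
  col2im_add(cols.data(), d, C, stride, gx.begin());
  return List::create(_["gW"] = gW, _["gb"] = gb, _["gx"] = gx);
}

// For each row of a (n_a x 3, physical coordinates) return the Euclidean
// distance to the nearest row of b. Used for directed Hausdorff percentiles.
// [[Rcpp::export]]
NumericVector min_dists(const NumericMatrix& a, const NumericMatrix& b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// instance norm forward: per-column standardisation with affine transform;
// returns y plus the cached xhat and inverse std needed by the backward pass
// [[Rcpp::export]]
List instnorm_cpp_fw(const NumericMatrix& x, const NumericVector& gamma,
                     const NumericVector& beta, const double eps) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix y(no_init(n, C)), xhat(no_init(n, C));
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * n;
    double* yc = y.begin() + (size_t)c * n;
    double* hc = xhat.begin() + (size_t)c * n;
    double mu = 0.0;
    for (int i = 0; i < n; ++i) mu += xc[i];
    mu /= n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) { const double d = xc[i] - mu; v += d * d; }
    v /= n;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// instance norm backward
// [[Rcpp::export]]
List instnorm_cpp_bw(const NumericMatrix& xhat, const NumericVector& istd,
                     const NumericVector& gamma, const NumericMatrix& gout) {
  const int n = xhat.nrow(), C = xhat.ncol();
  NumericMatrix gx(no_init(n, C));
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* hc = xhat.begin() + (size_t)c * n;
    const double* gc = gout.begin() + (size_t)c * n;
    double* oc = gx.begin() + (size_t)c * n;
    double sg = 0.0, sgh = 0.0;
    for (int i = 0; i < n; ++i) { sg += gc[i]; sgh += gc[i] * hc[i]; }
    ggamma[c] = sgh;
    gbeta[c] = sg;
    const double g = gamma[c], is = istd[c];
    const double m1 = g * sg / n, m2 = g * sgh / n;
    for (int i = 0; i < n; ++i)
      oc[i] = (g * gc[i] - m1 - hc[i] * m2) * is;
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
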
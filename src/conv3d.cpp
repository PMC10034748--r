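// Zero-padded 3D cross-correlation forward/backward used by the CNN
// regularizer. Each of the k1*k2*k3 kernel offsets contributes one
// shifted-slab GEMM; a single reusable buffer holds the shifted slab so no
// per-call R-level copies accumulate.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>
#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

// copy the slab x shifted by (d1,d2,d3) (zero outside) into buf (V x Ci)
static void fill_slab(const double* x, double* buf,
                      int n1, int n2, int n3, int ci_n,
                      int d1, int d2, int d3) {
  const R_xlen_t V = (R_xlen_t)n1 * n2 * n3;
  int i_lo = std::max(0, -d1), i_hi = std::min(n1, n1 - d1);
  int j_lo = std::max(0, -d2), j_hi = std::min(n2, n2 - d2);
  int k_lo = std::max(0, -d3), k_hi = std::min(n3, n3 - d3);
  std::memset(buf, 0, sizeof(double) * V * ci_n);
  if (i_lo >= i_hi || j_lo >= j_hi || k_lo >= k_hi) return;
  for (int c = 0; c < ci_n; ++c) {
    const double* xs = x + (R_xlen_t)c * V;
    double* bs = buf + (R_xlen_t)c * V;
    for (int k = k_lo; k < k_hi; ++k) {
      for (int j = j_lo; j < j_hi; ++j) {
        R_xlen_t t = ((R_xlen_t)k * n2 + j) * n1 + i_lo;
        R_xlen_t s = ((R_xlen_t)(k + d3) * n2 + (j + d2)) * n1 + (i_lo + d1);
        std::memcpy(bs + t, xs + s, sizeof(double) * (i_hi - i_lo));
      }
    }
  }
}

// accumulate buf (V x Ci) into gx shifted by (d1,d2,d3), dropping out-of-range
static void scatter_slab(double* gx, const double* buf,
                         int n1, int n2, int n3, int ci_n,
                         int d1, int d2, int d3) {
  const R_xlen_t V = (R_xlen_t)n1 * n2 * n3;
  int i_lo = std::max(0, -d1), i_hi = std::min(n1, n1 - d1);
  int j_lo = std::max(0, -d2), j_hi = std::min(n2, n2 - d2);
  int k_lo = std::max(0, -d3), k_hi = std::min(n3, n3 - d3);
  if (i_lo >= i_hi || j_lo >= j_hi || k_lo >= k_hi) return;
  for (int c = 0; c < ci_n; ++c) {
    double* gs = gx + (R_xlen_t)c * V;
    const double* bs = buf + (R_xlen_t)c * V;
    for (int k = k_lo; k < k_hi; ++k) {
      for (int j = j_lo; j < j_hi; ++j) {
        R_xlen_t t = ((R_xlen_t)k * n2 + j) * n1 + i_lo;
        R_xlen_t s = ((R_xlen_t)(k + d3) * n2 + (j + d2)) * n1 + (i_lo + d1);
        const double* b = bs + t;
        double* g = gs + s;
        for (int i = 0; i < i_hi - i_lo; ++i) g[i] += b[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], ci_n = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], co_n = wdim[4];
  const int r1 = (k1 - 1) / 2, r2 = (k2 - 1) / 2, r3 = (k3 - 1) / 2;
  const R_xlen_t V = (R_xlen_t)n1 * n2 * n3;
  const int Vi = (int)V;
  NumericVector out(V * co_n);
  std::vector<double> slab(V * ci_n), wbuf(ci_n * co_n);
  const double one = 1.0, zero_beta = 1.0;
  (void)zero_beta;
  for (int o3 = 0; o3 < k3; ++o3)
    for (int o2 = 0; o2 < k2; ++o2)
      for (int o1 = 0; o1 < k1; ++o1) {
        fill_slab(x.begin(), slab.data(), n1, n2, n3, ci_n,
                  o1 - r1, o2 - r2, o3 - r3);
        for (int co = 0; co < co_n; ++co)
          for (int ci = 0; ci < ci_n; ++ci)
            wbuf[ci + (R_xlen_t)co * ci_n] =
              w[o1 + k1 * (o2 + (R_xlen_t)k2 * (o3 + (R_xlen_t)k3 *
                (ci + (R_xlen_t)ci_n * co)))];
        F77_CALL(dgemm)("N", "N", &Vi, &co_n, &ci_n, &one,
                        slab.data(), &Vi, wbuf.data(), &ci_n, &one,
                        out.begin(), &Vi FCONE FCONE);
      }
  return out;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector g) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], ci_n = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], co_n = wdim[4];
  const int r1 = (k1 - 1) / 2, r2 = (k2 - 1) / 2, r3 = (k3 - 1) / 2;
  const R_xlen_t V = (R_xlen_t)n1 * n2 * n3;
  const int Vi = (int)V;
  NumericVector gx(V * ci_n), gw((R_xlen_t)k1 * k2 * k3 * ci_n * co_n);
  std::vector<double> slab(V * ci_n), wbuf(ci_n * co_n), gwbuf(ci_n * co_n);
  const double one = 1.0, zero = 0.0;
  for (int o3 = 0; o3 < k3; ++o3)
    for (int o2 = 0; o2 < k2; ++o2)
      for (int o1 = 0; o1 < k1; ++o1) {
        const int d1 = o1 - r1, d2 = o2 - r2, d3 = o3 - r3;
        // weight gradient: slab^T * g
        fill_slab(x.begin(), slab.data(), n1, n2, n3, ci_n, d1, d2, d3);
        F77_CALL(dgemm)("T", "N", &ci_n, &co_n, &Vi, &one,
                        slab.data(), &Vi, g.begin(), &Vi, &zero,
                        gwbuf.data(), &ci_n FCONE FCONE);
        for (int co = 0; co < co_n; ++co)
          for (int ci = 0; ci < ci_n; ++ci) {
            gw[o1 + k1 * (o2 + (R_xlen_t)k2 * (o3 + (R_xlen_t)k3 *
              (ci + (R_xlen_t)ci_n * co)))] = gwbuf[ci + (R_xlen_t)co * ci_n];
            wbuf[ci + (R_xlen_t)co * ci_n] =
              w[o1 + k1 * (o2 + (R_xlen_t)k2 * (o3 + (R_xlen_t)k3 *
                (ci + (R_xlen_t)ci_n * co)))];
          }
        // input gradient: (g * w^T) scattered back to the shifted source
        F77_CALL(dgemm)("N", "T", &Vi, &ci_n, &co_n, &one,
                        g.begin(), &Vi, wbuf.data(), &ci_n, &zero,
                        slab.data(), &Vi FCONE FCONE);
        scatter_slab(gx.begin(), slab.data(), n1, n2, n3, ci_n, d1, d2, d3);
      }
  return List::create(Named("gx") = gx, Named("gw") = gw);
}

// [[Rcpp::export]]
NumericVector leaky_relu_cpp(NumericVector x, double slope) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? x[i] : slope * x[i];
  return out;
}

// [[Rcpp::export]]
NumericVector leaky_relu_grad_cpp(NumericVector x, NumericVector g, double slope) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? g[i] : slope * g[i];
  return out;
}
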
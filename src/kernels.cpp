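// Hot inner kernels of the CNN engine. Everything here is a plain memory
// rearrangement or per-column affine map; all heavy arithmetic stays in
// BLAS on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// Build the im2col matrix from a padded feature map.
// xp: padded map as a flat vector with dims (hp, wp, n, c);
// idx: (ho*wo) x (k*k) matrix of 1-based spatial indices into (hp, wp).
// Returns (ho*wo*n) x (k*k*c), rows ordered pixel-fastest then sample,
// columns ordered kernel-offset-fastest then channel.
// [[Rcpp::export]]
NumericMatrix im2col_gather(NumericVector xp, IntegerMatrix idx,
                            int hp, int wp, int n, int c) {
  const int hw = idx.nrow();
  const int kk = idx.ncol();
  const int plane = hp * wp;
  NumericMatrix out(hw * n, kk * c);
  const double* x = xp.begin();
  double* o = out.begin();
  for (int ch = 0; ch < c; ++ch) {
    for (int q = 0; q < kk; ++q) {
      const int* id = &idx(0, q);
      double* col = o + (size_t)(q + kk * ch) * hw * n;
      for (int s = 0; s < n; ++s) {
        const double* base = x + (size_t)plane * (s + (size_t)n * ch);
        double* dst = col + (size_t)hw * s;
        for (int p = 0; p < hw; ++p) dst[p] = base[id[p] - 1];
      }
    }
  }
  return out;
}

// Scatter-add the columns gradient back onto the padded map (inverse of
// im2col_gather). dxcol: (ho*wo*n) x (k*k*c). Returns flat (hp, wp, n, c).
// [[Rcpp::export]]
NumericVector col2im_scatter(NumericMatrix dxcol, IntegerMatrix idx,
                             int hp, int wp, int n, int c) {
  const int hw = idx.nrow();
  const int kk = idx.ncol();
  const int plane = hp * wp;
  NumericVector out((size_t)plane * n * c);
  double* o = out.begin();
  const double* dc = dxcol.begin();
  for (int ch = 0; ch < c; ++ch) {
    for (int q = 0; q < kk; ++q) {
      const int* id = &idx(0, q);
      const double* col = dc + (size_t)(q + kk * ch) * hw * n;
      for (int s = 0; s < n; ++s) {
        double* base = o + (size_t)plane * (s + (size_t)n * ch);
        const double* src = col + (size_t)hw * s;
        for (int p = 0; p < hw; ++p) base[id[p] - 1] += src[p];
      }
    }
  }
  return out;
}

// out[i, j] = x[i, j] * s[j] + b[j] (per-column affine, no temporaries)
// [[Rcpp::export]]
NumericMatrix affine_cols(NumericMatrix x, NumericVector s, NumericVector b) {
  const int m = x.nrow(), cc = x.ncol();
  NumericMatrix out(m, cc);
  for (int j = 0; j < cc; ++j) {
    const double sj = s[j], bj = b[j];
    const double* xi = &x(0, j);
    double* oi = &out(0, j);
    for (int i = 0; i < m; ++i) oi[i] = xi[i] * sj + bj;
  }
  return out;
}

// Training-mode batch-norm input gradient:
// dx[i, j] = gs[j] * (dy[i, j] - mb[j] - xhat[i, j] * mg[j])
// with xhat[i, j] = ctr[i, j] * istd[j].
// [[Rcpp::export]]
NumericMatrix bn_bwd_core(NumericMatrix dy, NumericMatrix ctr,
                          NumericVector istd, NumericVector gs,
                          NumericVector mb, NumericVector mg) {
  const int m = dy.nrow(), cc = dy.ncol();
  NumericMatrix out(m, cc);
  for (int j = 0; j < cc; ++j) {
    const double gj = gs[j], bj = mb[j], mgj = mg[j], isj = istd[j];
    const double* dyj = &dy(0, j);
    const double* cj = &ctr(0, j);
    double* oj = &out(0, j);
    for (int i = 0; i < m; ++i) {
      oj[i] = gj * (dyj[i] - bj - cj[i] * isj * mgj);
    }
  }
  return out;
}
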
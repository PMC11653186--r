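// im2col / col2im kernels for same-padded stride-1 convolution.
//
// Tensor layout is (H, W, N, C) column-major.  The column matrix has rows
// ordered (h, w, n) and columns ordered ((kj, ki) block, then channel),
// matching the conv weight matrix used by the R training loop.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& xp, int Hp, int Wp, int N,
                         int C, int k, int H, int W) {
  NumericMatrix cols((R_xlen_t)H * W * N, (R_xlen_t)k * k * C);
  const double* src = xp.begin();
  double* dst = cols.begin();
  const R_xlen_t col_len = (R_xlen_t)H * W * N;
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) {
      const int blk = j * k + i;
      for (int c = 0; c < C; ++c) {
        double* col = dst + ((R_xlen_t)blk * C + c) * col_len;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const double* s =
              src + i + (R_xlen_t)Hp * ((w + j) + (R_xlen_t)Wp * (n + (R_xlen_t)N * c));
            std::memcpy(col + ((R_xlen_t)n * W + w) * H, s, H * sizeof(double));
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& dcols, int N, int C, int k,
                         int H, int W) {
  const int Hp = H + k - 1, Wp = W + k - 1;
  NumericVector dxp((R_xlen_t)Hp * Wp * N * C);
  double* dst = dxp.begin();
  const double* src = dcols.begin();
  const R_xlen_t col_len = (R_xlen_t)H * W * N;
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) {
      const int blk = j * k + i;
      for (int c = 0; c < C; ++c) {
        const double* col = src + ((R_xlen_t)blk * C + c) * col_len;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            double* d =
              dst + i + (R_xlen_t)Hp * ((w + j) + (R_xlen_t)Wp * (n + (R_xlen_t)N * c));
            const double* s = col + ((R_xlen_t)n * W + w) * H;
            for (int h = 0; h < H; ++h) d[h] += s[h];
          }
        }
      }
    }
  }
  return dxp;
}
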
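#include <Rcpp.h>
using namespace Rcpp;

// Activation layout used throughout the network code: a (B*H*W) x C matrix,
// row r = b*H*W + j*H + i (0-based; i = row index within the image, fastest),
// one column per channel.  A 3x3 "same" convolution is evaluated as an
// im2col gather followed by a BLAS matrix product in R; these two kernels
// implement the gather and its adjoint scatter-add.

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& X, int H, int W, int B) {
  const int HW = H * W;
  const int N = B * HW;
  const int C = X.ncol();
  NumericMatrix col(N, 9 * C);
  const double* x = X.begin();
  double* out = col.begin();
  for (int o = 0; o < 9; ++o) {
    const int di = o % 3 - 1;
    const int dj = o / 3 - 1;
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (std::size_t)N * c;
      double* oc = out + (std::size_t)N * (o * C + c);
      for (int b = 0; b < B; ++b) {
        const int base = b * HW;
        for (int j = 0; j < W; ++j) {
          const int jn = j + dj;
          double* orow = oc + base + j * H;
          if (jn < 0 || jn >= W) {
            for (int i = 0; i < H; ++i) orow[i] = 0.0;
            continue;
          }
          const double* xrow = xc + base + jn * H;
          // interior rows shift by di; edges are zero-padded
          const int i0 = (di < 0) ? 1 : 0;
          const int i1 = (di > 0) ? H - 1 : H;
          if (di < 0) orow[0] = 0.0;
          if (di > 0) orow[H - 1] = 0.0;
          for (int i = i0; i < i1; ++i) orow[i] = xrow[i + di];
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col3: scatter-add a (B*H*W) x (9*C) gradient back onto the
// (B*H*W) x C input layout.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& dcol, int H, int W, int B) {
  const int HW = H * W;
  const int N = B * HW;
  const int C = dcol.ncol() / 9;
  NumericMatrix dX(N, C);
  const double* g = dcol.begin();
  double* out = dX.begin();
  for (int o = 0; o < 9; ++o) {
    const int di = o % 3 - 1;
    const int dj = o / 3 - 1;
    for (int c = 0; c < C; ++c) {
      const double* gc = g + (std::size_t)N * (o * C + c);
      double* oc = out + (std::size_t)N * c;
      for (int b = 0; b < B; ++b) {
        const int base = b * HW;
        for (int j = 0; j < W; ++j) {
          const int jn = j + dj;
          if (jn < 0 || jn >= W) continue;
          const double* grow = gc + base + j * H;
          double* orow = oc + base + jn * H;
          const int i0 = (di < 0) ? 1 : 0;
          const int i1 = (di > 0) ? H - 1 : H;
          for (int i = i0; i < i1; ++i) orow[i + di] += grow[i];
        }
      }
    }
  }
  return dX;
}
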
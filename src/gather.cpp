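// Performance kernels for the 3x3 / pad-1 convolution layers. Feature maps
// are (H*W*N) x C matrices with rows ordered h-fastest, then w, then sample;
// shifting a 3x3 tap is then a contiguous copy of H-|dh| elements per image
// column, which lets the gather (im2col) and its transpose (col2im
// scatter-add) run at memcpy speed.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static const int DH[9] = {-1, 0, 1, -1, 0, 1, -1, 0, 1};
static const int DW[9] = {-1, -1, -1, 0, 0, 0, 1, 1, 1};

// F: (H*W*N) x C -> patches (H*W*N) x (9*C), offset-major blocks of C
// [[Rcpp::export]]
NumericMatrix im2col3x3(const NumericMatrix& F, const int H, const int W,
                        const int N) {
  const int C = F.ncol();
  const R_xlen_t R = (R_xlen_t)H * W * N;
  NumericMatrix out = no_init_matrix(R, 9 * C);
  for (int k = 0; k < 9; ++k) {
    const int dh = DH[k], dw = DW[k];
    const int len = H - std::abs(dh);
    const int dst0 = dh < 0 ? -dh : 0;
    const int src0 = dh > 0 ? dh : 0;
    for (int c = 0; c < C; ++c) {
      const double* fc = &F(0, c);
      double* oc = &out(0, (R_xlen_t)k * C + c);
      for (int n = 0; n < N; ++n) {
        const R_xlen_t base = (R_xlen_t)n * H * W;
        for (int w = 0; w < W; ++w) {
          double* dst = oc + base + (R_xlen_t)w * H;
          const int sw = w + dw;
          if (sw < 0 || sw >= W) {           // zero pad: whole column
            std::memset(dst, 0, sizeof(double) * H);
            continue;
          }
          if (dh < 0) dst[0] = 0.0;          // zero pad: h edge
          else if (dh > 0) dst[H - 1] = 0.0;
          std::memcpy(dst + dst0,
                      fc + base + (R_xlen_t)sw * H + src0,
                      sizeof(double) * len);
        }
      }
    }
  }
  return out;
}

// transpose of im2col3x3: accumulate patch gradients back onto the grid
// [[Rcpp::export]]
NumericMatrix col2im3x3(const NumericMatrix& dX, const int H, const int W,
                        const int N) {
  const int C = dX.ncol() / 9;
  const R_xlen_t R = (R_xlen_t)H * W * N;
  NumericMatrix out(R, C);
  for (int k = 0; k < 9; ++k) {
    const int dh = DH[k], dw = DW[k];
    const int len = H - std::abs(dh);
    const int dst0 = dh < 0 ? -dh : 0;  // rows of dX that carried data
    const int src0 = dh > 0 ? dh : 0;   // rows of the grid they came from
    for (int c = 0; c < C; ++c) {
      const double* gc = &dX(0, (R_xlen_t)k * C + c);
      double* oc = &out(0, c);
      for (int n = 0; n < N; ++n) {
        const R_xlen_t base = (R_xlen_t)n * H * W;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          const double* g = gc + base + (R_xlen_t)w * H + dst0;
          double* o = oc + base + (R_xlen_t)sw * H + src0;
          for (int i = 0; i < len; ++i) o[i] += g[i];
        }
      }
    }
  }
  return out;
}
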
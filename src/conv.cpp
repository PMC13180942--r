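// im2col / col2im kernels for the batched convolution engine. Geometry
// conventions match the R side: activations are H x W x C x B arrays
// (column-major), im2col matrices are (k*k*Cin) x (Hout*Wout*B) with
// sample-contiguous column blocks and kernel rows ordered row-fast,
// then column, then channel.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int h, int w, int cin, int B,
                         int k, int stride, int pad, int hout, int wout) {
  const int K = k * k * cin;
  const int P = hout * wout;
  NumericMatrix out(K, P * B);
  const double *px = x.begin();
  double *po = out.begin();
  const int plane = h * w;
  const int sample = plane * cin;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < wout; ++j) {
      for (int i = 0; i < hout; ++i) {
        const int col = b * P + j * hout + i;
        double *dst = po + (size_t)col * K;
        const int r0 = i * stride - pad;
        const int c0 = j * stride - pad;
        for (int c = 0; c < cin; ++c) {
          const double *src = px + (size_t)b * sample + (size_t)c * plane;
          for (int kc = 0; kc < k; ++kc) {
            const int cc = c0 + kc;
            for (int kr = 0; kr < k; ++kr) {
              const int rr = r0 + kr;
              const int at = c * k * k + kc * k + kr;
              if (rr >= 0 && rr < h && cc >= 0 && cc < w) {
                dst[at] = src[(size_t)cc * h + rr];
              } else {
                dst[at] = 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dxcol, int h, int w, int cin, int B,
                         int k, int stride, int pad, int hout, int wout) {
  const int K = k * k * cin;
  const int P = hout * wout;
  NumericVector dx((size_t)h * w * cin * B);
  dx.attr("dim") = IntegerVector::create(h, w, cin, B);
  double *pd = dx.begin();
  const double *pc = dxcol.begin();
  const int plane = h * w;
  const int sample = plane * cin;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < wout; ++j) {
      for (int i = 0; i < hout; ++i) {
        const int col = b * P + j * hout + i;
        const double *src = pc + (size_t)col * K;
        const int r0 = i * stride - pad;
        const int c0 = j * stride - pad;
        for (int c = 0; c < cin; ++c) {
          double *dst = pd + (size_t)b * sample + (size_t)c * plane;
          for (int kc = 0; kc < k; ++kc) {
            const int cc = c0 + kc;
            if (cc < 0 || cc >= w) continue;
            for (int kr = 0; kr < k; ++kr) {
              const int rr = r0 + kr;
              if (rr < 0 || rr >= h) continue;
              dst[(size_t)cc * h + rr] += src[c * k * k + kc * k + kr];
            }
          }
        }
      }
    }
  }
  return dx;
}
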
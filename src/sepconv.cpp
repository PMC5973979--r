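// Separable 2-D correlation used by the Gaussian filters behind SSIM,
// unsharp masking and the phantom generator. Modes:
//   "valid"        : output (H-k+1) x (W-k+1)
//   "full"         : output (H+k-1) x (W+k-1), zero padding
//   "same_reflect" : output H x W, symmetric (half-sample) boundary
//   "same_zero"    : output H x W, zero boundary
// With a symmetric kernel, "full" is the adjoint of "valid".
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

enum Mode { VALID, FULL, SAME_REFLECT, SAME_ZERO };

inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1-D correlation along columns of src (length n per column)
void corr_cols(const std::vector<double>& src, int n, int ncol,
               const std::vector<double>& ker, Mode mode,
               std::vector<double>& dst, int& nout) {
  const int k = (int)ker.size();
  switch (mode) {
  case VALID: nout = n - k + 1; break;
  case FULL: nout = n + k - 1; break;
  default: nout = n; break;
  }
  if (nout < 1) Rcpp::stop("kernel larger than image in 'valid' mode");
  dst.assign((size_t)nout * ncol, 0.0);
  const int r = (k - 1) / 2;
  for (int c = 0; c < ncol; ++c) {
    const double* s = &src[(size_t)c * n];
    double* d = &dst[(size_t)c * nout];
    for (int o = 0; o < nout; ++o) {
      int start;  // source index aligned with kernel tap 0
      switch (mode) {
      case VALID: start = o; break;
      case FULL: start = o - (k - 1); break;
      default: start = o - r; break;
      }
      double acc = 0.0;
      for (int t = 0; t < k; ++t) {
        int i = start + t;
        if (mode == SAME_REFLECT) {
          i = reflect_idx(i, n);
        } else if (i < 0 || i >= n) {
          continue;
        }
        acc += ker[t] * s[i];
      }
      d[o] = acc;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector kernel,
                          std::string mode) {
  Mode m;
  if (mode == "valid") m = VALID;
  else if (mode == "full") m = FULL;
  else if (mode == "same_reflect") m = SAME_REFLECT;
  else if (mode == "same_zero") m = SAME_ZERO;
  else stop("unknown mode");
  const int H = img.nrow(), W = img.ncol(), k = kernel.size();
  std::vector<double> ker(kernel.begin(), kernel.end());
  std::vector<double> a(img.begin(), img.end());
  std::vector<double> b;
  int H2 = 0, W2 = 0;
  corr_cols(a, H, W, ker, m, b, H2);
  // transpose, filter the other axis, transpose back
  std::vector<double> bt((size_t)W * H2);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H2; ++r)
      bt[(size_t)r * W + c] = b[(size_t)c * H2 + r];
  std::vector<double> ct;
  corr_cols(bt, W, H2, ker, m, ct, W2);
  NumericMatrix out(H2, W2);
  for (int r = 0; r < H2; ++r)
    for (int c = 0; c < W2; ++c)
      out(r, c) = ct[(size_t)r * W2 + c];
  (void)k;
  return out;
}
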
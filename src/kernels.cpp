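#include <Rcpp.h>
using namespace Rcpp;

// im2col for same-padded k x k convolution on an (H*W) x Cin feature matrix
// (pixels column-major, y fastest). Output column layout: offset-major
// blocks of Cin channels, offsets ordered dx (outer) then dy (inner),
// both from -r to r. cpp_col2im is the exact adjoint.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int k) {
  const int HW = H * W, Cin = x.ncol(), r = (k - 1) / 2;
  NumericMatrix out(HW, k * k * Cin);
  double* po = REAL(out);
  const double* px = REAL(x);
  int ko = 0;
  for (int dx = -r; dx <= r; ++dx) {
    for (int dy = -r; dy <= r; ++dy, ++ko) {
      for (int c = 0; c < Cin; ++c) {
        double* dst = po + (size_t)(ko * Cin + c) * HW;
        const double* src = px + (size_t)c * HW;
        for (int xx = 0; xx < W; ++xx) {
          const int sx = xx + dx;
          double* d = dst + (size_t)xx * H;
          if (sx < 0 || sx >= W) {
            for (int y = 0; y < H; ++y) d[y] = 0.0;
            continue;
          }
          const double* s = src + (size_t)sx * H;
          for (int y = 0; y < H; ++y) {
            const int sy = y + dy;
            d[y] = (sy >= 0 && sy < H) ? s[sy] : 0.0;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dA, int H, int W, int k,
                         int Cin) {
  const int HW = H * W, r = (k - 1) / 2;
  NumericMatrix out(HW, Cin);
  double* po = REAL(out);
  const double* pa = REAL(dA);
  int ko = 0;
  for (int dx = -r; dx <= r; ++dx) {
    for (int dy = -r; dy <= r; ++dy, ++ko) {
      for (int c = 0; c < Cin; ++c) {
        const double* src = pa + (size_t)(ko * Cin + c) * HW;
        double* dst = po + (size_t)c * HW;
        for (int xx = 0; xx < W; ++xx) {
          const int sx = xx + dx;
          if (sx < 0 || sx >= W) continue;
          const double* s = src + (size_t)xx * H;
          double* d = dst + (size_t)sx * H;
          for (int y = 0; y < H; ++y) {
            const int sy = y + dy;
            if (sy >= 0 && sy < H) d[sy] += s[y];
          }
        }
      }
    }
  }
  return out;
}

// For every point (row) of a, the Euclidean distance to the nearest point
// of b; rows are physical coordinates in mm. Used by the 95th-percentile
// Hausdorff distance.

// [[Rcpp::export]]
NumericVector cpp_nn_distances(const NumericMatrix& a,
                               const NumericMatrix& b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (b.ncol() != d) stop("coordinate dimensions differ");
  NumericVector out(n);
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int t = 0; t < d; ++t) {
        const double diff = pa[i + (size_t)t * n] - pb[j + (size_t)t * m];
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
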
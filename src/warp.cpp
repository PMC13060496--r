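// Nearest-neighbor label warp: out(x) = in(A (x - c) + c + u(x)), with A a
// 4x4 affine in voxel units, c the volume center and u an optional
// displacement field. Out-of-volume sources map to background (0).

#include <Rcpp.h>
using Rcpp::IntegerVector;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

// [[Rcpp::export]]
IntegerVector nn_warp_cpp(IntegerVector labels, IntegerVector dims,
                          NumericMatrix affine, NumericVector disp,
                          bool has_field) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t n = (size_t)d1 * d2 * d3;
  IntegerVector out(n);
  const double c1 = (d1 + 1) / 2.0, c2 = (d2 + 1) / 2.0, c3 = (d3 + 1) / 2.0;
  const double a11 = affine(0, 0), a12 = affine(0, 1), a13 = affine(0, 2),
               a14 = affine(0, 3);
  const double a21 = affine(1, 0), a22 = affine(1, 1), a23 = affine(1, 2),
               a24 = affine(1, 3);
  const double a31 = affine(2, 0), a32 = affine(2, 1), a33 = affine(2, 2),
               a34 = affine(2, 3);
  const double* u = has_field ? disp.begin() : nullptr;
  const int* lab = labels.begin();
  int* o = out.begin();
  size_t idx = 0;
  for (int k = 1; k <= d3; ++k) {
    const double zc = k - c3;
    for (int j = 1; j <= d2; ++j) {
      const double yc = j - c2;
      for (int i = 1; i <= d1; ++i, ++idx) {
        const double xc = i - c1;
        double sx = a11 * xc + a12 * yc + a13 * zc + a14 + c1;
        double sy = a21 * xc + a22 * yc + a23 * zc + a24 + c2;
        double sz = a31 * xc + a32 * yc + a33 * zc + a34 + c3;
        if (u) {
          sx += u[idx];
          sy += u[idx + n];
          sz += u[idx + 2 * n];
        }
        const int si = (int)std::lround(sx);
        const int sj = (int)std::lround(sy);
        const int sk = (int)std::lround(sz);
        if (si >= 1 && si <= d1 && sj >= 1 && sj <= d2 && sk >= 1 && sk <= d3)
          o[idx] = lab[(size_t)(sk - 1) * d1 * d2 + (size_t)(sj - 1) * d1
                       + (si - 1)];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
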
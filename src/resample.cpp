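// Center-aligned trilinear resampling between isotropic/anisotropic grids.
// Voxel i on axis a sits at physical coordinate (i - (n-1)/2) * spacing, so the
// physical field-of-view center of input and output always coincide; output
// voxels falling outside the input field of view take `fill`.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector vol, IntegerVector dim_in,
                                     NumericVector sp_in, IntegerVector dim_out,
                                     NumericVector sp_out, double fill) {
  const int n1 = dim_in[0], n2 = dim_in[1], n3 = dim_in[2];
  const int m1 = dim_out[0], m2 = dim_out[1], m3 = dim_out[2];
  NumericVector out((size_t)m1 * m2 * m3);
  out.attr("dim") = IntegerVector::create(m1, m2, m3);

  const double c_in[3]  = {(n1 - 1) / 2.0, (n2 - 1) / 2.0, (n3 - 1) / 2.0};
  const double c_out[3] = {(m1 - 1) / 2.0, (m2 - 1) / 2.0, (m3 - 1) / 2.0};
  const double* v = vol.begin();
  double* o = out.begin();

  auto src_index = [&](int i, int axis) {
    return (i - c_out[axis]) * sp_out[axis] / sp_in[axis] + c_in[axis];
  };

  std::vector<double> x1(m1), x2(m2), x3(m3);
  for (int i = 0; i < m1; ++i) x1[i] = src_index(i, 0);
  for (int i = 0; i < m2; ++i) x2[i] = src_index(i, 1);
  for (int i = 0; i < m3; ++i) x3[i] = src_index(i, 2);

  size_t idx = 0;
  for (int k = 0; k < m3; ++k) {
    const double z = x3[k];
    for (int j = 0; j < m2; ++j) {
      const double y = x2[j];
      for (int i = 0; i < m1; ++i, ++idx) {
        const double x = x1[i];
        if (x < 0 || x > n1 - 1 || y < 0 || y > n2 - 1 || z < 0 || z > n3 - 1) {
          o[idx] = fill;
          continue;
        }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
        if (x0 == n1 - 1) --x0;
        if (y0 == n2 - 1) --y0;
        if (z0 == n3 - 1) --z0;
        if (n1 == 1) x0 = 0;
        if (n2 == 1) y0 = 0;
        if (n3 == 1) z0 = 0;
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        auto at = [&](int a, int b, int c) {
          a = std::min(a, n1 - 1); b = std::min(b, n2 - 1); c = std::min(c, n3 - 1);
          return v[(size_t)a + (size_t)b * n1 + (size_t)c * n1 * n2];
        };
        const double c00 = at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx;
        const double c10 = at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx;
        const double c01 = at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx;
        const double c11 = at(x0, y0 + 1, z0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1, z0 + 1) * fx;
        o[idx] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
      }
    }
  }
  return out;
}
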
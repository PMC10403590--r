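#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discretized Rayleigh integral of exp(i k r) / r over a rectangular
// aperture, evaluated on one quadrant of a parallel plane at the given
// depth (the element is mirror-symmetric in x and y).
// [[Rcpp::export]]
ComplexMatrix rayleigh_quarter_cpp(NumericVector xs, NumericVector ys,
                                   double depth, double k,
                                   NumericVector sub_x, NumericVector sub_y) {
  const int nx = xs.size(), ny = ys.size();
  const int nsx = sub_x.size(), nsy = sub_y.size();
  ComplexMatrix out(nx, ny);
  const double z2 = depth * depth;
  for (int iy = 0; iy < ny; ++iy) {
    const double yv = ys[iy];
    for (int ix = 0; ix < nx; ++ix) {
      const double xv = xs[ix];
      double re = 0.0, im = 0.0;
      for (int jy = 0; jy < nsy; ++jy) {
        const double dyv = yv - sub_y[jy];
        const double dy2 = dyv * dyv + z2;
        for (int jx = 0; jx < nsx; ++jx) {
          const double dxv = xv - sub_x[jx];
          const double r = std::sqrt(dxv * dxv + dy2);
          re += std::cos(k * r) / r;
          im += std::sin(k * r) / r;
        }
      }
      out(ix, iy).r = re / (nsx * nsy);
      out(ix, iy).i = im / (nsx * nsy);
    }
  }
  return out;
}
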
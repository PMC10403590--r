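#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Windowed-sinc gather for the dispersion-relation (Stolt) resampling:
// for every (kx, ky, kz) node, interpolate the omega-domain spectrum at
// omega = -sign(kz) * c * |k| and scale by the Jacobian c |kz| / |k|.
// P is the (nx x ny x nw) spectrum; the omega axis is in fft bin order
// with spacing dw. Taps that would wrap across the Nyquist fold are zeroed.
// [[Rcpp::export]]
ComplexVector stolt_gather_cpp(ComplexVector P, int nx, int ny, int nw,
                               NumericVector kx, NumericVector ky,
                               NumericVector kz, double ct, double dw,
                               int J) {
  const int nz = kz.size();
  ComplexVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const Rcomplex *p = P.begin();
  Rcomplex *o = out.begin();
  const double half = nw / 2.0 - J - 1.0;
  for (int iz = 0; iz < nz; ++iz) {
    const double kzv = kz[iz], kz2 = kzv * kzv;
    const double sgn = (kzv > 0) - (kzv < 0);
    for (int iy = 0; iy < ny; ++iy) {
      const double ky2 = ky[iy] * ky[iy];
      Rcomplex *orow = o + (static_cast<R_xlen_t>(iz) * ny + iy) * nx;
      const Rcomplex *prow = p + static_cast<R_xlen_t>(iy) * nx;
      for (int ix = 0; ix < nx; ++ix) {
        const double kmag = std::sqrt(kx[ix] * kx[ix] + ky2 + kz2);
        orow[ix].r = 0.0; orow[ix].i = 0.0;
        if (kmag <= 0.0) continue;
        const double bfrac = -sgn * ct * kmag / dw;
        if (std::fabs(bfrac) > half) continue;
        const int base = static_cast<int>(std::lround(bfrac));
        double accr = 0.0, acci = 0.0;
        for (int j = -J; j <= J; ++j) {
          const int b = base + j;
          const double u = bfrac - b;
          double wgt;
          if (std::fabs(u) < 1e-12) wgt = 1.0;
          else wgt = std::sin(M_PI * u) / (M_PI * u);
          wgt *= 0.5 + 0.5 * std::cos(M_PI * u / (J + 1.0));
          int bb = b % nw; if (bb < 0) bb += nw;
          const Rcomplex v = prow[static_cast<R_xlen_t>(bb) * nx * ny + ix];
          accr += v.r * wgt; acci += v.i * wgt;
        }
        const double jac = ct * std::fabs(kzv) / kmag;
        orow[ix].r = accr * jac;
        orow[ix].i = acci * jac;
      }
    }
  }
  return out;
}
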
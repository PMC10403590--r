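#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Delay-and-sum accumulation. channels: (n_el x nt) matrix; tau: (nz x nrho)
// travel-time lookup with uniform rho axis. Delays outside the record
// contribute zero and are counted.
// [[Rcpp::export]]
List das_sum_cpp(NumericMatrix channels, NumericVector ex, NumericVector ey,
                 NumericVector apod, NumericVector vx, NumericVector vy,
                 NumericMatrix tau, double rho0, double drho,
                 double t0, double dt) {
  const int nel = channels.nrow(), nt = channels.ncol();
  const int nvx = vx.size(), nvy = vy.size(), nvz = tau.nrow();
  const int nrho = tau.ncol();
  NumericVector vol(static_cast<R_xlen_t>(nvx) * nvy * nvz);
  double *out = REAL(vol);
  const double *ch = &channels(0, 0);
  long long clipped = 0;
  const double *tp = &tau(0, 0);  // column-major: tau[iz + nvz * irho]
  for (int e = 0; e < nel; ++e) {
    const double exe = ex[e], eye = ey[e], w = apod[e];
    for (int iz = 0; iz < nvz; ++iz) {
      const double *trow = tp + iz;
      for (int iy = 0; iy < nvy; ++iy) {
        const double dy = vy[iy] - eye, dy2 = dy * dy;
        double *orow = out + (static_cast<R_xlen_t>(iz) * nvy + iy) * nvx;
        for (int ix = 0; ix < nvx; ++ix) {
          const double dx = vx[ix] - exe;
          const double rho = std::sqrt(dx * dx + dy2);
          double fr = (rho - rho0) / drho;
          int ir = static_cast<int>(fr);
          if (ir >= nrho - 1) { ir = nrho - 2; fr = nrho - 1; }
          const double ta = trow[static_cast<R_xlen_t>(ir) * nvz];
          const double tb = trow[static_cast<R_xlen_t>(ir + 1) * nvz];
          const double t = ta + (fr - ir) * (tb - ta);
          const double fi = (t - t0) / dt;
          const int j = static_cast<int>(fi);
          if (fi < 0 || j >= nt - 1) { ++clipped; continue; }
          const double frac = fi - j;
          const double s = ch[e + static_cast<R_xlen_t>(j) * nel] * (1.0 - frac)
                         + ch[e + static_cast<R_xlen_t>(j + 1) * nel] * frac;
          orow[ix] += w * s;
        }
      }
    }
  }
  return List::create(Named("volume") = vol,
                      Named("clipped") = static_cast<double>(clipped));
}
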
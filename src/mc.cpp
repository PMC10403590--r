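#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

// MCML-style photon-packet random walk in a homogeneous half-space with
// absorption-weight deposition, Henyey-Greenstein scattering, Russian
// roulette, and termination on exit from the simulation box. Deposited
// weight is scored on a voxel grid (a sub-region of the box).
// [[Rcpp::export]]
List mc_fluence_cpp(NumericMatrix pos, NumericMatrix dir,
                    double mua, double mus, double g,
                    double x0, double dx, int nx,
                    double y0, double dy, int ny,
                    double z0, double dz, int nz,
                    double box_halfwidth, double box_depth,
                    int seed) {
  const int n = pos.nrow();
  const double mut = mua + mus;
  const double albedo_dep = mua / mut;
  const double wthresh = 1e-4;
  const double m_roul = 10.0;
  NumericVector A(static_cast<R_xlen_t>(nx) * ny * nz);
  double *a = REAL(A);
  double absorbed = 0.0, escaped = 0.0;
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  for (int i = 0; i < n; ++i) {
    double px = pos(i, 0), py = pos(i, 1), pz = pos(i, 2);
    double ux = dir(i, 0), uy = dir(i, 1), uz = dir(i, 2);
    double w = 1.0;
    for (;;) {
      const double s = -std::log(U(rng) + 1e-300) / mut;
      px += s * ux; py += s * uy; pz += s * uz;
      if (pz < 0.0 || pz > box_depth ||
          px < -box_halfwidth || px > box_halfwidth ||
          py < -box_halfwidth || py > box_halfwidth) {
        escaped += w;
        break;
      }
      const double dw = w * albedo_dep;
      const int ix = static_cast<int>(std::floor((px - x0) / dx));
      const int iy = static_cast<int>(std::floor((py - y0) / dy));
      const int iz = static_cast<int>(std::floor((pz - z0) / dz));
      if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
        a[ix + static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz)] += dw;
      absorbed += dw;
      w -= dw;
      if (w <= 0.0) break;
      if (w < wthresh) {
        if (U(rng) > 1.0 / m_roul) { break; }  // absorbed share already scored
        w *= m_roul;
      }
      // Henyey-Greenstein deflection
      double ct;
      if (g != 0.0) {
        const double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * U(rng));
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      } else {
        ct = 2.0 * U(rng) - 1.0;
      }
      if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      const double st = std::sqrt(1.0 - ct * ct);
      const double phi = 2.0 * M_PI * U(rng);
      const double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        const double den = std::sqrt(1.0 - uz * uz);
        const double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        const double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        const double nuz = -st * cp * den + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }
    }
  }
  return List::create(Named("A") = A, Named("absorbed") = absorbed,
                      Named("escaped") = escaped);
}
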
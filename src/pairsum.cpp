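#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// r-dependent effective temperature factor: two-sphere overlap-volume
// interpolation between beqlo at r = 0 and beqhi at r >= 2*radius
static inline double beq_eff(double r, double blo, double bhi, double R) {
  if (r >= 2.0 * R) return bhi;
  double w = 1.0 - 3.0 * r / (4.0 * R) + (r * r * r) / (16.0 * R * R * R);
  return bhi - (bhi - blo) * w;
}

// Raw weighted pair density: for every ordered pair (i, j + lattice image)
// with 0 < d <= cutoff, accumulate w_i * w_j * Normal(r; d, sigma_ij) on the
// grid, where sigma_ij^2 = (B_i(d) + B_j(d)) / (8 pi^2).  Gaussians are
// truncated at 8 sigma.  The grid must be uniform.
// [[Rcpp::export]]
NumericVector pair_density_cpp(NumericMatrix cart, NumericVector w,
                               NumericVector beqlo, NumericVector beqhi,
                               NumericVector radius,
                               NumericMatrix lattice, IntegerVector nmax,
                               NumericVector r, double cutoff) {
  const int ns = cart.nrow();
  const int ng = r.size();
  NumericVector out(ng);
  if (ng < 2) stop("grid must have at least 2 points");
  const double r0 = r[0];
  const double dr = r[1] - r[0];
  for (int k = 2; k < ng; ++k)
    if (std::abs((r[k] - r[k - 1]) - dr) > 1e-9 * dr)
      stop("pair_density_cpp requires a uniform r grid");

  const double ax = lattice(0, 0), ay = lattice(1, 0), az = lattice(2, 0);
  const double bx = lattice(0, 1), by = lattice(1, 1), bz = lattice(2, 1);
  const double cx = lattice(0, 2), cy = lattice(1, 2), cz = lattice(2, 2);
  const double cut2 = cutoff * cutoff;
  const double eightpi2 = 8.0 * M_PI * M_PI;

  for (int na = -nmax[0]; na <= nmax[0]; ++na) {
    for (int nb = -nmax[1]; nb <= nmax[1]; ++nb) {
      for (int nc = -nmax[2]; nc <= nmax[2]; ++nc) {
        const double tx = na * ax + nb * bx + nc * cx;
        const double ty = na * ay + nb * by + nc * cy;
        const double tz = na * az + nb * bz + nc * cz;
        for (int i = 0; i < ns; ++i) {
          const double xi = cart(i, 0), yi = cart(i, 1), zi = cart(i, 2);
          for (int j = 0; j < ns; ++j) {
            const double dx = cart(j, 0) + tx - xi;
            const double dy = cart(j, 1) + ty - yi;
            const double dz = cart(j, 2) + tz - zi;
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > cut2 || d2 < 1e-16) continue;
            const double d = std::sqrt(d2);
            const double bi = beq_eff(d, beqlo[i], beqhi[i], radius[i]);
            const double bj = beq_eff(d, beqlo[j], beqhi[j], radius[j]);
            const double s2 = (bi + bj) / eightpi2;
            if (s2 <= 0.0) stop("pair with non-positive displacement variance");
            const double sig = std::sqrt(s2);
            const double wij = w[i] * w[j];
            const double norm = wij / (sig * std::sqrt(2.0 * M_PI));
            int klo = (int)std::ceil((d - 8.0 * sig - r0) / dr);
            int khi = (int)std::floor((d + 8.0 * sig - r0) / dr);
            if (klo < 0) klo = 0;
            if (khi > ng - 1) khi = ng - 1;
            if (klo > khi) continue;
            // incremental evaluation of exp(-u^2/2) along the uniform
            // grid: E(k+1) = E(k) * t(k), t(k+1) = t(k) * B
            const double del = dr / sig;
            const double u0 = (r0 + klo * dr - d) / sig;
            double E = std::exp(-0.5 * u0 * u0);
            double t = std::exp(-(u0 * del + 0.5 * del * del));
            const double B = std::exp(-del * del);
            for (int k = klo; k <= khi; ++k) {
              out[k] += norm * E;
              E *= t;
              t *= B;
            }
          }
        }
      }
    }
  }
  return out;
}
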
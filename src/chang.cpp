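#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear in-plane interpolation of mu at fractional voxel position
// (x, y) (0-based) in slice k; 0 outside the grid.
static inline double mu_at(const double *mu, int nx, int ny, R_xlen_t koff,
                           double x, double y) {
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) return 0.0;
  int i0 = (int)std::floor(x);
  int j0 = (int)std::floor(y);
  if (i0 >= nx - 1) i0 = nx - 2;
  if (j0 >= ny - 1) j0 = ny - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  double fx = x - i0, fy = y - j0;
  const double *base = mu + koff + (R_xlen_t)j0 * nx + i0;
  double v00 = base[0], v10 = base[1];
  double v01 = base[nx], v11 = base[nx + 1];
  return (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
         (1 - fx) * fy * v01 + fx * fy * v11;
}

// Chang attenuation correction factors: for each voxel inside the body
// mask, average over n_angles equally spaced in-plane directions the
// transmission exp(-integral of mu to the grid edge), sampled with a fixed
// step (mm) and bilinear interpolation of mu; ACF = 1 / mean transmission.
// mu is in 1/mm, spacing in mm. Outside the body mask ACF = 1.
// [[Rcpp::export]]
NumericVector chang_acf_cpp(NumericVector mu, IntegerVector dims,
                            NumericVector spacing, LogicalVector body,
                            int n_angles, double step_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector acf(n, 1.0);
  const double *pmu = REAL(mu);

  std::vector<double> ca(n_angles), sa(n_angles);
  for (int a = 0; a < n_angles; ++a) {
    double th = 2.0 * M_PI * a / n_angles;
    ca[a] = std::cos(th);
    sa[a] = std::sin(th);
  }
  // max in-plane traversal in mm (diagonal of the slice) bounds the march
  const double diag = std::sqrt(nx * sx * nx * sx + ny * sy * ny * sy);
  const int max_steps = (int)std::ceil(diag / step_mm) + 2;

  for (int k = 0; k < nz; ++k) {
    R_xlen_t koff = (R_xlen_t)k * nx * ny;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = koff + (R_xlen_t)j * nx + i;
        if (!body[v]) continue;
        double mean_t = 0.0;
        for (int a = 0; a < n_angles; ++a) {
          double dxi = ca[a] * step_mm / sx;  // step in index units
          double dyi = sa[a] * step_mm / sy;
          double x = i + 0.5 * dxi, y = j + 0.5 * dyi;  // midpoint rule
          double integ = 0.0;
          for (int s = 0; s < max_steps; ++s) {
            if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) break;
            integ += mu_at(pmu, nx, ny, koff, x, y);
            x += dxi;
            y += dyi;
          }
          mean_t += std::exp(-integ * step_mm);
        }
        mean_t /= n_angles;
        acf[v] = 1.0 / mean_t;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return acf;
}
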
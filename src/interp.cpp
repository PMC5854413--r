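#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
// Coordinates outside the field of view return 0 (and zero gradients):
// downstream ROI means treat zero as the out-of-field fill.
//
// coords: N x 3 matrix of 0-based voxel coordinates.
// want_grad: if true, also return the intensity gradient in voxel units,
// computed by differentiating the trilinear interpolant itself.

// [[Rcpp::export]]
NumericMatrix c_sample_trilinear(NumericVector data, IntegerVector dims,
                                 NumericMatrix coords, bool want_grad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = coords.nrow();
  const int ncol = want_grad ? 4 : 1;
  NumericMatrix out(n, ncol);
  const double *d = REAL(data);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      continue;  // zero fill
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;  // clamp so x0+1 stays in range when x == nx-1
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const R_xlen_t base = x0 * sx + (R_xlen_t)y0 * sy + (R_xlen_t)z0 * sz;
    const R_xlen_t ox = (nx > 1) ? sx : 0, oy = (ny > 1) ? sy : 0,
                   oz = (nz > 1) ? sz : 0;
    const double c000 = d[base];
    const double c100 = d[base + ox];
    const double c010 = d[base + oy];
    const double c110 = d[base + ox + oy];
    const double c001 = d[base + oz];
    const double c101 = d[base + ox + oz];
    const double c011 = d[base + oy + oz];
    const double c111 = d[base + ox + oy + oz];

    const double c00 = c000 + fx * (c100 - c000);
    const double c10 = c010 + fx * (c110 - c010);
    const double c01 = c001 + fx * (c101 - c001);
    const double c11 = c011 + fx * (c111 - c011);
    const double c0 = c00 + fy * (c10 - c00);
    const double c1 = c01 + fy * (c11 - c01);
    out(i, 0) = c0 + fz * (c1 - c0);

    if (want_grad) {
      // d/dx at fixed fy, fz
      const double gx0 = (c100 - c000) + fy * ((c110 - c010) - (c100 - c000));
      const double gx1 = (c101 - c001) + fy * ((c111 - c011) - (c101 - c001));
      out(i, 1) = gx0 + fz * (gx1 - gx0);
      out(i, 2) = (c10 - c00) + fz * ((c11 - c01) - (c10 - c00));
      out(i, 3) = c1 - c0;
    }
  }
  return out;
}
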
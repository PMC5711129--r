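#include <Rcpp.h>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear interpolation of a 3D volume at continuous 0-based index
// coordinates. clamp_edge = 1 clamps points to the grid (nearest-edge
// extension); clamp_edge = 0 returns `fill` for points outside the grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& vol, const IntegerVector& dim,
                            const NumericMatrix& pts, const double fill,
                            const int clamp_edge) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  const double* v = vol.begin();
  NumericVector out(n);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (clamp_edge) {
      x = clampd(x, 0.0, nx - 1.0);
      y = clampd(y, 0.0, ny - 1.0);
      z = clampd(z, 0.0, nz - 1.0);
    } else if (x < 0.0 || x > nx - 1.0 || y < 0.0 || y > ny - 1.0 ||
               z < 0.0 || z > nz - 1.0 || ISNAN(x) || ISNAN(y) || ISNAN(z)) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2;
    if (j0 > ny - 2) j0 = ny - 2;
    if (k0 > nz - 2) k0 = nz - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    const int i1 = nx > 1 ? i0 + 1 : i0;
    const int j1 = ny > 1 ? j0 + 1 : j0;
    const int k1 = nz > 1 ? k0 + 1 : k0;
    const double fx = nx > 1 ? x - i0 : 0.0;
    const double fy = ny > 1 ? y - j0 : 0.0;
    const double fz = nz > 1 ? z - k0 : 0.0;
    const double gx = 1.0 - fx, gy = 1.0 - fy, gz = 1.0 - fz;
    const R_xlen_t b00 = i0 + j0 * sy, b10 = i1 + j0 * sy;
    const R_xlen_t b01 = i0 + j1 * sy, b11 = i1 + j1 * sy;
    const R_xlen_t o0 = k0 * sz, o1 = k1 * sz;
    out[p] = gz * (gy * (gx * v[b00 + o0] + fx * v[b10 + o0]) +
                   fy * (gx * v[b01 + o0] + fx * v[b11 + o0])) +
             fz * (gy * (gx * v[b00 + o1] + fx * v[b10 + o1]) +
                   fy * (gx * v[b01 + o1] + fx * v[b11 + o1]));
  }
  return out;
}
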
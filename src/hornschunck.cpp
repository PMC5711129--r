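#include <Rcpp.h>
using namespace Rcpp;

// Red-black Gauss-Seidel sweeps (with over-relaxation) of the Horn-Schunck
// update for a three-component displacement field on a 3D grid. All
// quantities are in voxel units; gradients (Ix, Iy, Iz) are per-voxel
// intensity derivatives of the currently warped source, and
// b = It - Ix*u0 - Iy*v0 - Iz*w0 re-expresses the linearised
// brightness-constancy constraint in terms of the absolute field so that
// the smoothness term acts on the total displacement. Neighbour averages
// use replicate (Neumann) boundaries. Returns the updated field, the
// number of sweeps performed, and the last mean update.
// [[Rcpp::export]]
List cpp_hs(const NumericVector& Ix, const NumericVector& Iy,
            const NumericVector& Iz, const NumericVector& b,
            const IntegerVector& dim, const NumericVector& u0,
            const NumericVector& v0, const NumericVector& w0,
            const double alpha2, const int max_iter, const double tol,
            const double omega = 1.6) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector u = clone(u0), v = clone(v0), w = clone(w0);
  const double* ix = Ix.begin();
  const double* iy = Iy.begin();
  const double* iz = Iz.begin();
  const double* bb = b.begin();
  double* pu = u.begin();
  double* pv = v.begin();
  double* pw = w.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  int iter = 0;
  double mean_update = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    double acc = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 0; k < nz; ++k) {
        const R_xlen_t km = (k > 0 ? k - 1 : k) * sz;
        const R_xlen_t kp = (k < nz - 1 ? k + 1 : k) * sz;
        const R_xlen_t kc = (R_xlen_t)k * sz;
        for (int j = 0; j < ny; ++j) {
          const R_xlen_t jm = (j > 0 ? j - 1 : j) * sy;
          const R_xlen_t jp = (j < ny - 1 ? j + 1 : j) * sy;
          const R_xlen_t jc = (R_xlen_t)j * sy;
          for (int i = (j + k + color) & 1; i < nx; i += 2) {
            const int im = i > 0 ? i - 1 : i;
            const int ip = i < nx - 1 ? i + 1 : i;
            const R_xlen_t c = i + jc + kc;
            const double ub = (pu[im + jc + kc] + pu[ip + jc + kc] +
                               pu[i + jm + kc] + pu[i + jp + kc] +
                               pu[i + jc + km] + pu[i + jc + kp]) / 6.0;
            const double vb = (pv[im + jc + kc] + pv[ip + jc + kc] +
                               pv[i + jm + kc] + pv[i + jp + kc] +
                               pv[i + jc + km] + pv[i + jc + kp]) / 6.0;
            const double wb = (pw[im + jc + kc] + pw[ip + jc + kc] +
                               pw[i + jm + kc] + pw[i + jp + kc] +
                               pw[i + jc + km] + pw[i + jc + kp]) / 6.0;
            const double gx = ix[c], gy = iy[c], gz = iz[c];
            const double t =
                (gx * ub + gy * vb + gz * wb + bb[c]) /
                (alpha2 + gx * gx + gy * gy + gz * gz);
            const double nu = ub - gx * t;
            const double nv = vb - gy * t;
            const double nw = wb - gz * t;
            const double du = omega * (nu - pu[c]);
            const double dv = omega * (nv - pv[c]);
            const double dw = omega * (nw - pw[c]);
            pu[c] += du;
            pv[c] += dv;
            pw[c] += dw;
            acc += std::abs(du) + std::abs(dv) + std::abs(dw);
          }
        }
      }
    }
    mean_update = acc / (3.0 * (double)n);
    if (mean_update < tol) {
      ++iter;
      break;
    }
  }
  return List::create(_["u"] = u, _["v"] = v, _["w"] = w,
                      _["iterations"] = iter,
                      _["mean_update"] = mean_update);
}
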
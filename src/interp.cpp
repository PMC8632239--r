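#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear interpolation of a 3D field at world points. Grid: voxel center of
// index (0,0,0) at `origin`, spacing in mm per axis. Points outside the voxel-
// center lattice hull return NA (caller raises the out-of-bounds error).
// [[Rcpp::export(name = ".cpp_trilinear")]]
NumericVector cpp_trilinear(NumericVector field, IntegerVector dims, NumericVector spacing,
                            NumericVector origin, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nxy = (size_t)nx * ny;
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double gx = (pts(p, 0) - origin[0]) / spacing[0];
    double gy = (pts(p, 1) - origin[1]) / spacing[1];
    double gz = (pts(p, 2) - origin[2]) / spacing[2];
    if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1) {
      out[p] = NA_REAL;
      continue;
    }
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double tx = gx - i0, ty = gy - j0, tz = gz - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
    double c000 = field[(size_t)k0 * nxy + (size_t)j0 * nx + i0];
    double c100 = field[(size_t)k0 * nxy + (size_t)j0 * nx + i1];
    double c010 = field[(size_t)k0 * nxy + (size_t)j1 * nx + i0];
    double c110 = field[(size_t)k0 * nxy + (size_t)j1 * nx + i1];
    double c001 = field[(size_t)k1 * nxy + (size_t)j0 * nx + i0];
    double c101 = field[(size_t)k1 * nxy + (size_t)j0 * nx + i1];
    double c011 = field[(size_t)k1 * nxy + (size_t)j1 * nx + i0];
    double c111 = field[(size_t)k1 * nxy + (size_t)j1 * nx + i1];
    double c00 = c000 * (1 - tx) + c100 * tx;
    double c10 = c010 * (1 - tx) + c110 * tx;
    double c01 = c001 * (1 - tx) + c101 * tx;
    double c11 = c011 * (1 - tx) + c111 * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    out[p] = c0 * (1 - tz) + c1 * tz;
  }
  return out;
}
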
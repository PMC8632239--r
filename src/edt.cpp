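#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform (lower-envelope-of-parabolas
// algorithm), separable per axis, anisotropic spacing supported.

static const double EDT_INF = std::numeric_limits<double>::infinity();

// 1D transform of f (squared distances; +Inf where no feature reached yet)
// with sample spacing h (mm). Writes result into d. Only finite parabolas
// enter the envelope; an all-infinite row stays infinite.
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                  double h, std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  double h2 = h * h;
  for (int q = 0; q < n; ++q) {
    if (f[q] == EDT_INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -EDT_INF; z[1] = EDT_INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q * h2) - (f[p] + (double)p * p * h2)) /
          (2.0 * h2 * (q - p));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { // k == 0 and new parabola dominates everywhere
      v[0] = q; z[0] = -EDT_INF; z[1] = EDT_INF; k = 0;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = EDT_INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = EDT_INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (double)q) ++j;
    double dq = (double)(q - v[j]) * h;
    d[q] = dq * dq + f[v[j]];
  }
}

// squared distance (mm^2) from every voxel center to the nearest feature voxel center
static std::vector<double> sq_edt(const std::vector<char>& feature, int nx, int ny, int nz,
                                  double sx, double sy, double sz) {
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : EDT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int k = 0; k < nz; ++k) // along x (fastest index)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      edt1d(f, d, nx, sx, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  for (int k = 0; k < nz; ++k) // along y
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      edt1d(f, d, ny, sy, v, z);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
  size_t nxy = (size_t)nx * ny;
  for (int j = 0; j < ny; ++j) // along z
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * nxy];
      edt1d(f, d, nz, sz, v, z);
      for (int k = 0; k < nz; ++k) g[base + (size_t)k * nxy] = d[k];
    }
  return g;
}

// Signed distance: sqrt(EDT to mask) - sqrt(EDT to background); negative inside.
// [[Rcpp::export(name = ".cpp_signed_edt")]]
NumericVector cpp_signed_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> fg(n), bg(n);
  for (size_t i = 0; i < n; ++i) { fg[i] = mask[i] ? 1 : 0; bg[i] = mask[i] ? 0 : 1; }
  std::vector<double> dOut = sq_edt(fg, nx, ny, nz, spacing[0], spacing[1], spacing[2]);
  std::vector<double> dIn = sq_edt(bg, nx, ny, nz, spacing[0], spacing[1], spacing[2]);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) {
    double a = dOut[i] == EDT_INF ? R_PosInf : std::sqrt(dOut[i]);
    double b = dIn[i] == EDT_INF ? R_PosInf : std::sqrt(dIn[i]);
    out[i] = a - b;
  }
  out.attr("dim") = dims;
  return out;
}

// Unsigned distance-to-feature transform (mm).
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector feature, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> fg(n);
  for (size_t i = 0; i < n; ++i) fg[i] = feature[i] ? 1 : 0;
  std::vector<double> g = sq_edt(fg, nx, ny, nz, spacing[0], spacing[1], spacing[2]);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = g[i] == EDT_INF ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
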
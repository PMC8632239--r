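#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Squared distance from point p to triangle (a,b,c) — Eberly's region scheme.
static double pt_tri_sq(const double* p, const double* a, const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  auto sq = [](const double* u, const double* v) {
    double s = 0; for (int i = 0; i < 3; ++i) { double d = u[i] - v[i]; s += d * d; } return s;
  };
  if (d1 <= 0 && d2 <= 0) return sq(p, a);
  double bp[3], cp[3];
  for (int i = 0; i < 3; ++i) { bp[i] = p[i] - b[i]; cp[i] = p[i] - c[i]; }
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return sq(p, b);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    double q[3]; for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
    return sq(p, q);
  }
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return sq(p, c);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    double q[3]; for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
    return sq(p, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3]; for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
    return sq(p, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3]; for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i] + w * ac[i];
  return sq(p, q);
}

// Min distance from each point to a triangle soup (V: n x 3, F: m x 3, 1-based).
// [[Rcpp::export(name = ".cpp_points_to_mesh")]]
NumericVector cpp_points_to_mesh(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  std::vector<double> tv(9 * (size_t)nf);
  double maxEdge = 0.0;
  for (int t = 0; t < nf; ++t) {
    for (int c = 0; c < 3; ++c) {
      int vi = F(t, c) - 1;
      for (int d = 0; d < 3; ++d) tv[9 * (size_t)t + 3 * c + d] = V(vi, d);
    }
    const double* a = &tv[9 * (size_t)t];
    for (int e = 0; e < 3; ++e) {
      const double* u = a + 3 * e;
      const double* w = a + 3 * ((e + 1) % 3);
      double s = 0;
      for (int d = 0; d < 3; ++d) { double dd = u[d] - w[d]; s += dd * dd; }
      if (s > maxEdge) maxEdge = s;
    }
  }
  maxEdge = std::sqrt(maxEdge);
  for (int p = 0; p < np; ++p) {
    double pp[3] = { pts(p, 0), pts(p, 1), pts(p, 2) };
    double best = std::numeric_limits<double>::infinity();
    double bestd = std::numeric_limits<double>::infinity();
    for (int t = 0; t < nf; ++t) {
      const double* base = &tv[9 * (size_t)t];
      // lower bound: dist(p, tri) >= dist(p, v0) - maxEdge
      double dx = pp[0] - base[0], dy = pp[1] - base[1], dz = pp[2] - base[2];
      double vsq = dx * dx + dy * dy + dz * dz;
      double lim = bestd + maxEdge;
      if (vsq > lim * lim) continue;
      double s = pt_tri_sq(pp, base, base + 3, base + 6);
      if (s < best) { best = s; bestd = std::sqrt(s); }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// Minimal surface-to-surface distance between two triangle meshes, computed as
// the min over (vertices of A -> faces of B) and (vertices of B -> faces of A).
// Exact when the closest pair involves a vertex of either mesh; for finely
// tessellated analytic surfaces the error is below the chord sag.
// [[Rcpp::export(name = ".cpp_mesh_min_dist")]]
double cpp_mesh_min_dist(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB, IntegerMatrix FB) {
  NumericVector d1 = cpp_points_to_mesh(VA, VB, FB);
  NumericVector d2 = cpp_points_to_mesh(VB, VA, FA);
  double best = R_PosInf;
  for (int i = 0; i < d1.size(); ++i) if (d1[i] < best) best = d1[i];
  for (int i = 0; i < d2.size(); ++i) if (d2[i] < best) best = d2[i];
  return best;
}
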
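#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the voxel-center lattice.
// Each cell between 8 voxel centers is split into 6 tetrahedra sharing the
// main diagonal; the decomposition matches across neighboring cells, so the
// output surface is watertight. The domain is implicitly padded with `pad`
// so masks touching the array border still close. Triangles are oriented
// with normals pointing from inside (value > level) to outside.

struct MTGrid {
  const double* v;
  int nx, ny, nz;
  double pad;
  double at(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return pad;
    return v[(size_t)k * nx * ny + (size_t)j * nx + i];
  }
};

// cube corner offsets, numbered so the main diagonal is c0-c6
static const int CDX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
static const int CDY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
static const int CDZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

// [[Rcpp::export(name = ".cpp_march_tets")]]
List cpp_march_tets(NumericVector values, IntegerVector dims, NumericVector spacing,
                    NumericVector origin, double level, double pad) {
  MTGrid g;
  g.v = REAL(values);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.pad = pad;

  int mx = g.nx + 2, my = g.ny + 2; // padded node grid for corner ids
  auto nodeId = [&](int i, int j, int k) -> std::uint64_t {
    return (std::uint64_t)(k + 1) * mx * my + (std::uint64_t)(j + 1) * mx + (i + 1);
  };

  std::unordered_map<std::uint64_t, int> edgeVert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F; // flat triples, 1-based

  double cval[8];
  int ci[8], cj[8], ck[8];

  auto edgeVertex = [&](int a, int b) -> int {
    std::uint64_t ida = nodeId(ci[a], cj[a], ck[a]);
    std::uint64_t idb = nodeId(ci[b], cj[b], ck[b]);
    if (ida > idb) std::swap(ida, idb);
    std::uint64_t key = (ida << 32) | idb; // node ids < 2^32: collision-free
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double va = cval[a], vb = cval[b];
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double px = origin[0] + spacing[0] * (ci[a] + t * (ci[b] - ci[a]));
    double py = origin[1] + spacing[1] * (cj[a] + t * (cj[b] - cj[a]));
    double pz = origin[2] + spacing[2] * (ck[a] + t * (ck[b] - ck[a]));
    int idx = (int)VX.size();
    VX.push_back(px); VY.push_back(py); VZ.push_back(pz);
    edgeVert.emplace(key, idx);
    return idx;
  };

  auto emitTri = [&](int v0, int v1, int v2, const double* insideCentroid) {
    // orient: normal should point away from the inside centroid
    double ax = VX[v1] - VX[v0], ay = VY[v1] - VY[v0], az = VZ[v1] - VZ[v0];
    double bx = VX[v2] - VX[v0], by = VY[v2] - VY[v0], bz = VZ[v2] - VZ[v0];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz, nzv = ax * by - ay * bx;
    double cx = (VX[v0] + VX[v1] + VX[v2]) / 3.0 - insideCentroid[0];
    double cy = (VY[v0] + VY[v1] + VY[v2]) / 3.0 - insideCentroid[1];
    double cz = (VZ[v0] + VZ[v1] + VZ[v2]) / 3.0 - insideCentroid[2];
    bool flip = (nxv * cx + nyv * cy + nzv * cz) < 0;
    F.push_back(v0 + 1);
    if (flip) { F.push_back(v2 + 1); F.push_back(v1 + 1); }
    else { F.push_back(v1 + 1); F.push_back(v2 + 1); }
  };

  for (int k = -1; k < g.nz; ++k)
    for (int j = -1; j < g.ny; ++j)
      for (int i = -1; i < g.nx; ++i) {
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          ci[c] = i + CDX[c]; cj[c] = j + CDY[c]; ck[c] = k + CDZ[c];
          cval[c] = g.at(ci[c], cj[c], ck[c]);
          if (cval[c] > level) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cval[T[c]] > level) in[nin++] = T[c]; else out[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          double icx = 0, icy = 0, icz = 0;
          for (int c = 0; c < nin; ++c) {
            icx += origin[0] + spacing[0] * ci[in[c]];
            icy += origin[1] + spacing[1] * cj[in[c]];
            icz += origin[2] + spacing[2] * ck[in[c]];
          }
          icx /= nin; icy /= nin; icz /= nin;
          double cen[3] = { icx, icy, icz };
          if (nin == 1) {
            int e0 = edgeVertex(in[0], out[0]);
            int e1 = edgeVertex(in[0], out[1]);
            int e2 = edgeVertex(in[0], out[2]);
            emitTri(e0, e1, e2, cen);
          } else if (nin == 3) {
            int e0 = edgeVertex(in[0], out[0]);
            int e1 = edgeVertex(in[1], out[0]);
            int e2 = edgeVertex(in[2], out[0]);
            emitTri(e0, e1, e2, cen);
          } else { // 2 in, 2 out -> quad
            int e00 = edgeVertex(in[0], out[0]);
            int e01 = edgeVertex(in[0], out[1]);
            int e10 = edgeVertex(in[1], out[0]);
            int e11 = edgeVertex(in[1], out[1]);
            emitTri(e00, e01, e11, cen);
            emitTri(e00, e11, e10, cen);
          }
        }
      }

  int nv = (int)VX.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = VX[v]; V(v, 1) = VY[v]; V(v, 2) = VZ[v]; }
  int nf = (int)F.size() / 3;
  IntegerMatrix Fm(nf, 3);
  for (int t = 0; t < nf; ++t) {
    Fm(t, 0) = F[3 * t]; Fm(t, 1) = F[3 * t + 1]; Fm(t, 2) = F[3 * t + 2];
  }
  return List::create(Named("vertices") = V, Named("faces") = Fm);
}
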
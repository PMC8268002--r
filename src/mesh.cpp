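#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Surface mesh of a scalar field by marching tetrahedra with linear edge
// interpolation at the given iso-level. Passing a 0/1 indicator yields the
// classic midpoint binary mesh; passing a smoothed indicator yields a
// low-bias surface-area estimate. Returns total surface area (mm^2) and
// enclosed mesh volume (mm^3). The field must be padded by the caller with
// a below-level border so the surface is closed.

struct V3 {
  double x, y, z;
};
static inline V3 sub(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross3(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot3(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
// crossing point on the edge a-b (field values va, vb straddling lev)
static inline V3 interp(const V3 &a, double va, const V3 &b, double vb, double lev) {
  double t = (lev - va) / (vb - va);
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

// accumulate one triangle oriented away from an interior reference point
static void add_tri(V3 p0, V3 p1, V3 p2, const V3 &inside_pt, double &area, double &vol6) {
  V3 n = cross3(sub(p1, p0), sub(p2, p0));
  V3 cen = {(p0.x + p1.x + p2.x) / 3, (p0.y + p1.y + p2.y) / 3, (p0.z + p1.z + p2.z) / 3};
  if (dot3(n, sub(cen, inside_pt)) < 0) {
    V3 tmp = p1; p1 = p2; p2 = tmp;
    n = cross3(sub(p1, p0), sub(p2, p0));
  }
  area += 0.5 * std::sqrt(dot3(n, n));
  vol6 += dot3(p0, cross3(p1, p2));
}

static void do_tet(const V3 v[4], const double f[4], double lev, double &area, double &vol6) {
  int ins[4], outs[4], ni = 0, no = 0;
  for (int a = 0; a < 4; a++) {
    if (f[a] > lev) ins[ni++] = a; else outs[no++] = a;
  }
  if (ni == 0 || ni == 4) return;
  if (ni == 1) {
    int p = ins[0];
    add_tri(interp(v[p], f[p], v[outs[0]], f[outs[0]], lev),
            interp(v[p], f[p], v[outs[1]], f[outs[1]], lev),
            interp(v[p], f[p], v[outs[2]], f[outs[2]], lev), v[p], area, vol6);
  } else if (ni == 3) {
    int q = outs[0];
    V3 c = {(v[ins[0]].x + v[ins[1]].x + v[ins[2]].x) / 3,
            (v[ins[0]].y + v[ins[1]].y + v[ins[2]].y) / 3,
            (v[ins[0]].z + v[ins[1]].z + v[ins[2]].z) / 3};
    add_tri(interp(v[q], f[q], v[ins[0]], f[ins[0]], lev),
            interp(v[q], f[q], v[ins[1]], f[ins[1]], lev),
            interp(v[q], f[q], v[ins[2]], f[ins[2]], lev), c, area, vol6);
  } else { // 2 in, 2 out: quad; cyclic edge order ac, ad, bd, bc
    int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
    V3 ic = {(v[a].x + v[b].x) / 2, (v[a].y + v[b].y) / 2, (v[a].z + v[b].z) / 2};
    V3 e1 = interp(v[a], f[a], v[c], f[c], lev);
    V3 e2 = interp(v[a], f[a], v[d], f[d], lev);
    V3 e3 = interp(v[b], f[b], v[d], f[d], lev);
    V3 e4 = interp(v[b], f[b], v[c], f[c], lev);
    add_tri(e1, e2, e3, ic, area, vol6);
    add_tri(e1, e3, e4, ic, area, vol6);
  }
}

// [[Rcpp::export(name = ".mesh_area_volume")]]
NumericVector mesh_area_volume(NumericVector field, IntegerVector dims,
                               NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  static const int corner[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                                   {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6-tetrahedra decomposition of the cube around diagonal c0-c6
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0, vol6 = 0.0;
  auto at = [&](int i, int j, int k) -> double {
    return field[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
  };
  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx - 1; i++) {
        double cf[8];
        int nin = 0;
        for (int c = 0; c < 8; c++) {
          cf[c] = at(i + corner[c][0], j + corner[c][1], k + corner[c][2]);
          if (cf[c] > level) nin++;
        }
        if (nin == 0 || nin == 8) continue;
        V3 pv[8];
        for (int c = 0; c < 8; c++)
          pv[c] = {(i + corner[c][0]) * sx, (j + corner[c][1]) * sy,
                   (k + corner[c][2]) * sz};
        for (int t = 0; t < 6; t++) {
          V3 tv[4];
          double tf[4];
          for (int a = 0; a < 4; a++) {
            tv[a] = pv[tets[t][a]];
            tf[a] = cf[tets[t][a]];
          }
          do_tet(tv, tf, level, area, vol6);
        }
      }
  return NumericVector::create(_["area"] = area, _["volume"] = std::fabs(vol6) / 6.0);
}

// Largest pairwise Euclidean distance among a set of points (rows of an
// n x d coordinate matrix). Exact O(n^2).
// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow(), d = pts.ncol();
  double best = 0.0;
  for (int a = 0; a < n; a++)
    for (int b = a + 1; b < n; b++) {
      double s = 0.0;
      for (int c = 0; c < d; c++) {
        double dd = pts(a, c) - pts(b, c);
        s += dd * dd;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
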
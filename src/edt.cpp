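#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite sentinel standing in for +infinity: keeps the parabola
// arithmetic in the lower-envelope transform well-defined on empty lines.
// The envelope boundaries use a far larger magnitude so that intersection
// abscissae derived from BIG (up to ~1e32 for sub-unit spacing) can never
// cross them.
static const double BIG = 1e30;
static const double ZLO = -1e300, ZHI = 1e300;

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher),
// with physical sampling step w (so distances come out in mm, not voxels).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double w2, std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = ZLO;
  z[1] = ZHI;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZHI;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = w2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel to the nearest TRUE voxel,
// under anisotropic spacing. Voxels inside the mask get 0; if the mask is
// empty everywhere the result is +Inf.
// [[Rcpp::export(name = ".edt_mm")]]
NumericVector edt_mm(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = g[base + i];
      dt1d(f, d, nx, w2, v, z);
      for (int i = 0; i < nx; i++) g[base + i] = std::min(d[i], BIG);
    }
  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, w2, v, z);
      for (int j = 0; j < ny; j++) g[base + (R_xlen_t)j * nx] = std::min(d[j], BIG);
    }
  // pass along z
  w2 = spacing[2] * spacing[2];
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = g[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, nz, w2, v, z);
      for (int k = 0; k < nz; k++) g[base + (R_xlen_t)k * nx * ny] = std::min(d[k], BIG);
    }

  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (g[i] >= 1e29) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
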
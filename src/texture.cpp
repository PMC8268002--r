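#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
using namespace Rcpp;

// Gray-level texture matrices on a discretized 3D grid. The grid is an
// integer array in column-major order; level 0 marks voxels outside the
// region of interest, levels 1..ng are inside. All five families use the
// 26-neighbourhood (13 unique directions) at Chebyshev distance 1.

static void unique_directions(std::vector<std::array<int,3>> &dirs) {
  // first non-zero component positive -> 13 unique 3D directions
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (dx > 0 || (dx == 0 && dy > 0) || (dx == 0 && dy == 0 && dz > 0))
          dirs.push_back({dx, dy, dz});
      }
}

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
}

// Symmetric co-occurrence counts: ng x ng x 13 array.
// [[Rcpp::export(name = ".glcm_counts")]]
NumericVector glcm_counts(IntegerVector grid, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::array<int,3>> dirs;
  unique_directions(dirs);
  NumericVector out((R_xlen_t)ng * ng * 13);
  for (size_t a = 0; a < dirs.size(); a++) {
    const int dx = dirs[a][0], dy = dirs[a][1], dz = dirs[a][2];
    double *m = &out[(R_xlen_t)a * ng * ng];
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          int li = grid[idx3(i, j, k, nx, ny)];
          if (li == 0) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
            continue;
          int lj = grid[idx3(i2, j2, k2, nx, ny)];
          if (lj == 0) continue;
          m[(R_xlen_t)(lj - 1) * ng + (li - 1)] += 1.0; // (i,j)
          m[(R_xlen_t)(li - 1) * ng + (lj - 1)] += 1.0; // symmetric (j,i)
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts: ng x maxlen x 13 array. A run is a maximal sequence of
// in-mask voxels of equal level along a grid line; out-of-mask voxels break
// runs.
// [[Rcpp::export(name = ".glrlm_counts")]]
NumericVector glrlm_counts(IntegerVector grid, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxlen = std::max(nx, std::max(ny, nz));
  std::vector<std::array<int,3>> dirs;
  unique_directions(dirs);
  NumericVector out((R_xlen_t)ng * maxlen * 13);
  for (size_t a = 0; a < dirs.size(); a++) {
    const int dx = dirs[a][0], dy = dirs[a][1], dz = dirs[a][2];
    double *m = &out[(R_xlen_t)a * ng * maxlen];
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          // only process voxels that start a line segment in this direction
          int ip = i - dx, jp = j - dy, kp = k - dz;
          bool has_prev = ip >= 0 && ip < nx && jp >= 0 && jp < ny &&
                          kp >= 0 && kp < nz;
          if (has_prev) continue;
          int ci = i, cj = j, ck = k;
          int cur = 0, len = 0;
          while (ci >= 0 && ci < nx && cj >= 0 && cj < ny && ck >= 0 && ck < nz) {
            int l = grid[idx3(ci, cj, ck, nx, ny)];
            if (l == cur && l != 0) {
              len++;
            } else {
              if (cur != 0)
                m[(R_xlen_t)(len - 1) * ng + (cur - 1)] += 1.0;
              cur = l;
              len = (l != 0) ? 1 : 0;
            }
            ci += dx; cj += dy; ck += dz;
          }
          if (cur != 0)
            m[(R_xlen_t)(len - 1) * ng + (cur - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// Size-zone triplets (level, size, count); zones are 26-connected components
// of equal level.
// [[Rcpp::export(name = ".glszm_zones")]]
DataFrame glszm_zones(IntegerVector grid, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::map<std::pair<int, R_xlen_t>, double> zones;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; s++) {
    if (seen[s] || grid[s] == 0) continue;
    const int lev = grid[s];
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      size++;
      int ci = c % nx, cj = (c / nx) % ny, ck = c / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int i2 = ci + dx, j2 = cj + dy, k2 = ck + dz;
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
              continue;
            R_xlen_t q = idx3(i2, j2, k2, nx, ny);
            if (!seen[q] && grid[q] == lev) {
              seen[q] = 1;
              stack.push_back(q);
            }
          }
    }
    zones[std::make_pair(lev, size)] += 1.0;
  }
  const size_t m = zones.size();
  IntegerVector lev(m);
  NumericVector size(m), count(m);
  size_t r = 0;
  for (auto &kv : zones) {
    lev[r] = kv.first.first;
    size[r] = (double)kv.first.second;
    count[r] = kv.second;
    r++;
  }
  return DataFrame::create(_["level"] = lev, _["size"] = size, _["count"] = count);
}

// Dependence counts (alpha = 0): matrix ng x 27 where column d holds the
// number of voxels of each level with (d-1) equal-level 26-neighbours
// (dependence size d includes the centre voxel).
// [[Rcpp::export(name = ".gldm_counts")]]
NumericMatrix gldm_counts(IntegerVector grid, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int l = grid[idx3(i, j, k, nx, ny)];
        if (l == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int i2 = i + dx, j2 = j + dy, k2 = k + dz;
              if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
                continue;
              if (grid[idx3(i2, j2, k2, nx, ny)] == l) dep++;
            }
        out(l - 1, dep) += 1.0;
      }
  return out;
}

// Neighbourhood gray-tone difference sums: for each level i, the voxel count
// n_i and s_i = sum over voxels of |level - mean(level of in-mask
// 26-neighbours)|; voxels with no in-mask neighbour contribute to n but 0
// to s (pure isolated voxel convention).
// [[Rcpp::export(name = ".ngtdm_sums")]]
NumericMatrix ngtdm_sums(IntegerVector grid, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2); // columns: n_i, s_i
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int l = grid[idx3(i, j, k, nx, ny)];
        if (l == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int i2 = i + dx, j2 = j + dy, k2 = k + dz;
              if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
                continue;
              int l2 = grid[idx3(i2, j2, k2, nx, ny)];
              if (l2 != 0) { sum += l2; cnt++; }
            }
        out(l - 1, 0) += 1.0;
        if (cnt > 0) out(l - 1, 1) += std::fabs((double)l - sum / cnt);
      }
  return out;
}
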
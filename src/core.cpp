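#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// symmetric (half-sample) boundary reflection: -1 -> 0, -2 -> 1, n -> n-1, ...
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1-D correlation along one axis of a 3-D array stored column-major (x fastest).
// out[i] = sum_t k[t] * x[i + t - center], reflect boundary.
// [[Rcpp::export]]
NumericVector cpp_correlate_axis(NumericVector vol, int nx, int ny, int nz,
                                 NumericVector kernel, int axis, int center) {
  int nk = kernel.size();
  NumericVector out(vol.size());
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  // strides
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = x * sx + y * sy + z * sz;
        int i = (axis == 0) ? x : (axis == 1) ? y : z;
        R_xlen_t line0 = base - (R_xlen_t)i * stride;
        double acc = 0.0;
        for (int t = 0; t < nk; ++t) {
          int j = reflect_idx(i + t - center, n);
          acc += kernel[t] * vol[line0 + (R_xlen_t)j * stride];
        }
        out[base] = acc;
      }
    }
  }
  return out;
}

// the 13 unique direction offsets of the 26-neighbourhood (one per +/- pair)
static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{1,1,0},{-1,1,0},
  {0,0,1},{1,0,1},{-1,0,1},{0,1,1},{0,-1,1},
  {1,1,1},{-1,1,1},{1,-1,1},{-1,-1,1}
};

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// levels: full 3-D integer array, values 0..Ng-1 inside the ROI, -1 outside.
// Returns per-direction GLCM counts (ordered pairs, not yet symmetrised).
// [[Rcpp::export]]
List cpp_glcm(IntegerVector levels, int nx, int ny, int nz, int ng) {
  List out(13);
  for (int d = 0; d < 13; ++d) {
    IntegerMatrix m(ng, ng);
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
          if (a < 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inside(x2, y2, z2, nx, ny, nz)) continue;
          int b = levels[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
          if (b < 0) continue;
          m(a, b) += 1;
        }
    out[d] = m;
  }
  return out;
}

// Gray-level run-length counts per direction; a run is a maximal streak of
// in-mask voxels with equal level along the direction.
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, int nx, int ny, int nz, int ng) {
  int max_run = std::max(std::max(nx, ny), nz);
  List out(13);
  for (int d = 0; d < 13; ++d) {
    IntegerMatrix m(ng, max_run);
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
          if (a < 0) continue;
          // run start: predecessor absent, out of mask, or different level
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inside(xp, yp, zp, nx, ny, nz)) {
            int p = levels[xp + (R_xlen_t)nx * (yp + (R_xlen_t)ny * zp)];
            if (p == a) continue;
          }
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (inside(xc, yc, zc, nx, ny, nz) &&
                 levels[xc + (R_xlen_t)nx * (yc + (R_xlen_t)ny * zc)] == a) {
            ++len; xc += dx; yc += dy; zc += dz;
          }
          m(a, len - 1) += 1;
        }
    out[d] = m;
  }
  return out;
}

// Size-zone enumeration: 26-connected components of equal level.
// Returns a matrix with columns (level, zone size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, int nx, int ny, int nz) {
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(nvox, 0);
  std::vector<int> zl, zs;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (seen[v] || levels[v] < 0) continue;
    int lev = levels[v];
    int size = 0;
    stack.clear(); stack.push_back(v); seen[v] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      ++size;
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny), z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
            R_xlen_t w = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
            if (!seen[w] && levels[w] == lev) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zl.push_back(lev); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  return out;
}

// Dependence counts: for each in-mask voxel, number of in-mask 26-neighbours
// whose |level difference| <= alpha. Returns an ng x 27 matrix of counts.
// [[Rcpp::export]]
IntegerMatrix cpp_gldm(IntegerVector levels, int nx, int ny, int nz, int ng, int alpha) {
  IntegerMatrix m(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        if (a < 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inside(x2, y2, z2, nx, ny, nz)) continue;
              int b = levels[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
              if (b >= 0 && std::abs(b - a) <= alpha) ++dep;
            }
        m(a, dep) += 1;
      }
  return m;
}

// NGTDM accumulators: per level, count of voxels with a valid neighbourhood
// and summed |level - mean(in-mask neighbour levels)|.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, int nx, int ny, int nz, int ng) {
  IntegerVector n(ng);
  NumericVector s(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        if (a < 0) continue;
        double acc = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inside(x2, y2, z2, nx, ny, nz)) continue;
              int b = levels[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
              if (b >= 0) { acc += b; ++cnt; }
            }
        if (cnt > 0) { n[a] += 1; s[a] += std::abs((double)a - acc / cnt); }
      }
  return List::create(_["n"] = n, _["s"] = s);
}

// Felzenszwalb 1-D squared distance transform (lower envelope of parabolas)
static void dt1d(std::vector<double>& f, double w2, std::vector<double>& d) {
  int n = (int)f.size();
  std::vector<int> v(n); std::vector<double> zb(n + 1);
  int k = 0; v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Euclidean distance (mm) from the foreground of a binary mask, on an
// anisotropic grid. Foreground voxels get distance 0.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, int nx, int ny, int nz,
                      double sx, double sy, double sz) {
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector d(nvox);
  const double BIG = 1e30;
  for (R_xlen_t i = 0; i < nvox; ++i) d[i] = mask[i] ? 0.0 : BIG;
  std::vector<double> f, g;
  // x pass
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, sx * sx, g);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // y pass
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, sy * sy, g);
      for (int y = 0; y < ny; ++y) d[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = g[y];
    }
  // z pass
  f.resize(nz); g.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, sz * sz, g);
      for (int z = 0; z < nz; ++z) d[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = g[z];
    }
  for (R_xlen_t i = 0; i < nvox; ++i) d[i] = std::sqrt(d[i]);
  return d;
}

// Bilinear in-plane resampling: every slice is sampled at (xs, ys) given in
// 0-based voxel coordinates; out-of-field samples take `fill`.
// xs, ys have length nx*ny (one source coordinate per in-plane output voxel,
// shared across slices).
// [[Rcpp::export]]
NumericVector cpp_resample_inplane(NumericVector vol, int nx, int ny, int nz,
                                   NumericVector xs, NumericVector ys, double fill) {
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z) {
    R_xlen_t zoff = (R_xlen_t)nx * ny * z;
    for (R_xlen_t p = 0; p < (R_xlen_t)nx * ny; ++p) {
      double x = xs[p], y = ys[p];
      if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) { out[zoff + p] = fill; continue; }
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
      double fx = x - x0, fy = y - y0;
      double v00 = vol[zoff + x0 + (R_xlen_t)nx * y0];
      double v10 = vol[zoff + x1 + (R_xlen_t)nx * y0];
      double v01 = vol[zoff + x0 + (R_xlen_t)nx * y1];
      double v11 = vol[zoff + x1 + (R_xlen_t)nx * y1];
      out[zoff + p] = (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
                      (1 - fx) * fy * v01 + fx * fy * v11;
    }
  }
  return out;
}

// Slice-wise bilinear warp through a displacement field (dz == 0): output
// voxel (x,y,z) samples the input at (x + dx(x,y,z), y + dy(x,y,z), z).
// [[Rcpp::export]]
NumericVector cpp_warp_field(NumericVector vol, int nx, int ny, int nz,
                             NumericVector dx, NumericVector dy, double fill) {
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z) {
    R_xlen_t zoff = (R_xlen_t)nx * ny * z;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = zoff + x + (R_xlen_t)nx * y;
        double xs = x + dx[v], ys = y + dy[v];
        if (xs < 0 || ys < 0 || xs > nx - 1 || ys > ny - 1) { out[v] = fill; continue; }
        int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
        double fx = xs - x0, fy = ys - y0;
        double v00 = vol[zoff + x0 + (R_xlen_t)nx * y0];
        double v10 = vol[zoff + x1 + (R_xlen_t)nx * y0];
        double v01 = vol[zoff + x0 + (R_xlen_t)nx * y1];
        double v11 = vol[zoff + x1 + (R_xlen_t)nx * y1];
        out[v] = (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
                 (1 - fx) * fy * v01 + fx * fy * v11;
      }
  }
  return out;
}
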
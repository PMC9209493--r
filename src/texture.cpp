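#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
using namespace Rcpp;

// Texture matrices on a 3D discretized region. `levels` is an integer array
// (dim attribute required) with 0 outside the region and 1..nlevels inside.
// Geometry conventions: distance-1 neighbourhoods, 13 unique 3D directions
// for GLCM/GLRLM (the 26-neighbourhood halved by central symmetry),
// 26-connectivity for GLSZM zones and NGTDM/NGLDM neighbourhoods.

static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, int nlevels) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix avg(nlevels, nlevels);
  int used = 0;
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    std::vector<double> cnt((size_t)nlevels * nlevels, 0.0);
    double total = 0.0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
            continue;
          int b = levels[idx3(X, Y, Z, nx, ny)];
          if (b == 0) continue;
          // symmetric: count the pair in both orders
          cnt[(a - 1) + (size_t)nlevels * (b - 1)] += 1.0;
          cnt[(b - 1) + (size_t)nlevels * (a - 1)] += 1.0;
          total += 2.0;
        }
    if (total == 0.0) continue;
    ++used;
    for (int j = 0; j < nlevels; ++j)
      for (int i = 0; i < nlevels; ++i)
        avg(i, j) += cnt[i + (size_t)nlevels * j] / total;
  }
  if (used > 0)
    for (int j = 0; j < nlevels; ++j)
      for (int i = 0; i < nlevels; ++i)
        avg(i, j) /= used;
  return avg;
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, int nlevels) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxdim = std::max(nx, std::max(ny, nz));
  // runs cannot exceed the bounding-box diagonal in voxels
  int maxrun = maxdim;
  NumericMatrix acc(nlevels, maxrun);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          // run start: predecessor out of bounds, out of region, or different
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz
              && levels[idx3(px, py, pz, nx, ny)] == a)
            continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny &&
                 cz >= 0 && cz < nz &&
                 levels[idx3(cx, cy, cz, nx, ny)] == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          if (len > maxrun) len = maxrun;  // cannot happen; safety
          acc(a - 1, len - 1) += 1.0;
        }
  }
  // average counts over the 13 directions
  for (int j = 0; j < maxrun; ++j)
    for (int i = 0; i < nlevels; ++i)
      acc(i, j) /= 13.0;
  // trim all-zero trailing run-length columns
  int keep = 1;
  for (int j = maxrun - 1; j >= 0; --j) {
    bool nonzero = false;
    for (int i = 0; i < nlevels; ++i) if (acc(i, j) > 0) { nonzero = true; break; }
    if (nonzero) { keep = j + 1; break; }
  }
  if (keep == maxrun) return acc;
  NumericMatrix out(nlevels, keep);
  for (int j = 0; j < keep; ++j)
    for (int i = 0; i < nlevels; ++i)
      out(i, j) = acc(i, j);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, int nlevels) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones;  // (level, size)
  int maxsize = 1;
  std::deque<int> queue;
  for (int s = 0; s < n; ++s) {
    int lev = levels[s];
    if (lev == 0 || seen[s]) continue;
    // BFS flood fill, 26-connected, same level
    int size = 0;
    seen[s] = 1;
    queue.push_back(s);
    while (!queue.empty()) {
      int v = queue.front(); queue.pop_front();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            int w = idx3(X, Y, Z, nx, ny);
            if (!seen[w] && levels[w] == lev) { seen[w] = 1; queue.push_back(w); }
          }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix out(nlevels, maxsize);
  for (size_t k = 0; k < zones.size(); ++k)
    out(zones[k].first - 1, zones[k].second - 1) += 1.0;
  return out;
}

// Returns an nlevels x 2 matrix: column 1 = n_i (voxels of level i with at
// least one in-region 26-neighbour), column 2 = s_i (summed absolute
// difference between the level and its neighbourhood mean level).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, int nlevels) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(nlevels, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              int b = levels[idx3(X, Y, Z, nx, ny)];
              if (b == 0) continue;  // only in-region neighbours
              sum += b; ++cnt;
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::abs((double)a - sum / cnt);
      }
  return out;
}

// Dependence matrix: entry (i, k+1) counts in-region voxels of level i with
// exactly k in-region 26-neighbours of the same level (alpha = 0).
// [[Rcpp::export]]
NumericMatrix cpp_ngldm(IntegerVector levels, int nlevels) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(nlevels, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              if (levels[idx3(X, Y, Z, nx, ny)] == a) ++k;
            }
        out(a - 1, k) += 1.0;
      }
  return out;
}
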
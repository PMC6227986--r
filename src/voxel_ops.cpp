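// Low-level voxel-grid operations for vessel morphometry:
// surface rasterization, exterior flood fill, parity inside-tests for
// boundary voxels, topology-preserving 3D thinning, chamfer distance
// transform and connected-component labelling.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Mark every voxel touched by the triangulated surface.  Triangles are
// sampled on a barycentric lattice fine enough (0.2 h) that each voxel the
// surface passes through receives at least one sample, so the marked set
// separates interior from exterior under 6-connected flood fill.
// [[Rcpp::export]]
LogicalVector cpp_mark_shell(const NumericMatrix& V, const IntegerMatrix& F,
                             const NumericVector& origin, double h,
                             const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector shell(nx * ny * nz, false);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double step = 0.2 * h;
  for (int f = 0; f < F.nrow(); ++f) {
    const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double p0[3] = {V(a,0), V(a,1), V(a,2)};
    double e1[3] = {V(b,0)-p0[0], V(b,1)-p0[1], V(b,2)-p0[2]};
    double e2[3] = {V(c,0)-p0[0], V(c,1)-p0[1], V(c,2)-p0[2]};
    double l1 = std::sqrt(e1[0]*e1[0]+e1[1]*e1[1]+e1[2]*e1[2]);
    double l2 = std::sqrt(e2[0]*e2[0]+e2[1]*e2[1]+e2[2]*e2[2]);
    double d0 = e1[0]-e2[0], d1 = e1[1]-e2[1], d2 = e1[2]-e2[2];
    double l3 = std::sqrt(d0*d0 + d1*d1 + d2*d2);
    double lmax = std::max(l1, std::max(l2, l3));
    int n = std::max(1, (int)std::ceil(lmax / step));
    for (int ia = 0; ia <= n; ++ia) {
      const double u = (double)ia / n;
      for (int ib = 0; ib <= n - ia; ++ib) {
        const double v = (double)ib / n;
        const double px = p0[0] + u*e1[0] + v*e2[0];
        const double py = p0[1] + u*e1[1] + v*e2[1];
        const double pz = p0[2] + u*e1[2] + v*e2[2];
        const int i = (int)std::llround((px - ox) / h);
        const int j = (int)std::llround((py - oy) / h);
        const int k = (int)std::llround((pz - oz) / h);
        if (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
          shell[idx3(i, j, k, nx, ny)] = true;
      }
    }
  }
  return shell;
}

// 6-connected flood from the grid boundary through non-barrier voxels.
// [[Rcpp::export]]
LogicalVector cpp_flood_exterior(const LogicalVector& barrier,
                                 const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  LogicalVector ext(n, false);
  std::queue<int> q;
  auto push = [&](int i, int j, int k) {
    int id = idx3(i, j, k, nx, ny);
    if (!barrier[id] && !ext[id]) { ext[id] = true; q.push(id); }
  };
  for (int j = 0; j < ny; ++j)
    for (int k = 0; k < nz; ++k) { push(0, j, k); push(nx - 1, j, k); }
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) { push(i, 0, k); push(i, ny - 1, k); }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) { push(i, j, 0); push(i, j, nz - 1); }
  while (!q.empty()) {
    int id = q.front(); q.pop();
    int k = id / (nx * ny), r = id % (nx * ny), j = r / nx, i = r % nx;
    if (i > 0)      push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0)      push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0)      push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  return ext;
}

// Parity inside-test (+z ray) for the voxel centers given by `cells`
// (0-based linear indices).  Faces are bucketed by their xy bounding box so
// each ray only visits nearby triangles; the ray origin is jittered by an
// irrational sub-voxel offset to avoid edge/vertex coincidences.
// [[Rcpp::export]]
LogicalVector cpp_inside_parity(const NumericMatrix& V, const IntegerMatrix& F,
                                const NumericVector& origin, double h,
                                const IntegerVector& dims,
                                const IntegerVector& cells) {
  const int nx = dims[0], ny = dims[1];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int nf = F.nrow();
  std::vector<std::vector<int>> bucket((size_t)nx * ny);
  for (int f = 0; f < nf; ++f) {
    double xs[3], ys[3];
    for (int v = 0; v < 3; ++v) {
      xs[v] = V(F(f, v) - 1, 0); ys[v] = V(F(f, v) - 1, 1);
    }
    double xmin = std::min(xs[0], std::min(xs[1], xs[2]));
    double xmax = std::max(xs[0], std::max(xs[1], xs[2]));
    double ymin = std::min(ys[0], std::min(ys[1], ys[2]));
    double ymax = std::max(ys[0], std::max(ys[1], ys[2]));
    int i0 = std::max(0, (int)std::floor((xmin - ox) / h - 0.6));
    int i1 = std::min(nx - 1, (int)std::ceil((xmax - ox) / h + 0.6));
    int j0 = std::max(0, (int)std::floor((ymin - oy) / h - 0.6));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - oy) / h + 0.6));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bucket[(size_t)i + (size_t)nx * j].push_back(f);
  }
  const double jx = 1.23456789e-4 * h, jy = 0.98765432e-4 * h;
  const int nq = cells.size();
  LogicalVector inside(nq, false);
  for (int q = 0; q < nq; ++q) {
    int id = cells[q];
    int k = id / (nx * ny), r = id % (nx * ny), j = r / nx, i = r % nx;
    const double x = ox + i * h + jx, y = oy + j * h + jy, z = oz + k * h;
    int crossings = 0;
    for (int f : bucket[(size_t)i + (size_t)nx * j]) {
      const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      const double x0 = V(a,0) - x, y0 = V(a,1) - y;
      const double x1 = V(b,0) - x, y1 = V(b,1) - y;
      const double x2 = V(c,0) - x, y2 = V(c,1) - y;
      // 2D barycentric test at the ray's (x, y)
      const double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
      if (det == 0.0) continue;
      const double l1 = (-x0 * (y2 - y0) - (-y0) * (x2 - x0)) / det;
      const double l2 = ((x1 - x0) * (-y0) - (y1 - y0) * (-x0)) / det;
      if (l1 < 0.0 || l2 < 0.0 || l1 + l2 > 1.0) continue;
      const double zhit = V(a,2) + l1 * (V(b,2) - V(a,2)) + l2 * (V(c,2) - V(a,2));
      if (zhit > z) ++crossings;
    }
    inside[q] = (crossings % 2) == 1;
  }
  return inside;
}

// ---- topology-preserving thinning -----------------------------------------

// Simple-point test for the (26, 6) digital topology: the voxel may be
// deleted iff the object voxels of its 26-neighbourhood form one
// 26-connected component and the background voxels of its 18-neighbourhood
// that touch a face-neighbour form one 6-connected component
// (Malandain & Bertrand characterization).
static bool is_simple(const uint8_t* nb) {
  // nb: 27 occupancy flags of the 3x3x3 cube, index (dx+1)+3*(dy+1)+9*(dz+1)
  // --- C*: 26-components of object voxels among the 26 neighbours
  int labels[27]; for (int i = 0; i < 27; ++i) labels[i] = -1;
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || labels[s] >= 0) continue;
    if (++ncomp > 1) return false;      // early exit: component count > 1
    // BFS
    int stack[27]; int top = 0; stack[top++] = s; labels[s] = ncomp;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int tx = cx + dx, ty = cy + dy, tz = cz + dz;
          if (tx < 0 || tx > 2 || ty < 0 || ty > 2 || tz < 0 || tz > 2) continue;
          int t = tx + 3 * ty + 9 * tz;
          if (t == 13 || !nb[t] || labels[t] >= 0) continue;
          labels[t] = ncomp; stack[top++] = t;
        }
    }
  }
  if (ncomp != 1) return false;
  // --- Cbar: 6-components of background in the 18-neighbourhood that are
  // 6-adjacent to the center
  int lab2[27]; for (int i = 0; i < 27; ++i) lab2[i] = -1;
  static const int face[6] = {4, 10, 12, 14, 16, 22}; // 6-neighbours of center
  int nback = 0;
  for (int fi = 0; fi < 6; ++fi) {
    int s = face[fi];
    if (nb[s] || lab2[s] >= 0) continue;
    if (++nback > 1) return false;
    int stack[18]; int top = 0; stack[top++] = s; lab2[s] = nback;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int d = 0; d < 6; ++d) {
        int tx = cx + d6[d][0], ty = cy + d6[d][1], tz = cz + d6[d][2];
        if (tx < 0 || tx > 2 || ty < 0 || ty > 2 || tz < 0 || tz > 2) continue;
        int t = tx + 3 * ty + 9 * tz;
        if (t == 13 || nb[t] || lab2[t] >= 0) continue;
        // stay inside the 18-neighbourhood
        int adx = std::abs(tx - 1), ady = std::abs(ty - 1), adz = std::abs(tz - 1);
        if (adx + ady + adz > 2) continue;
        lab2[t] = nback; stack[top++] = t;
      }
    }
  }
  return nback == 1;
}

static inline void fill_nb(const std::vector<uint8_t>& occ, int i, int j, int k,
                           int nx, int ny, int nz, uint8_t* nb) {
  int s = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++s) {
        int x = i + dx, y = j + dy, z = k + dz;
        nb[s] = (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz)
                  ? occ[idx3(x, y, z, nx, ny)] : 0;
      }
}

static inline int count_nbrs(const uint8_t* nb) {
  int c = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++c;
  return c;
}

// Curve-endpoint criterion protecting staircase tips: a digital curve tip
// may have two neighbours that are mutually 26-adjacent (a diagonal step);
// deleting such tips would let the curve retract voxel by voxel.
static inline bool is_curve_end(const uint8_t* nb) {
  int idx[2]; int c = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s]) continue;
    if (c < 2) idx[c] = s;
    if (++c > 2) return false;
  }
  if (c <= 1) return true;
  const int ax = idx[0] % 3, ay = (idx[0] / 3) % 3, az = idx[0] / 9;
  const int bx = idx[1] % 3, by = (idx[1] / 3) % 3, bz = idx[1] / 9;
  return std::abs(ax - bx) <= 1 && std::abs(ay - by) <= 1 &&
         std::abs(az - bz) <= 1;
}

// Curve-skeleton thinning: iteratively delete simple border points in six
// directional subiterations, keeping curve endpoints (<= 1 object neighbour).
// Deletion within a subiteration is sequential with re-checking, which
// guarantees topology preservation.
// [[Rcpp::export]]
LogicalVector cpp_thin(const LogicalVector& occupancy, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<uint8_t> occ(n);
  for (int i = 0; i < n; ++i) occ[i] = occupancy[i];
  static const int dir[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  uint8_t nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<int> cand;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int id = idx3(i, j, k, nx, ny);
            if (!occ[id]) continue;
            int x = i + dir[d][0], y = j + dir[d][1], z = k + dir[d][2];
            bool border = !(x >= 0 && x < nx && y >= 0 && y < ny &&
                            z >= 0 && z < nz && occ[idx3(x, y, z, nx, ny)]);
            if (!border) continue;
            fill_nb(occ, i, j, k, nx, ny, nz, nb);
            if (is_curve_end(nb)) continue;      // keep curve endpoints
            if (is_simple(nb)) cand.push_back(id);
          }
      for (int id : cand) {
        int k = id / (nx * ny), r = id % (nx * ny), j = r / nx, i = r % nx;
        fill_nb(occ, i, j, k, nx, ny, nz, nb);
        if (is_curve_end(nb)) continue;
        if (is_simple(nb)) { occ[id] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = occ[i] != 0;
  return out;
}

// Chamfer (3,4,5) distance transform to the background; returns distances in
// weight units (divide by 3 and multiply by spacing for mm).
// [[Rcpp::export]]
IntegerVector cpp_chamfer_dt(const LogicalVector& occupancy,
                             const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int INF = 1 << 28;
  std::vector<int> d(n);
  for (int i = 0; i < n; ++i) d[i] = occupancy[i] ? INF : 0;
  auto w = [](int dx, int dy, int dz) {
    int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
    return s == 1 ? 3 : (s == 2 ? 4 : 5);
  };
  // forward pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = idx3(i, j, k, nx, ny);
        if (d[id] == 0) continue;
        int best = d[id];
        for (int dz = -1; dz <= 0; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
              int x = i + dx, y = j + dy, z = k + dz;
              if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0) continue;
              best = std::min(best, d[idx3(x, y, z, nx, ny)] + w(dx, dy, dz));
            }
        d[id] = best;
      }
  // backward pass
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        int id = idx3(i, j, k, nx, ny);
        if (d[id] == 0) continue;
        int best = d[id];
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0))) continue;
              int x = i + dx, y = j + dy, z = k + dz;
              if (x < 0 || x >= nx || y < 0 || y >= ny || z >= nz) continue;
              best = std::min(best, d[idx3(x, y, z, nx, ny)] + w(dx, dy, dz));
            }
        d[id] = best;
      }
  return IntegerVector(d.begin(), d.end());
}

// Connected-component labelling (conn = 6 or 26); background label 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& occupancy,
                                   const IntegerVector& dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int seed = 0; seed < n; ++seed) {
    if (!occupancy[seed] || lab[seed]) continue;
    lab[seed] = ++next; q.push(seed);
    while (!q.empty()) {
      int id = q.front(); q.pop();
      int k = id / (nx * ny), r = id % (nx * ny), j = r / nx, i = r % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (conn == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            int x = i + dx, y = j + dy, z = k + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            int id2 = idx3(x, y, z, nx, ny);
            if (occupancy[id2] && !lab[id2]) { lab[id2] = next; q.push(id2); }
          }
    }
  }
  return lab;
}
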
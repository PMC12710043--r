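#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxel volumes are stored as R logical arrays with dims (nx, ny, nz) and
// linear index i + nx*(j + ny*k) (0-based here, 1-based on the R side).

// ---------------------------------------------------------------------------
// Visual-hull carving: a voxel stays occupied iff its center projects onto a
// foreground pixel in every view. Projection is a 3x4 matrix acting on
// (x, y, z, 1); projective views divide by the third row.
// [[Rcpp::export]]
LogicalVector carve_cpp(IntegerVector dims, NumericVector origin, double vs,
                        List views) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);

  const int nv = views.size();
  std::vector<std::vector<double>> P(nv);
  std::vector<bool> projective(nv);
  std::vector<LogicalMatrix> masks;
  std::vector<int> H(nv), W(nv);
  for (int v = 0; v < nv; ++v) {
    List vw = views[v];
    NumericMatrix Pm = vw["P"];
    std::vector<double> p(12);
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 4; ++c) p[r * 4 + c] = Pm(r, c);
    P[v] = p;
    projective[v] = as<bool>(vw["projective"]);
    LogicalMatrix m = vw["mask"];
    masks.push_back(m);
    H[v] = m.nrow();
    W[v] = m.ncol();
  }

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + (k + 0.5) * vs;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + (j + 0.5) * vs;
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = origin[0] + (i + 0.5) * vs;
        bool occ = true;
        for (int v = 0; v < nv && occ; ++v) {
          const std::vector<double> &p = P[v];
          double r0 = p[0] * x + p[1] * y + p[2] * z + p[3];
          double c0 = p[4] * x + p[5] * y + p[6] * z + p[7];
          if (projective[v]) {
            double w = p[8] * x + p[9] * y + p[10] * z + p[11];
            if (w <= 0) { occ = false; break; }
            r0 /= w; c0 /= w;
          }
          int ri = (int)std::lround(r0);
          int ci = (int)std::lround(c0);
          if (ri < 0 || ri >= H[v] || ci < 0 || ci >= W[v] ||
              !masks[v](ri, ci))
            occ = false;
        }
        out[idx] = occ;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test for (26, 6) connectivity. A voxel is simple iff deleting
// it preserves topology: exactly one 26-component of object voxels in the
// punctured 3x3x3 neighborhood, and exactly one 6-component of background
// voxels in the 18-neighborhood that touches a face neighbor.

static inline int nb_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool neighborhood(const std::vector<signed char> &vol, int nx, int ny,
                         int nz, int x, int y, int z, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = false;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          v = vol[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] != 0;
        nb[nb_index(dx, dy, dz)] = v;
      }
  return true;
}

static bool adj26(int a, int b) {
  int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
  int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
  int dx = std::abs(ax - bx), dy = std::abs(ay - by), dz = std::abs(az - bz);
  return (dx <= 1 && dy <= 1 && dz <= 1) && (dx + dy + dz > 0);
}

static bool adj6(int a, int b) {
  int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
  int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
  return std::abs(ax - bx) + std::abs(ay - by) + std::abs(az - bz) == 1;
}

static bool is_simple(const bool nb[27]) {
  const int C = 13; // center
  // T26: 26-components of object voxels in N26*(center)
  int labels[27];
  for (int i = 0; i < 27; ++i) labels[i] = -1;
  int ncomp26 = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == C || !nb[i] || labels[i] >= 0) continue;
    // BFS
    std::vector<int> stack(1, i);
    labels[i] = ncomp26;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int w = 0; w < 27; ++w) {
        if (w == C || !nb[w] || labels[w] >= 0) continue;
        if (adj26(u, w)) { labels[w] = ncomp26; stack.push_back(w); }
      }
    }
    ++ncomp26;
  }
  if (ncomp26 != 1) return false;

  // T6: 6-components of background voxels within the 18-neighborhood,
  // counted only when they contain a face neighbor of the center.
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3, y = (i / 3) % 3, z = i / 9;
    int d = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
    in18[i] = (d >= 1 && d <= 2);
  }
  int lab6[27];
  for (int i = 0; i < 27; ++i) lab6[i] = -1;
  int ncomp6 = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || lab6[i] >= 0) continue;
    bool touches_face = false;
    std::vector<int> stack(1, i);
    lab6[i] = ncomp6;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int ux = u % 3, uy = (u / 3) % 3, uz = u / 9;
      if (std::abs(ux - 1) + std::abs(uy - 1) + std::abs(uz - 1) == 1)
        touches_face = true;
      for (int w = 0; w < 27; ++w) {
        if (!in18[w] || nb[w] || lab6[w] >= 0) continue;
        if (adj6(u, w)) { lab6[w] = ncomp6; stack.push_back(w); }
      }
    }
    if (touches_face) ++ncomp6;
  }
  return ncomp6 == 1;
}

// [[Rcpp::export]]
bool is_simple_point_cpp(LogicalVector occ, IntegerVector dims,
                         IntegerVector at) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<signed char> vol(occ.size());
  for (R_xlen_t i = 0; i < occ.size(); ++i) vol[i] = occ[i] ? 1 : 0;
  bool nb[27];
  neighborhood(vol, nx, ny, nz, at[0], at[1], at[2], nb);
  return is_simple(nb);
}

// ---------------------------------------------------------------------------
// Curve thinning: sequential deletion of simple, non-endpoint border points,
// in six fixed sub-iteration directions. Endpoints (<= 1 object neighbor in
// N26) are retained so that curve tips survive. Deterministic: fixed
// direction order and ascending linear scan order.
// [[Rcpp::export]]
IntegerVector thin_cpp(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<signed char> vol(occ.size());
  std::vector<R_xlen_t> live;
  for (R_xlen_t i = 0; i < occ.size(); ++i) {
    vol[i] = occ[i] ? 1 : 0;
    if (vol[i]) live.push_back(i);
  }
  const int dirs[6][3] = {{0, 0, 1},  {0, 0, -1}, {0, 1, 0},
                          {0, -1, 0}, {1, 0, 0},  {-1, 0, 0}};
  bool nb[27];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // candidates: voxels that are border points in this direction at the
      // START of the sub-iteration (one layer per pass)
      cand.clear();
      for (size_t li = 0; li < live.size(); ++li) {
        R_xlen_t id = live[li];
        if (!vol[id]) continue;
        int x = (int)(id % nx);
        int y = (int)((id / nx) % ny);
        int z = (int)(id / ((R_xlen_t)nx * ny));
        int bx = x + dirs[d][0], by = y + dirs[d][1], bz = z + dirs[d][2];
        bool border;
        if (bx < 0 || bx >= nx || by < 0 || by >= ny || bz < 0 || bz >= nz)
          border = true;
        else
          border = vol[(R_xlen_t)bx + (R_xlen_t)nx * (by + (R_xlen_t)ny * bz)] == 0;
        if (border) cand.push_back(id);
      }
      // sequential deletion with simplicity re-checked at deletion time
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        R_xlen_t id = cand[ci];
        if (!vol[id]) continue;
        int x = (int)(id % nx);
        int y = (int)((id / nx) % ny);
        int z = (int)(id / ((R_xlen_t)nx * ny));
        neighborhood(vol, nx, ny, nz, x, y, z, nb);
        int ncount = 0, n1 = -1, n2 = -1;
        for (int q = 0; q < 27; ++q)
          if (q != 13 && nb[q]) {
            ++ncount;
            if (n1 < 0) n1 = q; else if (n2 < 0) n2 = q;
          }
        if (ncount <= 1) continue; // endpoint, keep
        // wedge tip of a thick diagonal line: two mutually adjacent
        // neighbors; removing it would let the line nibble itself away
        if (ncount == 2 && adj26(n1, n2)) continue;
        if (is_simple(nb)) {
          vol[id] = 0;
          changed = true;
        }
      }
    }
    // compact the live list
    size_t w = 0;
    for (size_t li = 0; li < live.size(); ++li)
      if (vol[live[li]]) live[w++] = live[li];
    live.resize(w);
  }
  IntegerVector out(live.size());
  for (size_t i = 0; i < live.size(); ++i) out[i] = (int)(live[i] + 1);
  return out;
}

// ---------------------------------------------------------------------------
// Local radius: distance (in voxels) from each node to the nearest background
// voxel of the hull, searched over offsets sorted by distance up to rmax.
// [[Rcpp::export]]
NumericVector local_radius_cpp(LogicalVector hull, IntegerVector dims,
                               IntegerMatrix nodes, int rmax) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  struct Off { int dx, dy, dz; double d; };
  std::vector<Off> offs;
  for (int dz = -rmax; dz <= rmax; ++dz)
    for (int dy = -rmax; dy <= rmax; ++dy)
      for (int dx = -rmax; dx <= rmax; ++dx) {
        double d = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        if (d <= rmax && d > 0) offs.push_back({dx, dy, dz, d});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &a, const Off &b) { return a.d < b.d; });
  NumericVector out(nodes.nrow());
  for (int r = 0; r < nodes.nrow(); ++r) {
    int x = nodes(r, 0), y = nodes(r, 1), z = nodes(r, 2);
    double rad = rmax;
    for (const Off &o : offs) {
      int xx = x + o.dx, yy = y + o.dy, zz = z + o.dz;
      bool bg;
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        bg = true;
      else
        bg = hull[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] == 0;
      if (bg) { rad = o.d; break; }
    }
    out[r] = rad;
  }
  return out;
}
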
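// Voxel-level kernels: watershed edge tracing, greedy vertex painting,
// local-minimum detection, ball/capsule mask rendering, 3x3x3 median.
// Axis order everywhere is (z, y, x) with z fastest (R column-major);
// linear indices are 0-based here and converted at the R boundary.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
#include <climits>

using namespace Rcpp;

static inline void lin2sub(long long lin, int nz, int ny,
                           int &z, int &y, int &x) {
  z = (int)(lin % nz);
  long long r = lin / nz;
  y = (int)(r % ny);
  x = (int)(r / ny);
}

// [[Rcpp::export]]
IntegerVector cpp_local_minima(NumericVector energy, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> out;
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      long long lin = z + (long long)nz * (y + (long long)ny * x);
      double e = energy[lin];
      if (!(e < 0)) continue;
      bool ok = true;
      for (int dx = -1; dx <= 1 && ok; ++dx)
        for (int dy = -1; dy <= 1 && ok; ++dy)
          for (int dz = -1; dz <= 1 && ok; ++dz) {
            if (!dx && !dy && !dz) continue;
            int z2 = z + dz, y2 = y + dy, x2 = x + dx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                x2 < 0 || x2 >= nx) continue;
            long long l2 = z2 + (long long)nz * (y2 + (long long)ny * x2);
            double e2 = energy[l2];
            // strict minimum; exact ties broken toward the earlier
            // (lexicographically smaller) voxel for determinism
            if (e2 < e || (e2 == e && l2 < lin)) ok = false;
          }
      if (ok) out.push_back((int)(lin + 1)); // 1-based for R
    }
  return wrap(out);
}

// Greedy non-overlap painting: candidates must arrive sorted by ascending
// energy. A candidate is accepted iff its centre voxel is not yet inside a
// previously painted ball; accepted balls (physical radius, anisotropic
// voxels) are painted into the mask.
// [[Rcpp::export]]
LogicalVector cpp_paint_vertices(IntegerVector cand, NumericVector radius,
                                 IntegerVector dims, NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  std::vector<char> mask((size_t)nz * ny * nx, 0);
  int n = cand.size();
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    long long lin = (long long)cand[i] - 1;
    if (mask[lin]) { keep[i] = false; continue; }
    keep[i] = true;
    int z, y, x;
    lin2sub(lin, nz, ny, z, y, x);
    double r = radius[i];
    int bz = (int)std::floor(r / sz), by = (int)std::floor(r / sy),
        bx = (int)std::floor(r / sx);
    double r2 = r * r;
    for (int dx = -bx; dx <= bx; ++dx) {
      int x2 = x + dx; if (x2 < 0 || x2 >= nx) continue;
      for (int dy = -by; dy <= by; ++dy) {
        int y2 = y + dy; if (y2 < 0 || y2 >= ny) continue;
        double dxy = dx * sx * dx * sx + dy * sy * dy * sy;
        if (dxy > r2) continue;
        for (int dz = -bz; dz <= bz; ++dz) {
          int z2 = z + dz; if (z2 < 0 || z2 >= nz) continue;
          if (dxy + dz * sz * dz * sz <= r2)
            mask[z2 + (long long)nz * (y2 + (long long)ny * x2)] = 1;
        }
      }
    }
  }
  return keep;
}

struct HeapItem {
  double e;
  long long lin;
  bool operator>(const HeapItem &o) const {
    return e > o.e || (e == o.e && lin > o.lin);
  }
};

// Best-first (watershed) exploration from each origin vertex. Returns a
// list of edges: origin id, terminal id, trace (1-based linear indices,
// terminal -> origin order). Per-origin sparse maps are epoch-stamped flat
// arrays so no per-origin allocation or hashing is needed.
// [[Rcpp::export]]
List cpp_trace_edges(NumericVector energy, IntegerVector dims,
                     NumericVector spacing, IntegerVector vert_lin,
                     int max_edges, NumericVector cap_um,
                     int max_explored) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long long N = (long long)nz * ny * nx;
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  int nv = vert_lin.size();
  std::vector<int> vertex_at(N, -1); // lin -> vertex id (0-based)
  std::vector<double> vpos(3 * nv);
  for (int i = 0; i < nv; ++i) {
    long long lin = (long long)vert_lin[i] - 1;
    vertex_at[lin] = i;
    int z, y, x; lin2sub(lin, nz, ny, z, y, x);
    vpos[3 * i] = z * sp[0]; vpos[3 * i + 1] = y * sp[1];
    vpos[3 * i + 2] = x * sp[2];
  }
  // epoch-stamped per-origin state
  std::vector<int> stamp(N, -1);
  std::vector<int> pointer(N);      // >= 0 explored idx; < 0 origin/edge
  std::vector<unsigned char> state(N); // 1 frontier, 2 visited
  std::vector<float> plen(N);
  const int PTR_ORIGIN = INT_MIN;
  List edges;
  for (int a = 0; a < nv; ++a) {
    std::vector<long long> explored;
    std::vector<int> found_terminals;
    std::priority_queue<HeapItem, std::vector<HeapItem>,
                        std::greater<HeapItem> > heap;
    long long loc = (long long)vert_lin[a] - 1;
    stamp[loc] = a; pointer[loc] = PTR_ORIGIN; state[loc] = 2;
    plen[loc] = 0.0f;
    int n_found = 0;
    double cap = cap_um[a];
    bool alive = true;
    while (alive) {
      int vb = vertex_at[loc];
      if (vb >= 0 && vb != a) {
        std::vector<long long> trace;
        long long cur = loc;
        trace.push_back(cur);
        while (pointer[cur] >= 0) {
          cur = explored[pointer[cur]];
          trace.push_back(cur);
        }
        ++n_found;
        for (size_t t = 0; t < trace.size(); ++t)
          pointer[trace[t]] = -n_found; // negative: belongs to an edge
        IntegerVector tr(trace.size());
        for (size_t t = 0; t < trace.size(); ++t)
          tr[t] = (int)(trace[t] + 1);
        edges.push_back(List::create(
          Named("origin") = a + 1, Named("terminal") = vb + 1,
          Named("trace") = tr));
        found_terminals.push_back(vb);
        if (n_found >= max_edges) break;
      }
      if ((int)explored.size() >= max_explored) break;
      explored.push_back(loc);
      int eidx = (int)explored.size() - 1;
      int z, y, x; lin2sub(loc, nz, ny, z, y, x);
      double lz = z * sp[0], ly = y * sp[1], lx = x * sp[2];
      double pl = plen[loc];
      for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int z2 = z + dz, y2 = y + dy, x2 = x + dx;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
              x2 < 0 || x2 >= nx) continue;
          long long l2 = z2 + (long long)nz * (y2 + (long long)ny * x2);
          if (stamp[l2] == a) continue; // write-once pointers
          double pz = z2 * sp[0], py = y2 * sp[1], px = x2 * sp[2];
          // beyond the facing plane of any found terminal B: half-space
          // through B with outward normal along B - A
          bool blocked = false;
          for (size_t t = 0; t < found_terminals.size() && !blocked; ++t) {
            int b = found_terminals[t];
            double nzb = vpos[3 * b] - vpos[3 * a];
            double nyb = vpos[3 * b + 1] - vpos[3 * a + 1];
            double nxb = vpos[3 * b + 2] - vpos[3 * a + 2];
            double dzb = pz - vpos[3 * b], dyb = py - vpos[3 * b + 1],
                   dxb = px - vpos[3 * b + 2];
            if (dzb * nzb + dyb * nyb + dxb * nxb > 0) blocked = true;
          }
          if (blocked) continue;
          double step = std::sqrt((pz - lz) * (pz - lz) +
                                  (py - ly) * (py - ly) +
                                  (px - lx) * (px - lx));
          if (pl + step > cap) continue; // trace-length limit
          stamp[l2] = a; pointer[l2] = eidx; state[l2] = 1;
          plen[l2] = (float)(pl + step);
          HeapItem h; h.e = energy[l2]; h.lin = l2;
          heap.push(h);
        }
      state[loc] = 2; // visited marker (energies are negative)
      alive = false;
      while (!heap.empty()) {
        HeapItem top = heap.top();
        heap.pop();
        if (stamp[top.lin] != a || state[top.lin] != 1) continue;
        if (!(top.e < 0)) break; // min energy >= 0: stop exploring
        state[top.lin] = 2;
        loc = top.lin;
        alive = true;
        break;
      }
    }
  }
  return edges;
}

// Stamp anisotropy-aware balls (centres in um, origin-relative) into a mask.
// [[Rcpp::export]]
LogicalVector cpp_stamp_balls(NumericMatrix centers, NumericVector radius,
                              IntegerVector dims, NumericVector spacing,
                              double radius_scale) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  size_t n = (size_t)nz * ny * nx;
  LogicalVector mask(n, false);
  for (int i = 0; i < centers.nrow(); ++i) {
    double cz = centers(i, 0), cy = centers(i, 1), cx = centers(i, 2);
    double r = radius[i] * radius_scale;
    if (r < 0) continue;
    int z0 = (int)std::ceil((cz - r) / sz), z1 = (int)std::floor((cz + r) / sz);
    int y0 = (int)std::ceil((cy - r) / sy), y1 = (int)std::floor((cy + r) / sy);
    int x0 = (int)std::ceil((cx - r) / sx), x1 = (int)std::floor((cx + r) / sx);
    z0 = std::max(z0, 0); z1 = std::min(z1, nz - 1);
    y0 = std::max(y0, 0); y1 = std::min(y1, ny - 1);
    x0 = std::max(x0, 0); x1 = std::min(x1, nx - 1);
    double r2 = r * r;
    for (int x = x0; x <= x1; ++x) {
      double ddx = x * sx - cx;
      for (int y = y0; y <= y1; ++y) {
        double ddy = y * sy - cy, dxy = ddx * ddx + ddy * ddy;
        if (dxy > r2) continue;
        for (int z = z0; z <= z1; ++z) {
          double ddz = z * sz - cz;
          if (dxy + ddz * ddz <= r2)
            mask[z + (long long)nz * (y + (long long)ny * x)] = true;
        }
      }
    }
  }
  return mask;
}

// Per-object sorted unique voxel lists for incremental threshold sweeps.
// group: 1-based object id per centre row.
// [[Rcpp::export]]
List cpp_ball_voxel_lists(NumericMatrix centers, NumericVector radius,
                          IntegerVector group, int n_groups,
                          IntegerVector dims, NumericVector spacing,
                          double radius_scale) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  std::vector< std::vector<long long> > vox(n_groups);
  for (int i = 0; i < centers.nrow(); ++i) {
    int g = group[i] - 1;
    double cz = centers(i, 0), cy = centers(i, 1), cx = centers(i, 2);
    double r = radius[i] * radius_scale;
    if (r < 0) continue;
    int z0 = std::max((int)std::ceil((cz - r) / sz), 0);
    int z1 = std::min((int)std::floor((cz + r) / sz), nz - 1);
    int y0 = std::max((int)std::ceil((cy - r) / sy), 0);
    int y1 = std::min((int)std::floor((cy + r) / sy), ny - 1);
    int x0 = std::max((int)std::ceil((cx - r) / sx), 0);
    int x1 = std::min((int)std::floor((cx + r) / sx), nx - 1);
    double r2 = r * r;
    for (int x = x0; x <= x1; ++x) {
      double ddx = x * sx - cx;
      for (int y = y0; y <= y1; ++y) {
        double ddy = y * sy - cy, dxy = ddx * ddx + ddy * ddy;
        if (dxy > r2) continue;
        for (int z = z0; z <= z1; ++z) {
          double ddz = z * sz - cz;
          if (dxy + ddz * ddz <= r2)
            vox[g].push_back(z + (long long)nz * (y + (long long)ny * x));
        }
      }
    }
  }
  List out(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    std::sort(vox[g].begin(), vox[g].end());
    vox[g].erase(std::unique(vox[g].begin(), vox[g].end()), vox[g].end());
    IntegerVector v(vox[g].size());
    for (size_t j = 0; j < vox[g].size(); ++j) v[j] = (int)(vox[g][j] + 1);
    out[g] = v;
  }
  return out;
}

// Capsule (tapered) rendering: voxel true iff within the linearly
// interpolated radius of some centreline segment.
// [[Rcpp::export]]
LogicalVector cpp_stamp_capsules(NumericMatrix p0, NumericMatrix p1,
                                 NumericVector r0, NumericVector r1,
                                 IntegerVector dims, NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  size_t n = (size_t)nz * ny * nx;
  LogicalVector mask(n, false);
  for (int i = 0; i < p0.nrow(); ++i) {
    double az = p0(i, 0), ay = p0(i, 1), ax = p0(i, 2);
    double bz = p1(i, 0), by = p1(i, 1), bx = p1(i, 2);
    double ra = r0[i], rb = r1[i], rmax = std::max(ra, rb);
    double loz = std::min(az, bz) - rmax, hiz = std::max(az, bz) + rmax;
    double loy = std::min(ay, by) - rmax, hiy = std::max(ay, by) + rmax;
    double lox = std::min(ax, bx) - rmax, hix = std::max(ax, bx) + rmax;
    int z0 = std::max((int)std::ceil(loz / sz), 0);
    int z1 = std::min((int)std::floor(hiz / sz), nz - 1);
    int y0 = std::max((int)std::ceil(loy / sy), 0);
    int y1 = std::min((int)std::floor(hiy / sy), ny - 1);
    int x0 = std::max((int)std::ceil(lox / sx), 0);
    int x1 = std::min((int)std::floor(hix / sx), nx - 1);
    double vz = bz - az, vy = by - ay, vx = bx - ax;
    double vv = vz * vz + vy * vy + vx * vx;
    for (int x = x0; x <= x1; ++x) for (int y = y0; y <= y1; ++y)
      for (int z = z0; z <= z1; ++z) {
        double wz = z * sz - az, wy = y * sy - ay, wx = x * sx - ax;
        double t = vv > 0 ? (wz * vz + wy * vy + wx * vx) / vv : 0.0;
        if (t < 0) t = 0; if (t > 1) t = 1;
        double dz = wz - t * vz, dy = wy - t * vy, dx = wx - t * vx;
        double r = ra + (rb - ra) * t;
        if (dz * dz + dy * dy + dx * dx <= r * r)
          mask[z + (long long)nz * (y + (long long)ny * x)] = true;
      }
  }
  return mask;
}

// 3x3x3 median filter with mirrored boundary.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector arr, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out((size_t)nz * ny * nx);
  double w[27];
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      int k = 0;
      for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int z2 = std::abs(z + dz); if (z2 >= nz) z2 = 2 * nz - 2 - z2;
          int y2 = std::abs(y + dy); if (y2 >= ny) y2 = 2 * ny - 2 - y2;
          int x2 = std::abs(x + dx); if (x2 >= nx) x2 = 2 * nx - 2 - x2;
          w[k++] = arr[z2 + (long long)nz * (y2 + (long long)ny * x2)];
        }
      std::nth_element(w, w + 13, w + 27);
      out[z + (long long)nz * (y + (long long)ny * x)] = w[13];
    }
  return out;
}
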
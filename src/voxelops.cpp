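// Low-level voxel grid operations: 3D medial-axis thinning, Euclidean
// distance transform, connected-component labeling, hole filling, cylinder
// voxelization and nearest-segment territory labeling.
//
// Grid convention throughout: column-major R array indexing, voxel (i,j,k)
// (0-based here) has world center origin + c(i,j,k) * spacing.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

inline int lin(int x, int y, int z, const int* d) {
  return x + d[0] * (y + d[1] * z);
}

// 3x3x3 neighborhood occupancy, index k = (dx+1) + 3*(dy+1) + 9*(dz+1).
// Out-of-bounds voxels are background. Center is k = 13.
void neighborhood27(const std::vector<uint8_t>& img, const int* d,
                    int x, int y, int z, uint8_t nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[k] = (xx >= 0 && yy >= 0 && zz >= 0 &&
                 xx < d[0] && yy < d[1] && zz < d[2])
                  ? img[lin(xx, yy, zz, d)] : 0;
      }
}

inline void coords_of(int k, int& dx, int& dy, int& dz) {
  dx = k % 3 - 1;
  dy = (k / 3) % 3 - 1;
  dz = k / 9 - 1;
}

int count_fg_neighbors(const uint8_t nb[27]) {
  int n = 0;
  for (int k = 0; k < 27; ++k)
    if (k != 13 && nb[k]) ++n;
  return n;
}

// Number of 26-connected components of foreground within the 26-neighborhood
// (center excluded).
int t26(const uint8_t nb[27]) {
  uint8_t seen[27] = {0};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    int top = 0;
    stack[top++] = s;
    seen[s] = 1;
    while (top > 0) {
      int cur = stack[--top];
      int cx, cy, cz;
      coords_of(cur, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || !nb[t] || seen[t]) continue;
        int tx, ty, tz;
        coords_of(t, tx, ty, tz);
        if (std::abs(tx - cx) <= 1 && std::abs(ty - cy) <= 1 &&
            std::abs(tz - cz) <= 1) {
          seen[t] = 1;
          stack[top++] = t;
        }
      }
    }
  }
  return comps;
}

// Number of 6-connected components of *background* within the
// 18-neighborhood that are 6-adjacent to the center.
int t6(const uint8_t nb[27]) {
  uint8_t in18[27] = {0}, seen[27] = {0};
  for (int k = 0; k < 27; ++k) {
    if (k == 13) continue;
    int dx, dy, dz;
    coords_of(k, dx, dy, dz);
    int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
    if (a == 1 || a == 2) in18[k] = 1;  // faces and edges, no corners
  }
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    int sx, sy, sz;
    coords_of(s, sx, sy, sz);
    if (std::abs(sx) + std::abs(sy) + std::abs(sz) != 1) continue;  // seed at face neighbors only
    ++comps;
    int top = 0;
    stack[top++] = s;
    seen[s] = 1;
    while (top > 0) {
      int cur = stack[--top];
      int cx, cy, cz;
      coords_of(cur, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (!in18[t] || nb[t] || seen[t]) continue;
        int tx, ty, tz;
        coords_of(t, tx, ty, tz);
        if (std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz) == 1) {
          seen[t] = 1;
          stack[top++] = t;
        }
      }
    }
  }
  return comps;
}

// Simple point for (26, 6) connectivity (Bertrand & Malandain): deleting the
// point changes neither object nor background topology.
bool is_simple(const uint8_t nb[27]) {
  return t26(nb) == 1 && t6(nb) == 1;
}

}  // namespace

// Six-subiteration border thinning. Per subiteration, candidates are the
// simple, non-endpoint voxels whose face neighbor in one direction is
// background, all judged on the subiteration-start state; they are then
// deleted sequentially, re-checking simplicity only. Freezing the border
// and endpoint conditions at collection time is essential: a freshly
// exposed centerline is not a candidate until the next subiteration (no
// unzipping along the scan order), and a voxel isolated mid-phase is not
// retroactively protected (no hairs growing toward the surface).
// [[Rcpp::export]]
LogicalVector thin_skeleton_cpp(LogicalVector vol, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  std::vector<uint8_t> img(n);
  for (int i = 0; i < n; ++i) img[i] = vol[i] ? 1 : 0;

  const int dir[6][3] = {{0, 0, -1}, {0, 0, 1}, {0, -1, 0},
                         {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};

  uint8_t nb[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 6; ++sub) {
      cand.clear();
      const int ox = dir[sub][0], oy = dir[sub][1], oz = dir[sub][2];
      for (int z = 0; z < d[2]; ++z)
        for (int y = 0; y < d[1]; ++y)
          for (int x = 0; x < d[0]; ++x) {
            int id = lin(x, y, z, d);
            if (!img[id]) continue;
            int xx = x + ox, yy = y + oy, zz = z + oz;
            bool border = !(xx >= 0 && yy >= 0 && zz >= 0 &&
                            xx < d[0] && yy < d[1] && zz < d[2]) ||
                          !img[lin(xx, yy, zz, d)];
            if (!border) continue;
            neighborhood27(img, d, x, y, z, nb);
            if (count_fg_neighbors(nb) <= 1) continue;  // endpoint: keep
            if (is_simple(nb)) cand.push_back(id);
          }
      for (size_t c = 0; c < cand.size(); ++c) {
        int id = cand[c];
        int x = id % d[0], y = (id / d[0]) % d[1], z = id / (d[0] * d[1]);
        neighborhood27(img, d, x, y, z, nb);
        if (count_fg_neighbors(nb) == 0) continue;  // isolated point stays
        if (is_simple(nb)) {
          img[id] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dims;
  return out;
}

namespace {

// 1D squared distance transform (Felzenszwalb & Huttenlocher).
void dt1d(const double* f, double* dout, int n,
          std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    dout[q] = dq * dq + f[v[k]];
  }
}

// Full 3D squared EDT from a 0 / +inf initialization, in place.
void edt_sq_raw(const std::vector<double>& init, const int* d,
                std::vector<double>& g) {
  if (&g != &init) g = init;
  int nmax = std::max(d[0], std::max(d[1], d[2]));
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1), f(nmax), dcol(nmax);

  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y) {
      for (int x = 0; x < d[0]; ++x) f[x] = g[lin(x, y, z, d)];
      dt1d(f.data(), dcol.data(), d[0], v, zb);
      for (int x = 0; x < d[0]; ++x) g[lin(x, y, z, d)] = dcol[x];
    }
  for (int z = 0; z < d[2]; ++z)
    for (int x = 0; x < d[0]; ++x) {
      for (int y = 0; y < d[1]; ++y) f[y] = g[lin(x, y, z, d)];
      dt1d(f.data(), dcol.data(), d[1], v, zb);
      for (int y = 0; y < d[1]; ++y) g[lin(x, y, z, d)] = dcol[y];
    }
  for (int y = 0; y < d[1]; ++y)
    for (int x = 0; x < d[0]; ++x) {
      for (int z = 0; z < d[2]; ++z) f[z] = g[lin(x, y, z, d)];
      dt1d(f.data(), dcol.data(), d[2], v, zb);
      for (int z = 0; z < d[2]; ++z) g[lin(x, y, z, d)] = dcol[z];
    }
}

}  // namespace

// Squared Euclidean distance (in voxel units) from each voxel to the nearest
// background voxel center. Background voxels get 0.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? 1e18 : 0.0;
  edt_sq_raw(g, d, g);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}

// Separable 3x3x3 box-mean filter (edge-replicated).
// [[Rcpp::export]]
NumericVector box_smooth_cpp(NumericVector vol, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int stride[3] = {1, d[0], d[0] * d[1]};
  for (int axis = 0; axis < 3; ++axis) {
    int st = stride[axis], len = d[axis];
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          int idx[3] = {x, y, z};
          int i = x + d[0] * (y + d[1] * z);
          int lo = idx[axis] > 0 ? i - st : i;
          int hi = idx[axis] < len - 1 ? i + st : i;
          b[i] = (a[lo] + a[i] + a[hi]) / 3.0;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Morphological closing with a 3x3x3 box: separable max then min filter.
// [[Rcpp::export]]
LogicalVector box_closing_cpp(LogicalVector mask, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  std::vector<uint8_t> a(n), b(n);
  for (int i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  const int stride[3] = {1, d[0], d[0] * d[1]};
  auto pass = [&](bool dilate) {
    for (int axis = 0; axis < 3; ++axis) {
      int st = stride[axis], len = d[axis];
      for (int z = 0; z < d[2]; ++z)
        for (int y = 0; y < d[1]; ++y)
          for (int x = 0; x < d[0]; ++x) {
            int idx[3] = {x, y, z};
            int i = x + d[0] * (y + d[1] * z);
            uint8_t lo = idx[axis] > 0 ? a[i - st] : (dilate ? 0 : 1);
            uint8_t hi = idx[axis] < len - 1 ? a[i + st] : (dilate ? 0 : 1);
            b[i] = dilate ? std::max(a[i], std::max(lo, hi))
                          : std::min(a[i], std::min(lo, hi));
          }
      std::swap(a, b);
    }
  };
  pass(true);   // dilation
  pass(false);  // erosion
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = a[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// Connected-component labels (1..k) in scan order; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && a != 1) continue;
        offs.push_back({{dx, dy, dz}});
      }

  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int x = cur % d[0], y = (cur / d[0]) % d[1], z = cur / (d[0] * d[1]);
      for (size_t o = 0; o < offs.size(); ++o) {
        int xx = x + offs[o][0], yy = y + offs[o][1], zz = z + offs[o][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
          continue;
        int j = lin(xx, yy, zz, d);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Fill interior cavities: background 6-components not touching the array
// border become foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  LogicalVector inv(n);
  for (int i = 0; i < n; ++i) inv[i] = !mask[i];
  IntegerVector lab = label_components_cpp(inv, dims, 6);

  std::vector<uint8_t> touches(1, 0);
  auto mark = [&](int x, int y, int z) {
    int l = lab[lin(x, y, z, d)];
    if (l > 0) {
      if ((int)touches.size() <= l) touches.resize(l + 1, 0);
      touches[l] = 1;
    }
  };
  for (int y = 0; y < d[1]; ++y)
    for (int x = 0; x < d[0]; ++x) { mark(x, y, 0); mark(x, y, d[2] - 1); }
  for (int z = 0; z < d[2]; ++z)
    for (int x = 0; x < d[0]; ++x) { mark(x, 0, z); mark(x, d[1] - 1, z); }
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y) { mark(0, y, z); mark(d[0] - 1, y, z); }

  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    int l = lab[i];
    out[i] = mask[i] || (l > 0 && ((int)touches.size() <= l || !touches[l]));
  }
  out.attr("dim") = dims;
  return out;
}

namespace {

inline double seg_dist2(double px, double py, double pz,
                        double x0, double y0, double z0,
                        double x1, double y1, double z1) {
  double vx = x1 - x0, vy = y1 - y0, vz = z1 - z0;
  double wx = px - x0, wy = py - y0, wz = pz - z0;
  double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

}  // namespace

// Occupancy of a set of cylinders. seg columns: x0 y0 z0 x1 y1 z1 r (mm).
// [[Rcpp::export]]
LogicalVector voxelize_cylinders_cpp(NumericMatrix seg, IntegerVector dims,
                                     NumericVector origin, double spacing) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  LogicalVector out(n);
  for (int s = 0; s < seg.nrow(); ++s) {
    double x0 = seg(s, 0), y0 = seg(s, 1), z0 = seg(s, 2);
    double x1 = seg(s, 3), y1 = seg(s, 4), z1 = seg(s, 5), r = seg(s, 6);
    double r2 = r * r;
    double lo[3] = {std::min(x0, x1) - r, std::min(y0, y1) - r,
                    std::min(z0, z1) - r};
    double hi[3] = {std::max(x0, x1) + r, std::max(y0, y1) + r,
                    std::max(z0, z1) + r};
    int ilo[3], ihi[3];
    for (int a = 0; a < 3; ++a) {
      ilo[a] = std::max(0, (int)std::floor((lo[a] - origin[a]) / spacing));
      ihi[a] = std::min(d[a] - 1, (int)std::ceil((hi[a] - origin[a]) / spacing));
    }
    for (int z = ilo[2]; z <= ihi[2]; ++z) {
      double pz = origin[2] + z * spacing;
      for (int y = ilo[1]; y <= ihi[1]; ++y) {
        double py = origin[1] + y * spacing;
        for (int x = ilo[0]; x <= ihi[0]; ++x) {
          int id = lin(x, y, z, d);
          if (out[id]) continue;
          double px = origin[0] + x * spacing;
          if (seg_dist2(px, py, pz, x0, y0, z0, x1, y1, z1) <= r2 + 1e-12)
            out[id] = true;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// For each true voxel of `mask`, the (1-based) index into `seglab` of the
// nearest segment; ties within 1e-9 mm^2 resolved toward the smallest label
// value (labels must be supplied in the desired priority order).
// seg columns: x0 y0 z0 x1 y1 z1. seglab: integer label per segment.
// [[Rcpp::export]]
IntegerVector nearest_segment_cpp(LogicalVector mask, IntegerVector dims,
                                  NumericVector origin, double spacing,
                                  NumericMatrix seg, IntegerVector seglab) {
  int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  const int ns = seg.nrow();
  IntegerVector out(n, 0);
  for (int z = 0; z < d[2]; ++z) {
    double pz = origin[2] + z * spacing;
    for (int y = 0; y < d[1]; ++y) {
      double py = origin[1] + y * spacing;
      for (int x = 0; x < d[0]; ++x) {
        int id = lin(x, y, z, d);
        if (!mask[id]) continue;
        double px = origin[0] + x * spacing;
        double best = std::numeric_limits<double>::infinity();
        int bestlab = 0;
        for (int s = 0; s < ns; ++s) {
          double d2 = seg_dist2(px, py, pz, seg(s, 0), seg(s, 1), seg(s, 2),
                                seg(s, 3), seg(s, 4), seg(s, 5));
          if (d2 < best - 1e-9) {
            best = d2;
            bestlab = seglab[s];
          } else if (d2 <= best + 1e-9 && seglab[s] < bestlab) {
            best = std::min(best, d2);
            bestlab = seglab[s];
          }
        }
        out[id] = bestlab;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
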
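// Binary-volume utilities: 26-connected component labeling, ball
// dilation/erosion, topology-preserving 3D thinning (Malandain-Bertrand
// simple-point test, six directional sub-iterations, sequential raster-order
// deletion), intensity-gated region growing, affine/trilinear resampling,
// ellipsoid rasterization and point-set distances.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline long vidx(int x, int y, int z, int X, int Y) {
  return x + (long)X * (y + (long)Y * z);
}

// ---- simple point test --------------------------------------------------
// nb: 27 booleans for the 3x3x3 neighborhood, index (dx+1)+3*(dy+1)+9*(dz+1).
// A foreground voxel is simple iff (a) its foreground 26-neighbors form
// exactly one 26-connected component and (b) the background voxels of its
// 18-neighborhood form exactly one 6-connected component that is 6-adjacent
// to the center.
static bool is_simple(const bool nb[27]) {
  static const int cx[27] = {-1, 0, 1, -1, 0, 1, -1, 0, 1, -1, 0, 1, -1, 0,
                             1,  -1, 0, 1, -1, 0, 1, -1, 0, 1, -1, 0, 1};
  // coordinates of position p: dx = p%3-1, dy = (p/3)%3-1, dz = p/9-1
  int fg[26], nfg = 0;
  for (int p = 0; p < 27; ++p)
    if (p != 13 && nb[p]) fg[nfg++] = p;
  if (nfg == 0) return false;
  // (a) one 26-connected foreground component among the 26 neighbors
  bool seen[27] = {false};
  std::vector<int> stack;
  stack.push_back(fg[0]);
  seen[fg[0]] = true;
  int reached = 0;
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    ++reached;
    int px = p % 3, py = (p / 3) % 3, pz = p / 9;
    for (int q = 0; q < 27; ++q) {
      if (q == 13 || seen[q] || !nb[q]) continue;
      int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
      if (std::abs(px - qx) <= 1 && std::abs(py - qy) <= 1 &&
          std::abs(pz - qz) <= 1) {
        seen[q] = true;
        stack.push_back(q);
      }
    }
  }
  if (reached != nfg) return false;
  // (b) one 6-connected background component in N18 touching a face neighbor
  bool in18[27];
  for (int p = 0; p < 27; ++p) {
    int px = p % 3 - 1, py = (p / 3) % 3 - 1, pz = p / 9 - 1;
    int man = std::abs(px) + std::abs(py) + std::abs(pz);
    in18[p] = (man == 1 || man == 2);
  }
  bool bseen[27] = {false};
  int ncomp_touch = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || bseen[s]) continue;
    int sx = s % 3 - 1, sy = (s / 3) % 3 - 1, sz = s / 9 - 1;
    if (std::abs(sx) + std::abs(sy) + std::abs(sz) != 1) continue;  // seed at faces
    // BFS over 6-adjacency within N18 background
    std::vector<int> st;
    st.push_back(s);
    bseen[s] = true;
    bool touches = false;
    while (!st.empty()) {
      int p = st.back();
      st.pop_back();
      int px = p % 3 - 1, py = (p / 3) % 3 - 1, pz = p / 9 - 1;
      if (std::abs(px) + std::abs(py) + std::abs(pz) == 1) touches = true;
      static const int d6[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                                   {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
      for (int d = 0; d < 6; ++d) {
        int qx = px + d6[d][0], qy = py + d6[d][1], qz = pz + d6[d][2];
        if (qx < -1 || qx > 1 || qy < -1 || qy > 1 || qz < -1 || qz > 1)
          continue;
        int q = (qx + 1) + 3 * (qy + 1) + 9 * (qz + 1);
        if (!in18[q] || nb[q] || bseen[q]) continue;
        bseen[q] = true;
        st.push_back(q);
      }
    }
    if (touches) ++ncomp_touch;
    if (ncomp_touch > 1) return false;
  }
  return ncomp_touch == 1;
  (void)cx;
}

static inline void fill_nb(const int* m, int x, int y, int z, int X, int Y,
                           int Z, bool nb[27]) {
  int p = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++p) {
        int sx = x + dx, sy = y + dy, sz = z + dz;
        nb[p] = (sx >= 0 && sx < X && sy >= 0 && sy < Y && sz >= 0 &&
                 sz < Z && m[vidx(sx, sy, sz, X, Y)] != 0);
      }
}

static inline int count_fg26(const bool nb[27]) {
  int c = 0;
  for (int p = 0; p < 27; ++p)
    if (p != 13 && nb[p]) ++c;
  return c;
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  std::vector<int> m(mask.begin(), mask.end());
  static const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1},  {0, -1, 0},
                                 {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  bool changed = true;
  bool nb[27];
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<long> cand;
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          for (int x = 0; x < X; ++x) {
            long i = vidx(x, y, z, X, Y);
            if (!m[i]) continue;
            int sx = x + dirs[d][0], sy = y + dirs[d][1], sz = z + dirs[d][2];
            bool border = !(sx >= 0 && sx < X && sy >= 0 && sy < Y &&
                            sz >= 0 && sz < Z &&
                            m[vidx(sx, sy, sz, X, Y)]);
            if (border) cand.push_back(i);
          }
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        long i = cand[ci];
        if (!m[i]) continue;
        int x = (int)(i % X), y = (int)((i / X) % Y), z = (int)(i / ((long)X * Y));
        fill_nb(m.data(), x, y, z, X, Y, Z, nb);
        if (count_fg26(nb) <= 1) continue;  // keep curve endpoints/isolated
        if (is_simple(nb)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(mask.size());
  for (long i = 0; i < (long)m.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
IntegerVector label26_cpp(LogicalVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long n = (long)X * Y * Z;
  IntegerVector lab(n);
  int cur = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      long i = stack.back();
      stack.pop_back();
      int x = (int)(i % X), y = (int)((i / X) % Y), z = (int)(i / ((long)X * Y));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int sx = x + dx, sy = y + dy, sz = z + dz;
            if (sx < 0 || sx >= X || sy < 0 || sy >= Y || sz < 0 || sz >= Z)
              continue;
            long j = vidx(sx, sy, sz, X, Y);
            if (mask[j] && !lab[j]) {
              lab[j] = cur;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = cur;
  return lab;
}

static std::vector<std::array<int, 3>> ball_offsets(double r) {
  std::vector<std::array<int, 3>> off;
  int R = (int)std::floor(r);
  for (int dz = -R; dz <= R; ++dz)
    for (int dy = -R; dy <= R; ++dy)
      for (int dx = -R; dx <= R; ++dx)
        if ((double)dx * dx + dy * dy + dz * dz <= r * r + 1e-9)
          off.push_back({dx, dy, dz});
  return off;
}

// [[Rcpp::export]]
LogicalVector dilate_ball_cpp(LogicalVector mask, IntegerVector dims,
                              double radius) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  auto off = ball_offsets(radius);
  LogicalVector out((long)X * Y * Z);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        long i = vidx(x, y, z, X, Y);
        if (!mask[i]) continue;
        for (auto& o : off) {
          int sx = x + o[0], sy = y + o[1], sz = z + o[2];
          if (sx >= 0 && sx < X && sy >= 0 && sy < Y && sz >= 0 && sz < Z)
            out[vidx(sx, sy, sz, X, Y)] = true;
        }
      }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
LogicalVector erode_ball_cpp(LogicalVector mask, IntegerVector dims,
                             double radius, bool border_fg) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  auto off = ball_offsets(radius);
  LogicalVector out((long)X * Y * Z);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        long i = vidx(x, y, z, X, Y);
        if (!mask[i]) continue;
        bool keep = true;
        for (auto& o : off) {
          int sx = x + o[0], sy = y + o[1], sz = z + o[2];
          if (sx < 0 || sx >= X || sy < 0 || sy >= Y || sz < 0 || sz >= Z) {
            if (!border_fg) { keep = false; break; }
          } else if (!mask[vidx(sx, sy, sz, X, Y)]) {
            keep = false;
            break;
          }
        }
        if (keep) out[i] = true;
      }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
LogicalVector region_grow_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector img, double threshold) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long n = (long)X * Y * Z;
  LogicalVector out(n);
  std::vector<long> stack;
  for (long i = 0; i < n; ++i)
    if (mask[i]) {
      out[i] = true;
      stack.push_back(i);
    }
  while (!stack.empty()) {
    long i = stack.back();
    stack.pop_back();
    int x = (int)(i % X), y = (int)((i / X) % Y), z = (int)(i / ((long)X * Y));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int sx = x + dx, sy = y + dy, sz = z + dz;
          if (sx < 0 || sx >= X || sy < 0 || sy >= Y || sz < 0 || sz >= Z)
            continue;
          long j = vidx(sx, sy, sz, X, Y);
          if (!out[j] && img[j] >= threshold) {
            out[j] = true;
            stack.push_back(j);
          }
        }
  }
  out.attr("dim") = dims;
  return out;
}

// Map output voxel (0-based) p_out through p_in = A %*% p_out + t and sample.
// [[Rcpp::export]]
NumericVector affine_sample_cpp(NumericVector vol, IntegerVector in_dims,
                                IntegerVector out_dims, NumericMatrix A,
                                NumericVector t, bool nearest, double oob,
                                bool clamp) {
  const int X = in_dims[0], Y = in_dims[1], Z = in_dims[2];
  const int OX = out_dims[0], OY = out_dims[1], OZ = out_dims[2];
  NumericVector out((long)OX * OY * OZ);
  const double* v = REAL(vol);
  long o = 0;
  for (int z = 0; z < OZ; ++z)
    for (int y = 0; y < OY; ++y)
      for (int x = 0; x < OX; ++x, ++o) {
        double px = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + t[0];
        double py = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + t[1];
        double pz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + t[2];
        if (clamp) {
          px = std::min((double)X - 1, std::max(0.0, px));
          py = std::min((double)Y - 1, std::max(0.0, py));
          pz = std::min((double)Z - 1, std::max(0.0, pz));
        }
        if (nearest) {
          int ix = (int)std::lround(px), iy = (int)std::lround(py),
              iz = (int)std::lround(pz);
          out[o] = (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 &&
                    iz < Z)
                       ? v[vidx(ix, iy, iz, X, Y)]
                       : oob;
        } else {
          if (px < 0 || py < 0 || pz < 0 || px > X - 1 || py > Y - 1 ||
              pz > Z - 1) {
            out[o] = oob;
            continue;
          }
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
              z1 = std::min(z0 + 1, Z - 1);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          double c00 = v[vidx(x0, y0, z0, X, Y)] * (1 - fx) +
                       v[vidx(x1, y0, z0, X, Y)] * fx;
          double c10 = v[vidx(x0, y1, z0, X, Y)] * (1 - fx) +
                       v[vidx(x1, y1, z0, X, Y)] * fx;
          double c01 = v[vidx(x0, y0, z1, X, Y)] * (1 - fx) +
                       v[vidx(x1, y0, z1, X, Y)] * fx;
          double c11 = v[vidx(x0, y1, z1, X, Y)] * (1 - fx) +
                       v[vidx(x1, y1, z1, X, Y)] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          out[o] = c0 * (1 - fz) + c1 * fz;
        }
      }
  out.attr("dim") = out_dims;
  return out;
}

// Rasterize axis-aligned ellipsoids (centers in 0-based continuous voxel
// coordinates, per-axis radii in voxel units) into a logical volume.
// [[Rcpp::export]]
LogicalVector stamp_ellipsoids_cpp(IntegerVector dims, NumericMatrix centers,
                                   NumericMatrix radii) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  LogicalVector out((long)X * Y * Z);
  for (int i = 0; i < centers.nrow(); ++i) {
    double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    double rx = radii(i, 0), ry = radii(i, 1), rz = radii(i, 2);
    int x0 = std::max(0, (int)std::floor(cx - rx)),
        x1 = std::min(X - 1, (int)std::ceil(cx + rx));
    int y0 = std::max(0, (int)std::floor(cy - ry)),
        y1 = std::min(Y - 1, (int)std::ceil(cy + ry));
    int z0 = std::max(0, (int)std::floor(cz - rz)),
        z1 = std::min(Z - 1, (int)std::ceil(cz + rz));
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double dx = (x - cx) / rx, dy = (y - cy) / ry, dz = (z - cz) / rz;
          if (dx * dx + dy * dy + dz * dz <= 1.0)
            out[vidx(x, y, z, X, Y)] = true;
        }
  }
  out.attr("dim") = dims;
  return out;
}

// Minimum physical distance (mm) from each query voxel to a reference voxel
// set; coordinates are 0-based voxel indices.
// [[Rcpp::export]]
NumericVector min_dist_mm_cpp(NumericMatrix query, NumericMatrix ref,
                              NumericVector spacing) {
  NumericVector out(query.nrow());
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int i = 0; i < query.nrow(); ++i) {
    double best = R_PosInf;
    for (int j = 0; j < ref.nrow(); ++j) {
      double dx = (query(i, 0) - ref(j, 0)) * sx;
      double dy = (query(i, 1) - ref(j, 1)) * sy;
      double dz = (query(i, 2) - ref(j, 2)) * sz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Separable Gaussian blur with replicated edges; sigma in voxels.
// [[Rcpp::export]]
NumericVector blur3d_cpp(NumericVector vol, IntegerVector dims, double sigma) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const long n = (long)X * Y * Z;
  if (sigma <= 0) return clone(vol);
  int h = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * h + 1);
  double s = 0;
  for (int i = -h; i <= h; ++i) {
    k[i + h] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + h];
  }
  for (auto& v : k) v /= s;
  std::vector<double> a(REAL(vol), REAL(vol) + n), b(n);
  const int dimv[3] = {X, Y, Z};
  for (int ax = 0; ax < 3; ++ax) {
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int x = 0; x < X; ++x) {
          double acc = 0;
          int pos[3] = {x, y, z};
          for (int i = -h; i <= h; ++i) {
            int p[3] = {x, y, z};
            p[ax] = std::min(dimv[ax] - 1, std::max(0, pos[ax] + i));
            acc += k[i + h] * a[vidx(p[0], p[1], p[2], X, Y)];
          }
          b[vidx(x, y, z, X, Y)] = acc;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
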
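// Voxel-level primitives for 3D segmentation and meshing.
// All arrays use R's column-major layout with dim = (nz, ny, nx);
// linear index = z + nz * (y + ny * x), zero-based here.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes, anisotropic sampling supported.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d, double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  const double BIG = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = out[idx3(z, y, x, nz, ny)];
      dt1d(f, d, sz);
      for (int z = 0; z < nz; ++z) out[idx3(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = out[idx3(z, y, x, nz, ny)];
      dt1d(f, d, sy);
      for (int y = 0; y < ny; ++y) out[idx3(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = out[idx3(z, y, x, nz, ny)];
      dt1d(f, d, sx);
      for (int x = 0; x < nx; ++x) out[idx3(z, y, x, nz, ny)] = d[x];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Seeded watershed by priority flooding: regions grow from seeds into the
// foreground mask in order of decreasing height (the distance map).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector height, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  for (R_xlen_t i = 0; i < n; ++i) lab[i] = seeds[i];

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE> pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0) pq.push(QE(height[i], i));

  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};

  while (!pq.empty()) {
    R_xlen_t i = pq.top().second;
    pq.pop();
    int z = (int)(i % nz);
    int y = (int)((i / nz) % ny);
    int x = (int)(i / ((R_xlen_t)nz * ny));
    int li = lab[i];
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t j = idx3(zz, yy, xx, nz, ny);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = li;
      pq.push(QE(height[j], j));
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Connected components, 6-connectivity.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int z = (int)(i % nz);
      int y = (int)((i / nz) % ny);
      int x = (int)(i / ((R_xlen_t)nz * ny));
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = idx3(zz, yy, xx, nz, ny);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Local maxima of a height map within a box window, greedily thinned so
// accepted peaks are at least min_sep (in the same units as spacing) apart.
// Returns 1-based linear indices, strongest first.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_peaks3d(NumericVector height, IntegerVector dim,
                          NumericVector spacing, IntegerVector radius_vox,
                          double min_height, double min_sep) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int rz = radius_vox[0], ry = radius_vox[1], rx = radius_vox[2];
  std::vector<std::pair<double, R_xlen_t> > cand;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        double h = height[i];
        if (h < min_height) continue;
        bool is_max = true;
        for (int xx = std::max(0, x - rx); is_max && xx <= std::min(nx - 1, x + rx); ++xx)
          for (int yy = std::max(0, y - ry); is_max && yy <= std::min(ny - 1, y + ry); ++yy)
            for (int zz = std::max(0, z - rz); zz <= std::min(nz - 1, z + rz); ++zz) {
              R_xlen_t j = idx3(zz, yy, xx, nz, ny);
              if (height[j] > h || (height[j] == h && j < i)) { is_max = false; break; }
            }
        if (is_max) cand.push_back(std::make_pair(h, i));
      }
  std::sort(cand.begin(), cand.end(),
            [](const std::pair<double, R_xlen_t> &a, const std::pair<double, R_xlen_t> &b) {
              return a.first > b.first;
            });
  std::vector<R_xlen_t> kept;
  std::vector<double> kz, ky, kx;
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  for (size_t c = 0; c < cand.size(); ++c) {
    R_xlen_t i = cand[c].second;
    double z = (double)(i % nz) * sz;
    double y = (double)((i / nz) % ny) * sy;
    double x = (double)(i / ((R_xlen_t)nz * ny)) * sx;
    bool ok = true;
    for (size_t k = 0; k < kept.size(); ++k) {
      double d2 = (z - kz[k]) * (z - kz[k]) + (y - ky[k]) * (y - ky[k]) +
                  (x - kx[k]) * (x - kx[k]);
      if (d2 < min_sep * min_sep) { ok = false; break; }
    }
    if (ok) {
      kept.push_back(i);
      kz.push_back(z); ky.push_back(y); kx.push_back(x);
    }
  }
  IntegerVector out(kept.size());
  for (size_t k = 0; k < kept.size(); ++k) out[k] = (int)(kept[k] + 1);
  return out;
}

// ---------------------------------------------------------------------------
// Binary morphology on the 6-neighbourhood plus a 26-neighbourhood majority
// filter (one step of discrete mean-curvature motion for binary sets).
// ---------------------------------------------------------------------------

// accumulate the 6-neighbour OR (dilate) / AND-with-complement (erode) by
// six shifted passes over contiguous memory; outside the stack counts as
// background
static void morph6(const std::vector<uint8_t> &in, std::vector<uint8_t> &out,
                   int nz, int ny, int nx, bool dilate) {
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const R_xlen_t sz = 1, sy = nz, sx = (R_xlen_t)nz * ny;
  std::copy(in.begin(), in.end(), out.begin());
  auto pass = [&](R_xlen_t stride, R_xlen_t axis_len) {
    const R_xlen_t block = stride * axis_len;
    for (R_xlen_t b = 0; b < n; b += block)
      for (R_xlen_t pos = 0; pos < axis_len; ++pos) {
        const R_xlen_t row = b + pos * stride;
        const bool has_lo = pos > 0, has_hi = pos + 1 < axis_len;
        for (R_xlen_t k = 0; k < stride; ++k) {
          const R_xlen_t i = row + k;
          uint8_t lo = has_lo ? in[i - stride] : 0;
          uint8_t hi = has_hi ? in[i + stride] : 0;
          if (dilate) {
            if (lo | hi) out[i] = 1;
          } else if (!has_lo || !has_hi || !lo || !hi) {
            out[i] = 0;
          }
        }
      }
  };
  pass(sz, nz);
  pass(sy, ny);
  pass(sx, nx);
}

// 26-neighbourhood majority vote via a separable 3x3x3 box sum with
// zero padding (outside the stack counts as background, denominator 27)
static void majority26(const std::vector<uint8_t> &in, std::vector<uint8_t> &out,
                       int nz, int ny, int nx) {
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  static thread_local std::vector<int16_t> t1, t2;
  t1.assign(n, 0);
  t2.assign(n, 0);
  const R_xlen_t sz = 1, sy = nz, sx = (R_xlen_t)nz * ny;
  auto boxsum = [&](const int16_t *src, int16_t *dst, R_xlen_t stride,
                    R_xlen_t axis_len) {
    const R_xlen_t block = stride * axis_len;
    for (R_xlen_t b = 0; b < n; b += block)
      for (R_xlen_t pos = 0; pos < axis_len; ++pos) {
        const R_xlen_t row = b + pos * stride;
        const bool has_lo = pos > 0, has_hi = pos + 1 < axis_len;
        for (R_xlen_t k = 0; k < stride; ++k) {
          const R_xlen_t i = row + k;
          int16_t v = src[i];
          if (has_lo) v += src[i - stride];
          if (has_hi) v += src[i + stride];
          dst[i] = v;
        }
      }
  };
  for (R_xlen_t i = 0; i < n; ++i) t1[i] = in[i];
  boxsum(t1.data(), t2.data(), sz, nz);
  boxsum(t2.data(), t1.data(), sy, ny);
  boxsum(t1.data(), t2.data(), sx, nx);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (2 * t2[i] > 27) ? 1 : 0;
}

// [[Rcpp::export]]
LogicalVector cpp_morph3d(LogicalVector mask, IntegerVector dim,
                          std::string op, int iterations) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<uint8_t> a(n), b(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  for (int it = 0; it < iterations; ++it) {
    if (op == "dilate") morph6(a, b, nz, ny, nx, true);
    else if (op == "erode") morph6(a, b, nz, ny, nx, false);
    else if (op == "majority") majority26(a, b, nz, ny, nx);
    else stop("unknown morphology op '%s'", op.c_str());
    a.swap(b);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Morphological geodesic active contour.
// g is the edge-stopping function in [0, 1] (1 in flat regions, ~0 on edges);
// gz, gy, gx its spatial gradient. Per iteration: balloon step on the
// 6-neighbourhood where g exceeds balloon_threshold, then an edge-attraction
// update that moves the front along the gradient of g, then `smoothing`
// majority-filter passes (discrete curvature flow).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_gac(LogicalVector init, NumericVector g, NumericVector gz,
                      NumericVector gy, NumericVector gx, IntegerVector dim,
                      int iterations, double balloon, double balloon_threshold,
                      int smoothing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<uint8_t> u(n), aux(n), tmp(n);
  for (R_xlen_t i = 0; i < n; ++i) u[i] = init[i] ? 1 : 0;

  for (int it = 0; it < iterations; ++it) {
    if (balloon != 0.0) {
      morph6(u, aux, nz, ny, nx, balloon > 0.0);
      for (R_xlen_t i = 0; i < n; ++i)
        if (g[i] > balloon_threshold) u[i] = aux[i];
    }
    // attraction: du/dt = grad(g) . grad(u); forward/backward differences via
    // the central-difference of u on the current binary front
    std::copy(u.begin(), u.end(), tmp.begin());
    const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
    const double *pgz = REAL(gz), *pgy = REAL(gy), *pgx = REAL(gx);
    for (int x = 0; x < nx; ++x) {
      const bool xl = x > 0, xh = x + 1 < nx;
      for (int y = 0; y < ny; ++y) {
        const bool yl = y > 0, yh = y + 1 < ny;
        const R_xlen_t base = idx3(0, y, x, nz, ny);
        for (int z = 0; z < nz; ++z) {
          const R_xlen_t i = base + z;
          int uzp = (z + 1 < nz) ? tmp[i + 1] : 0;
          int uzm = (z > 0) ? tmp[i - 1] : 0;
          int uyp = yh ? tmp[i + sy] : 0;
          int uym = yl ? tmp[i - sy] : 0;
          int uxp = xh ? tmp[i + sx] : 0;
          int uxm = xl ? tmp[i - sx] : 0;
          double dot = pgz[i] * (uzp - uzm) + pgy[i] * (uyp - uym) +
                       pgx[i] * (uxp - uxm);
          if (dot > 0) u[i] = 1;
          else if (dot < 0) u[i] = 0;
        }
      }
    }
    for (int s = 0; s < smoothing; ++s) {
      majority26(u, aux, nz, ny, nx);
      u.swap(aux);
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = u[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface extraction by marching tetrahedra (Kuhn 6-tet decomposition of
// each cell; faces match across neighbouring cells, so the surface of any
// field that is below iso on the array border is watertight). Vertices are
// emitted in world coordinates (x, y, z) = index * spacing, triangles with
// consistent outward orientation (normals point from above-iso to below-iso).
// ---------------------------------------------------------------------------

struct VKey {
  uint64_t k;
  bool operator==(const VKey &o) const { return k == o.k; }
};
struct VKeyHash {
  size_t operator()(const VKey &v) const { return std::hash<uint64_t>()(v.k); }
};

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dim,
                        NumericVector spacing, double iso) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];

  // Kuhn decomposition: tets {0, e_p1, e_p1+e_p2, (1,1,1)} over axis
  // permutations; corner bit order (bit0 = x, bit1 = y, bit2 = z)
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  std::vector<double> vx, vy, vzc;
  std::vector<int> tri;
  std::unordered_map<VKey, int, VKeyHash> vmap;

  const uint64_t NVERT = (uint64_t)nz * (uint64_t)ny * (uint64_t)nx;

  double cpos[8][3];  // (x, y, z) of cube corners
  double cval[8];
  uint64_t cgid[8];

  auto edge_vertex = [&](int a, int b) -> int {
    uint64_t ga = cgid[a], gb = cgid[b];
    if (ga > gb) std::swap(ga, gb);
    VKey key;
    key.k = ga * NVERT + gb;
    std::unordered_map<VKey, int, VKeyHash>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = cval[a], fb = cval[b];
    double t = (iso - fa) / (fb - fa);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    double px = cpos[a][0] + t * (cpos[b][0] - cpos[a][0]);
    double py = cpos[a][1] + t * (cpos[b][1] - cpos[a][1]);
    double pz = cpos[a][2] + t * (cpos[b][2] - cpos[a][2]);
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vzc.push_back(pz);
    vmap[key] = id;
    return id;
  };

  auto emit = [&](int v0, int v1, int v2, const double refIn[3], const double refOut[3]) {
    // orient so the normal points from the inside (above iso) to the outside
    double ax = vx[v1] - vx[v0], ay = vy[v1] - vy[v0], az = vzc[v1] - vzc[v0];
    double bx = vx[v2] - vx[v0], by = vy[v2] - vy[v0], bz = vzc[v2] - vzc[v0];
    double nxv = ay * bz - az * by;
    double nyv = az * bx - ax * bz;
    double nzv = ax * by - ay * bx;
    double rx = refOut[0] - refIn[0], ry = refOut[1] - refIn[1], rz = refOut[2] - refIn[2];
    if (nxv * rx + nyv * ry + nzv * rz < 0) std::swap(v1, v2);
    tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
  };

  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          cval[c] = field[idx3(cz, cy, cx, nz, ny)];
          cpos[c][0] = cx * sx; cpos[c][1] = cy * sy; cpos[c][2] = cz * sz;
          cgid[c] = (uint64_t)cz + (uint64_t)nz * ((uint64_t)cy + (uint64_t)ny * (uint64_t)cx);
          if (cval[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cval[T[c]] > iso) in[ni++] = T[c];
            else out[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) cin[d] += cpos[in[c]][d] / ni;
          for (int c = 0; c < no; ++c)
            for (int d = 0; d < 3; ++d) cout[d] += cpos[out[c]][d] / no;
          if (ni == 1) {
            int a = edge_vertex(in[0], out[0]);
            int b = edge_vertex(in[0], out[1]);
            int c = edge_vertex(in[0], out[2]);
            emit(a, b, c, cin, cout);
          } else if (ni == 3) {
            int a = edge_vertex(out[0], in[0]);
            int b = edge_vertex(out[0], in[1]);
            int c = edge_vertex(out[0], in[2]);
            emit(a, b, c, cin, cout);
          } else {  // ni == 2: quad split into two triangles
            int a = edge_vertex(in[0], out[0]);
            int b = edge_vertex(in[0], out[1]);
            int c = edge_vertex(in[1], out[1]);
            int d = edge_vertex(in[1], out[0]);
            emit(a, b, c, cin, cout);
            emit(a, c, d, cin, cout);
          }
        }
      }

  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vzc[i];
  }
  int nt = (int)tri.size() / 3;
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i) {
    F(i, 0) = tri[3 * i] + 1; F(i, 1) = tri[3 * i + 1] + 1; F(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}
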
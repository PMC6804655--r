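// Low-level geometry kernels: Euclidean distance transform, separable
// Gaussian smoothing, marching-tetrahedra isosurface extraction,
// point/segment-to-mesh distances, segment-triangle intersection,
// surface voxelization, exterior flood fill and trilinear sampling.
// Conventions: voxel (i,j,k) (0-based) has its center at
// origin + c(i,j,k) * voxdim (mm); faces are returned 1-based for R.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher) with spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    while (true) {
      double xv = v[k] * w;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else { break; }
    }
    ++k;
    v[k] = q;
    z[k] = ((f[q] + xq * xq) -
            (f[v[k - 1]] + (v[k - 1] * w) * (v[k - 1] * w))) /
           (2 * xq - 2 * v[k - 1] * w);
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dim,
                        NumericVector voxdim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  std::vector<double> d(n);
  const double INF = 1e30;
  for (long long t = 0; t < n; ++t) d[t] = fg[t] ? 0.0 : INF;

  std::vector<double> f, g;
  // x pass
  f.resize(nx); g.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, g, nx, voxdim[0]);
      for (int i = 0; i < nx; ++i) d[idx3(i, j, k, nx, ny)] = g[i];
    }
  // y pass
  f.resize(ny); g.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, g, ny, voxdim[1]);
      for (int j = 0; j < ny; ++j) d[idx3(i, j, k, nx, ny)] = g[j];
    }
  // z pass
  f.resize(nz); g.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, g, nz, voxdim[2]);
      for (int k = 0; k < nz; ++k) d[idx3(i, j, k, nx, ny)] = g[k];
    }

  NumericVector out(n);
  for (long long t = 0; t < n; ++t) out[t] = std::sqrt(d[t]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, reflected boundary, kernel radius 3 sigma.
static void blur_axis(std::vector<double>& vol, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (double& kv : ker) kv /= s;

  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), out(len);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      for (int t = 0; t < len; ++t) {
        int i, j, k;
        if (axis == 0) { i = t; j = a; k = b; }
        else if (axis == 1) { i = a; j = t; k = b; }
        else { i = a; j = b; k = t; }
        line[t] = vol[idx3(i, j, k, nx, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int u = -r; u <= r; ++u) {
          int p = t + u;
          if (p < 0) p = -p - 1;
          if (p >= len) p = 2 * len - p - 1;
          acc += ker[u + r] * line[p];
        }
        out[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        int i, j, k;
        if (axis == 0) { i = t; j = a; k = b; }
        else if (axis == 1) { i = a; j = t; k = b; }
        else { i = a; j = b; k = t; }
        vol[idx3(i, j, k, nx, ny)] = out[t];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(v, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(v, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(n);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Kuhn (6-tet) cube decomposition.
// Inside := value > iso.  Triangles oriented with normals pointing outward
// (from inside toward outside).

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
};

static int edge_point(MTState& st, const double* val, const double* px,
                      const double* py, const double* pz,
                      long long ga, long long gb, int a, int b, double iso) {
  long long lo = ga < gb ? ga : gb, hi = ga < gb ? gb : ga;
  uint64_t key = ((uint64_t)lo << 32) ^ (uint64_t)hi;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double va = val[a], vb = val[b];
  double t = (std::fabs(vb - va) < 1e-300) ? 0.5 : (iso - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  st.vx.push_back(px[a] + t * (px[b] - px[a]));
  st.vy.push_back(py[a] + t * (py[b] - py[a]));
  st.vz.push_back(pz[a] + t * (pz[b] - pz[a]));
  int id = (int)st.vx.size();  // 1-based
  st.edge_vertex[key] = id;
  return id;
}

static void add_tri(MTState& st, int a, int b, int c,
                    double ix, double iy, double iz,
                    double ox, double oy, double oz) {
  // orient so the normal points from the inside centroid to the outside one
  double ax = st.vx[a - 1], ay = st.vy[a - 1], az = st.vz[a - 1];
  double ux = st.vx[b - 1] - ax, uy = st.vy[b - 1] - ay, uz = st.vz[b - 1] - az;
  double wx = st.vx[c - 1] - ax, wy = st.vy[c - 1] - ay, wz = st.vz[c - 1] - az;
  double nxv = uy * wz - uz * wy;
  double nyv = uz * wx - ux * wz;
  double nzv = ux * wy - uy * wx;
  double dot = nxv * (ox - ix) + nyv * (oy - iy) + nzv * (oz - iz);
  if (dot < 0) std::swap(b, c);
  st.fa.push_back(a); st.fb.push_back(b); st.fc.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector vol, IntegerVector dim, double iso,
                        NumericVector voxdim, NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  static const int off[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};

  MTState st;
  double cval[8], cx[8], cy[8], cz[8];
  long long gid[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          gid[c] = idx3(ii, jj, kk, nx, ny);
          cval[c] = vol[gid[c]];
          cx[c] = origin[0] + ii * voxdim[0];
          cy[c] = origin[1] + jj * voxdim[1];
          cz[c] = origin[2] + kk * voxdim[2];
          if (cval[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cval[vi[c]] > iso) ins[ni++] = vi[c];
            else outs[no++] = vi[c];
          }
          if (ni == 0 || ni == 4) continue;
          double ix = 0, iy = 0, iz = 0, ox = 0, oy = 0, oz = 0;
          for (int c = 0; c < ni; ++c) { ix += cx[ins[c]]; iy += cy[ins[c]]; iz += cz[ins[c]]; }
          for (int c = 0; c < no; ++c) { ox += cx[outs[c]]; oy += cy[outs[c]]; oz += cz[outs[c]]; }
          ix /= ni; iy /= ni; iz /= ni; ox /= no; oy /= no; oz /= no;

          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? ins[0] : outs[0];
            const int* oth = (ni == 1) ? outs : ins;
            int e1 = edge_point(st, cval, cx, cy, cz, gid[apex], gid[oth[0]], apex, oth[0], iso);
            int e2 = edge_point(st, cval, cx, cy, cz, gid[apex], gid[oth[1]], apex, oth[1], iso);
            int e3 = edge_point(st, cval, cx, cy, cz, gid[apex], gid[oth[2]], apex, oth[2], iso);
            add_tri(st, e1, e2, e3, ix, iy, iz, ox, oy, oz);
          } else {  // ni == 2: quad from the four crossing edges
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int eac = edge_point(st, cval, cx, cy, cz, gid[a], gid[c], a, c, iso);
            int ead = edge_point(st, cval, cx, cy, cz, gid[a], gid[d], a, d, iso);
            int ebc = edge_point(st, cval, cx, cy, cz, gid[b], gid[c], b, c, iso);
            int ebd = edge_point(st, cval, cx, cy, cz, gid[b], gid[d], b, d, iso);
            add_tri(st, eac, ead, ebd, ix, iy, iz, ox, oy, oz);
            add_tri(st, eac, ebd, ebc, ix, iy, iz, ox, oy, oz);
          }
        }
      }

  int nv = (int)st.vx.size(), nf = (int)st.fa.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v]; }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) { F(f, 0) = st.fa[f]; F(f, 1) = st.fb[f]; F(f, 2) = st.fc[f]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Closest point on triangle (Ericson, Real-Time Collision Detection).
static inline void closest_pt_tri(const double p[3], const double a[3],
                                  const double b[3], const double c[3],
                                  double out[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { out[0] = a[0]; out[1] = a[1]; out[2] = a[2]; return; }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { out[0] = b[0]; out[1] = b[1]; out[2] = b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int t = 0; t < 3; ++t) out[t] = a[t] + v * ab[t];
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { out[0] = c[0]; out[1] = c[1]; out[2] = c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int t = 0; t < 3; ++t) out[t] = a[t] + w * ac[t];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int t = 0; t < 3; ++t) out[t] = b[t] + w * (c[t] - b[t]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int t = 0; t < 3; ++t) out[t] = a[t] + ab[t] * v + ac[t] * w;
}

static inline double dist2(const double p[3], const double q[3]) {
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

struct TriSoup {
  std::vector<double> ax, ay, az, bx, by, bz, cx, cy, cz;
  std::vector<double> lo0, lo1, lo2, hi0, hi1, hi2;
  int nf;
};

static TriSoup make_soup(const NumericMatrix& V, const IntegerMatrix& F) {
  TriSoup s;
  s.nf = F.nrow();
  s.ax.resize(s.nf); s.ay.resize(s.nf); s.az.resize(s.nf);
  s.bx.resize(s.nf); s.by.resize(s.nf); s.bz.resize(s.nf);
  s.cx.resize(s.nf); s.cy.resize(s.nf); s.cz.resize(s.nf);
  s.lo0.resize(s.nf); s.lo1.resize(s.nf); s.lo2.resize(s.nf);
  s.hi0.resize(s.nf); s.hi1.resize(s.nf); s.hi2.resize(s.nf);
  for (int f = 0; f < s.nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    s.ax[f] = V(ia, 0); s.ay[f] = V(ia, 1); s.az[f] = V(ia, 2);
    s.bx[f] = V(ib, 0); s.by[f] = V(ib, 1); s.bz[f] = V(ib, 2);
    s.cx[f] = V(ic, 0); s.cy[f] = V(ic, 1); s.cz[f] = V(ic, 2);
    s.lo0[f] = std::min({s.ax[f], s.bx[f], s.cx[f]});
    s.lo1[f] = std::min({s.ay[f], s.by[f], s.cy[f]});
    s.lo2[f] = std::min({s.az[f], s.bz[f], s.cz[f]});
    s.hi0[f] = std::max({s.ax[f], s.bx[f], s.cx[f]});
    s.hi1[f] = std::max({s.ay[f], s.by[f], s.cy[f]});
    s.hi2[f] = std::max({s.az[f], s.bz[f], s.cz[f]});
  }
  return s;
}

static inline double aabb_lb2(const TriSoup& s, int f, const double p[3]) {
  double d = 0, t;
  t = (p[0] < s.lo0[f]) ? s.lo0[f] - p[0] : (p[0] > s.hi0[f] ? p[0] - s.hi0[f] : 0); d += t * t;
  t = (p[1] < s.lo1[f]) ? s.lo1[f] - p[1] : (p[1] > s.hi1[f] ? p[1] - s.hi1[f] : 0); d += t * t;
  t = (p[2] < s.lo2[f]) ? s.lo2[f] - p[2] : (p[2] > s.hi2[f] ? p[2] - s.hi2[f] : 0); d += t * t;
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix V,
                                  IntegerMatrix F) {
  TriSoup s = make_soup(V, F);
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double q[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < s.nf; ++f) {
      if (aabb_lb2(s, f, q) >= best) continue;
      double a[3] = {s.ax[f], s.ay[f], s.az[f]};
      double b[3] = {s.bx[f], s.by[f], s.bz[f]};
      double c[3] = {s.cx[f], s.cy[f], s.cz[f]};
      double cp[3];
      closest_pt_tri(q, a, b, c, cp);
      double d2 = dist2(q, cp);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

static double seg_tri_dist2(const double p[3], const double q[3],
                            const double a[3], const double b[3],
                            const double c[3]);
static inline double aabb_seg_lb2(const TriSoup& s, int f, const double p[3],
                                  const double q[3]);

// Uniform-grid spatial index over triangles for accelerated queries.
struct MeshGrid {
  double org[3], cell;
  int gd[3];
  std::vector<std::vector<int>> bins;
  std::vector<int> stamp;
  int cur_stamp = 0;
  inline int bidx(int i, int j, int k) const {
    return i + gd[0] * (j + gd[1] * k);
  }
};

static MeshGrid build_grid(const TriSoup& s) {
  MeshGrid g;
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int f = 0; f < s.nf; ++f) {
    lo[0] = std::min(lo[0], s.lo0[f]); hi[0] = std::max(hi[0], s.hi0[f]);
    lo[1] = std::min(lo[1], s.lo1[f]); hi[1] = std::max(hi[1], s.hi1[f]);
    lo[2] = std::min(lo[2], s.lo2[f]); hi[2] = std::max(hi[2], s.hi2[f]);
  }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-6});
  g.cell = std::max(ext / 64.0, 1e-6);
  for (int t = 0; t < 3; ++t) {
    g.org[t] = lo[t] - 0.5 * g.cell;
    g.gd[t] = std::max(1, (int)std::ceil((hi[t] - g.org[t]) / g.cell) + 1);
  }
  g.bins.resize((size_t)g.gd[0] * g.gd[1] * g.gd[2]);
  for (int f = 0; f < s.nf; ++f) {
    int i0 = (int)((s.lo0[f] - g.org[0]) / g.cell);
    int i1 = (int)((s.hi0[f] - g.org[0]) / g.cell);
    int j0 = (int)((s.lo1[f] - g.org[1]) / g.cell);
    int j1 = (int)((s.hi1[f] - g.org[1]) / g.cell);
    int k0 = (int)((s.lo2[f] - g.org[2]) / g.cell);
    int k1 = (int)((s.hi2[f] - g.org[2]) / g.cell);
    for (int k = std::max(0, k0); k <= std::min(g.gd[2] - 1, k1); ++k)
      for (int j = std::max(0, j0); j <= std::min(g.gd[1] - 1, j1); ++j)
        for (int i = std::max(0, i0); i <= std::min(g.gd[0] - 1, i1); ++i)
          g.bins[g.bidx(i, j, k)].push_back(f);
  }
  g.stamp.assign(s.nf, -1);
  return g;
}

static inline void test_cell_point(const TriSoup& s, MeshGrid& g, int ci,
                                   const double p[3], double& best2) {
  for (int f : g.bins[ci]) {
    if (g.stamp[f] == g.cur_stamp) continue;
    g.stamp[f] = g.cur_stamp;
    if (aabb_lb2(s, f, p) >= best2) continue;
    double a[3] = {s.ax[f], s.ay[f], s.az[f]};
    double b[3] = {s.bx[f], s.by[f], s.bz[f]};
    double c[3] = {s.cx[f], s.cy[f], s.cz[f]};
    double cp[3];
    closest_pt_tri(p, a, b, c, cp);
    double d2 = dist2(p, cp);
    if (d2 < best2) best2 = d2;
  }
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist_grid(NumericMatrix pts, NumericMatrix V,
                                       IntegerMatrix F) {
  TriSoup s = make_soup(V, F);
  MeshGrid g = build_grid(s);
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double q[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    ++g.cur_stamp;
    double best2 = std::numeric_limits<double>::infinity();
    int ci = (int)std::floor((q[0] - g.org[0]) / g.cell);
    int cj = (int)std::floor((q[1] - g.org[1]) / g.cell);
    int ck = (int)std::floor((q[2] - g.org[2]) / g.cell);
    // farthest Chebyshev ring that can still touch the grid
    int reach = 0;
    reach = std::max(reach, std::max(std::abs(ci - 0), std::abs(g.gd[0] - 1 - ci)));
    reach = std::max(reach, std::max(std::abs(cj - 0), std::abs(g.gd[1] - 1 - cj)));
    reach = std::max(reach, std::max(std::abs(ck - 0), std::abs(g.gd[2] - 1 - ck)));
    for (int ring = 0; ring <= reach; ++ring) {
      if (ring > 1) {
        double lb = (ring - 1) * g.cell;   // cells on this ring are at least this far
        if (lb * lb >= best2) break;
      }
      for (int k = ck - ring; k <= ck + ring; ++k) {
        if (k < 0 || k >= g.gd[2]) continue;
        for (int j = cj - ring; j <= cj + ring; ++j) {
          if (j < 0 || j >= g.gd[1]) continue;
          for (int i = ci - ring; i <= ci + ring; ++i) {
            if (i < 0 || i >= g.gd[0]) continue;
            if (ring > 0 && std::abs(i - ci) != ring && std::abs(j - cj) != ring &&
                std::abs(k - ck) != ring) continue;  // shell only
            test_cell_point(s, g, g.bidx(i, j, k), q, best2);
          }
        }
      }
    }
    out[p] = std::sqrt(best2);
  }
  return out;
}

// Does any triangle come within `radius` of each segment? Grid-accelerated:
// walk the segment, testing triangles binned near it.
// [[Rcpp::export]]
LogicalVector cpp_segment_mesh_within(NumericMatrix p0, NumericMatrix p1,
                                      NumericMatrix V, IntegerMatrix F,
                                      double radius) {
  TriSoup s = make_soup(V, F);
  MeshGrid g = build_grid(s);
  int ns = p0.nrow();
  LogicalVector out(ns);
  double r2 = radius * radius;
  int pad = (int)std::ceil(radius / g.cell) + 1;
  for (int q = 0; q < ns; ++q) {
    double a[3] = {p0(q, 0), p0(q, 1), p0(q, 2)};
    double b[3] = {p1(q, 0), p1(q, 1), p1(q, 2)};
    double len = std::sqrt(dist2(a, b));
    int nstep = std::max(1, (int)std::ceil(len / (0.5 * g.cell)));
    ++g.cur_stamp;
    bool hit = false;
    for (int st = 0; st <= nstep && !hit; ++st) {
      double t = (double)st / nstep;
      double p[3] = {a[0] + t * (b[0] - a[0]), a[1] + t * (b[1] - a[1]),
                     a[2] + t * (b[2] - a[2])};
      int ci = (int)std::floor((p[0] - g.org[0]) / g.cell);
      int cj = (int)std::floor((p[1] - g.org[1]) / g.cell);
      int ck = (int)std::floor((p[2] - g.org[2]) / g.cell);
      for (int k = std::max(0, ck - pad); k <= std::min(g.gd[2] - 1, ck + pad) && !hit; ++k)
        for (int j = std::max(0, cj - pad); j <= std::min(g.gd[1] - 1, cj + pad) && !hit; ++j)
          for (int i = std::max(0, ci - pad); i <= std::min(g.gd[0] - 1, ci + pad) && !hit; ++i)
            for (int f : g.bins[g.bidx(i, j, k)]) {
              if (g.stamp[f] == g.cur_stamp) continue;
              g.stamp[f] = g.cur_stamp;
              if (aabb_seg_lb2(s, f, a, b) >= r2) continue;
              double ta[3] = {s.ax[f], s.ay[f], s.az[f]};
              double tb[3] = {s.bx[f], s.by[f], s.bz[f]};
              double tc[3] = {s.cx[f], s.cy[f], s.cz[f]};
              if (seg_tri_dist2(a, b, ta, tb, tc) <= r2) { hit = true; break; }
            }
    }
    out[q] = hit;
  }
  return out;
}

// Segment-segment squared distance (clamped, standard).
static double seg_seg_dist2(const double p1[3], const double q1[3],
                            const double p2[3], const double q2[3]) {
  double d1[3] = {q1[0] - p1[0], q1[1] - p1[1], q1[2] - p1[2]};
  double d2v[3] = {q2[0] - p2[0], q2[1] - p2[1], q2[2] - p2[2]};
  double r[3] = {p1[0] - p2[0], p1[1] - p2[1], p1[2] - p2[2]};
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2v[0]*d2v[0] + d2v[1]*d2v[1] + d2v[2]*d2v[2];
  double f = d2v[0]*r[0] + d2v[1]*r[1] + d2v[2]*r[2];
  double sN, tN;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) { sN = tN = 0; }
  else if (a <= EPS) { sN = 0; tN = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) { tN = 0; sN = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = d1[0]*d2v[0] + d1[1]*d2v[1] + d1[2]*d2v[2];
      double denom = a * e - b * b;
      sN = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      tN = (b * sN + f) / e;
      if (tN < 0) { tN = 0; sN = std::min(1.0, std::max(0.0, -c / a)); }
      else if (tN > 1) { tN = 1; sN = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double c1[3], c2[3];
  for (int t = 0; t < 3; ++t) { c1[t] = p1[t] + sN * d1[t]; c2[t] = p2[t] + tN * d2v[t]; }
  return dist2(c1, c2);
}

// [[Rcpp::export]]
double cpp_seg_seg_dist(NumericVector p1, NumericVector q1,
                        NumericVector p2, NumericVector q2) {
  double a[3] = {p1[0], p1[1], p1[2]}, b[3] = {q1[0], q1[1], q1[2]};
  double c[3] = {p2[0], p2[1], p2[2]}, d[3] = {q2[0], q2[1], q2[2]};
  return std::sqrt(seg_seg_dist2(a, b, c, d));
}

// Moller-Trumbore segment-triangle intersection.
static bool seg_tri_intersect(const double p[3], const double q[3],
                              const double a[3], const double b[3],
                              const double c[3]) {
  double dir[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double h[3] = {dir[1]*e2[2] - dir[2]*e2[1], dir[2]*e2[0] - dir[0]*e2[2],
                 dir[0]*e2[1] - dir[1]*e2[0]};
  double det = e1[0]*h[0] + e1[1]*h[1] + e1[2]*h[2];
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  double s[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double u = (s[0]*h[0] + s[1]*h[1] + s[2]*h[2]) * inv;
  if (u < 0 || u > 1) return false;
  double qv[3] = {s[1]*e1[2] - s[2]*e1[1], s[2]*e1[0] - s[0]*e1[2],
                  s[0]*e1[1] - s[1]*e1[0]};
  double v = (dir[0]*qv[0] + dir[1]*qv[1] + dir[2]*qv[2]) * inv;
  if (v < 0 || u + v > 1) return false;
  double t = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
  return t >= 0 && t <= 1;
}

static double seg_tri_dist2(const double p[3], const double q[3],
                            const double a[3], const double b[3],
                            const double c[3]) {
  if (seg_tri_intersect(p, q, a, b, c)) return 0.0;
  double best = std::numeric_limits<double>::infinity();
  double cp[3];
  closest_pt_tri(p, a, b, c, cp); best = std::min(best, dist2(p, cp));
  closest_pt_tri(q, a, b, c, cp); best = std::min(best, dist2(q, cp));
  best = std::min(best, seg_seg_dist2(p, q, a, b));
  best = std::min(best, seg_seg_dist2(p, q, b, c));
  best = std::min(best, seg_seg_dist2(p, q, c, a));
  return best;
}

static inline double aabb_seg_lb2(const TriSoup& s, int f, const double p[3],
                                  const double q[3]) {
  // lower bound: distance from the segment AABB to the triangle AABB
  double slo[3] = {std::min(p[0], q[0]), std::min(p[1], q[1]), std::min(p[2], q[2])};
  double shi[3] = {std::max(p[0], q[0]), std::max(p[1], q[1]), std::max(p[2], q[2])};
  double tlo[3] = {s.lo0[f], s.lo1[f], s.lo2[f]};
  double thi[3] = {s.hi0[f], s.hi1[f], s.hi2[f]};
  double d = 0;
  for (int t = 0; t < 3; ++t) {
    double g = 0;
    if (thi[t] < slo[t]) g = slo[t] - thi[t];
    else if (tlo[t] > shi[t]) g = tlo[t] - shi[t];
    d += g * g;
  }
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_segment_mesh_dist(NumericMatrix p0, NumericMatrix p1,
                                    NumericMatrix V, IntegerMatrix F,
                                    double early_stop = -1.0) {
  // early_stop >= 0: per segment, stop as soon as distance <= early_stop
  TriSoup s = make_soup(V, F);
  int ns = p0.nrow();
  NumericVector out(ns);
  double stop2 = early_stop >= 0 ? early_stop * early_stop : -1.0;
  for (int g = 0; g < ns; ++g) {
    double p[3] = {p0(g, 0), p0(g, 1), p0(g, 2)};
    double q[3] = {p1(g, 0), p1(g, 1), p1(g, 2)};
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < s.nf; ++f) {
      if (aabb_seg_lb2(s, f, p, q) >= best) continue;
      double a[3] = {s.ax[f], s.ay[f], s.az[f]};
      double b[3] = {s.bx[f], s.by[f], s.bz[f]};
      double c[3] = {s.cx[f], s.cy[f], s.cz[f]};
      double d2 = seg_tri_dist2(p, q, a, b, c);
      if (d2 < best) best = d2;
      if (stop2 >= 0 && best <= stop2) break;
    }
    out[g] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mark voxels touched by any triangle (dense barycentric sampling at
// sub-voxel pitch).
// [[Rcpp::export]]
LogicalVector cpp_voxelize_surface(NumericMatrix V, IntegerMatrix F,
                                   IntegerVector dim, NumericVector voxdim,
                                   NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  LogicalVector out(n);
  double pitch = 0.5 * std::min({voxdim[0], voxdim[1], voxdim[2]});
  for (int f = 0; f < F.nrow(); ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
    double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
    double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
    double lab = std::sqrt(dist2(a, b)), lac = std::sqrt(dist2(a, c));
    int nu = std::max(1, (int)std::ceil(lab / pitch));
    int nv = std::max(1, (int)std::ceil(lac / pitch));
    for (int iu = 0; iu <= nu; ++iu)
      for (int iv = 0; iv <= nv; ++iv) {
        double u = (double)iu / nu, v = (double)iv / nv;
        if (u + v > 1.0) { u = 1.0 - u; v = 1.0 - v; }  // fold onto triangle
        double px = a[0] + u * (b[0] - a[0]) + v * (c[0] - a[0]);
        double py = a[1] + u * (b[1] - a[1]) + v * (c[1] - a[1]);
        double pz = a[2] + u * (b[2] - a[2]) + v * (c[2] - a[2]);
        int i = (int)std::lround((px - origin[0]) / voxdim[0]);
        int j = (int)std::lround((py - origin[1]) / voxdim[1]);
        int k = (int)std::lround((pz - origin[2]) / voxdim[2]);
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        out[idx3(i, j, k, nx, ny)] = true;
      }
  }
  return out;
}

// 6-connected flood fill from the volume boundary over !blocked voxels.
// Returns TRUE for voxels reachable from outside.
// [[Rcpp::export]]
LogicalVector cpp_fill_exterior(LogicalVector blocked, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  LogicalVector vis(n);
  std::vector<int> stack;
  stack.reserve(1 << 16);
  auto push = [&](int i, int j, int k) {
    long long t = idx3(i, j, k, nx, ny);
    if (!vis[t] && !blocked[t]) { vis[t] = true; stack.push_back((int)t); }
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) { push(i, j, 0); push(i, j, nz - 1); }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) { push(i, 0, k); push(i, ny - 1, k); }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) { push(0, j, k); push(nx - 1, j, k); }
  while (!stack.empty()) {
    int t = stack.back(); stack.pop_back();
    int i = t % nx, j = (t / nx) % ny, k = t / (nx * ny);
    if (i > 0) push(i - 1, j, k);
    if (i + 1 < nx) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j + 1 < ny) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k + 1 < nz) push(i, j, k + 1);
  }
  return vis;
}

// ---------------------------------------------------------------------------
// For each point in A, distance to the nearest point in B (brute force).
// [[Rcpp::export]]
NumericVector cpp_point_set_mindist(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int j = 0; j < nb; ++j) { bx[j] = B(j, 0); by[j] = B(j, 1); bz[j] = B(j, 2); }
  for (int i = 0; i < na; ++i) {
    double px = A(i, 0), py = A(i, 1), pz = A(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nb; ++j) {
      double dx = px - bx[j], dy = py - by[j], dz = pz - bz[j];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear sampling of a volume at mm points; `outside` for out-of-grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericVector voxdim, NumericVector origin,
                            NumericMatrix pts, double outside = 0.0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double x = (pts(p, 0) - origin[0]) / voxdim[0];
    double y = (pts(p, 1) - origin[1]) / voxdim[1];
    double z = (pts(p, 2) - origin[2]) / voxdim[2];
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = outside;
      continue;
    }
    int i0 = std::min((int)std::floor(x), nx - 2);
    int j0 = std::min((int)std::floor(y), ny - 2);
    int k0 = std::min((int)std::floor(z), nz - 2);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          acc += w * vol[idx3(i0 + dx, j0 + dy, k0 + dz, nx, ny)];
        }
    out[p] = acc;
  }
  return out;
}
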
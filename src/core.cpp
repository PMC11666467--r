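// Voxel-level kernels shared by the segmentation and morphometry stages.
//
// Array convention: R arrays with dim = c(nz, ny, nx), axis order (z, y, x),
// column-major, so linear index = k + nz * (j + ny * i) with 0-based k, j, i.
// All distances are physical (micrometres) on the anisotropic grid.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <limits>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 26-neighbourhood offsets (z, y, x), excluding (0,0,0)
// ---------------------------------------------------------------------------
struct Neigh {
  int dz[26], dy[26], dx[26];
  Neigh() {
    int n = 0;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dz[n] = a; dy[n] = b; dx[n] = c; ++n;
        }
  }
};
static const Neigh NB26;

static const int NB6_DZ[6] = {-1, 1, 0, 0, 0, 0};
static const int NB6_DY[6] = {0, 0, -1, 1, 0, 0};
static const int NB6_DX[6] = {0, 0, 0, 0, -1, 1};

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform
// (lower-envelope-of-parabolas algorithm, one pass per axis).
// Returns, for every voxel, the distance in um to the nearest voxel where
// mask is FALSE.  All-true mask -> Inf everywhere.
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w, int n) {
  // w = grid spacing along this axis; squared distances.
  // Parabolas with infinite height never enter the lower envelope, so they
  // are skipped; the caller guarantees at least one finite entry.
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + w2 * (double)q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along z (stride 1)
  f.resize(nz); d.resize(nz);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
      bool any_fin = false;
      for (int k = 0; k < nz; ++k) { f[k] = out[base + k]; if (f[k] < INF) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, spacing[0], nz);
      for (int k = 0; k < nz; ++k) out[base + k] = d[k];
    }
  // pass along y (stride nz)
  f.resize(ny); d.resize(ny);
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) {
      R_xlen_t base = k + (R_xlen_t)nz * ny * i;
      bool any_fin = false;
      for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)nz * j]; if (f[j] < INF) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, spacing[1], ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nz * j] = d[j];
    }
  // pass along x (stride nz*ny)
  f.resize(nx); d.resize(nx);
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int j = 0; j < ny; ++j)
    for (int k = 0; k < nz; ++k) {
      R_xlen_t base = k + (R_xlen_t)nz * j;
      bool any_fin = false;
      for (int i = 0; i < nx; ++i) { f[i] = out[base + sx * i]; if (f[i] < INF) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, d, spacing[2], nx);
      for (int i = 0; i < nx; ++i) out[base + sx * i] = d[i];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] < INF) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Multi-source geodesic Dijkstra on the 26-connected voxel graph restricted
// to `domain`.  Edge weights are physical centre-to-centre distances,
// quantized to integer multiples of q = 2^-20 * max(spacing) and accumulated
// in 64-bit integers, so path lengths are exact and ties are exact.
// Keys are lexicographic (distance, label): each voxel receives the label of
// the seed with the smallest geodesic distance, ties resolved to the smaller
// label id.  Returns dist (um, Inf if unreachable) and labels (0 if none).
// ---------------------------------------------------------------------------
struct QNode {
  uint64_t dist;
  int label;
  R_xlen_t voxel;
};
struct QNodeCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    if (a.label != b.label) return a.label > b.label;
    return a.voxel > b.voxel;
  }
};

// [[Rcpp::export(name = ".geodesic_cpp")]]
List geodesic_cpp(LogicalVector domain, IntegerVector seeds,
                  IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double sp_max = std::max(spacing[0], std::max(spacing[1], spacing[2]));
  const double q = sp_max / 1048576.0; // 2^-20 * max spacing

  // integer edge weights per 26-offset
  uint64_t w26[26];
  for (int m = 0; m < 26; ++m) {
    double ez = NB26.dz[m] * spacing[0];
    double ey = NB26.dy[m] * spacing[1];
    double ex = NB26.dx[m] * spacing[2];
    double len = std::sqrt(ez * ez + ey * ey + ex * ex);
    w26[m] = (uint64_t)std::llround(len / q);
  }

  const uint64_t UINF = std::numeric_limits<uint64_t>::max();
  std::vector<uint64_t> dist(n, UINF);
  std::vector<int> lab(n, 0);
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;

  for (R_xlen_t v = 0; v < n; ++v) {
    if (seeds[v] > 0) {
      if (!domain[v]) stop("seed voxel outside domain");
      dist[v] = 0;
      lab[v] = seeds[v];
      pq.push({0, seeds[v], v});
    }
  }

  while (!pq.empty()) {
    QNode cur = pq.top();
    pq.pop();
    if (cur.dist != dist[cur.voxel] || cur.label != lab[cur.voxel]) continue;
    R_xlen_t v = cur.voxel;
    int k = (int)(v % nz);
    R_xlen_t rest = v / nz;
    int j = (int)(rest % ny);
    int i = (int)(rest / ny);
    for (int m = 0; m < 26; ++m) {
      int kk = k + NB26.dz[m], jj = j + NB26.dy[m], ii = i + NB26.dx[m];
      if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
        continue;
      R_xlen_t u = kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii);
      if (!domain[u]) continue;
      uint64_t nd = cur.dist + w26[m];
      if (nd < dist[u] || (nd == dist[u] && cur.label < lab[u])) {
        dist[u] = nd;
        lab[u] = cur.label;
        pq.push({nd, cur.label, u});
      }
    }
  }

  NumericVector dout(n);
  IntegerVector lout(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    dout[v] = (dist[v] == UINF) ? INF : dist[v] * q;
    lout[v] = lab[v];
  }
  return List::create(_["dist"] = dout, _["label"] = lout);
}

// ---------------------------------------------------------------------------
// Connected-component labelling (BFS), connectivity 6 or 26.
// Components numbered 1..N in order of first linear-scan encounter.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  const int nnb = (connectivity == 6) ? 6 : 26;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v % nz);
      R_xlen_t rest = v / nz;
      int j = (int)(rest % ny);
      int i = (int)(rest / ny);
      for (int m = 0; m < nnb; ++m) {
        int kk, jj, ii;
        if (connectivity == 6) {
          kk = k + NB6_DZ[m]; jj = j + NB6_DY[m]; ii = i + NB6_DX[m];
        } else {
          kk = k + NB26.dz[m]; jj = j + NB26.dy[m]; ii = i + NB26.dx[m];
        }
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
          continue;
        R_xlen_t u = kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii);
        if (mask[u] && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable 1D correlation along one axis (0 = z, 1 = y, 2 = x) with
// reflect ("mirror") boundary handling.  Kernel must have odd length.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector x, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int r = kl / 2;
  NumericVector out(x.size());
  int nax = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nz : (R_xlen_t)nz * ny;

  // iterate over all lines along `axis`
  std::vector<double> line(nax), res(nax);
  int n1 = (axis == 0) ? ny : nz;
  int n2 = (axis == 2) ? ny : nx;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)nz * (a + (R_xlen_t)ny * b);
      else if (axis == 1) base = a + (R_xlen_t)nz * ny * b;
      else base = a + (R_xlen_t)nz * b;
      for (int t = 0; t < nax; ++t) line[t] = x[base + stride * t];
      for (int t = 0; t < nax; ++t) {
        double acc = 0.0;
        for (int m = -r; m <= r; ++m) {
          int s = t + m;
          // reflect: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
          while (s < 0 || s >= nax) {
            if (s < 0) s = -s - 1;
            if (s >= nax) s = 2 * nax - s - 1;
          }
          acc += kernel[m + r] * line[s];
        }
        res[t] = acc;
      }
      for (int t = 0; t < nax; ++t) out[base + stride * t] = res[t];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Regional maxima of `values` restricted to `domain`, 26-connectivity:
// a domain voxel is kept when no in-domain 26-neighbour has a larger value
// (plateau voxels are all kept).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".regional_maxima_cpp")]]
LogicalVector regional_maxima_cpp(NumericVector values, LogicalVector domain,
                                  IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, FALSE);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!domain[v]) continue;
    int k = (int)(v % nz);
    R_xlen_t rest = v / nz;
    int j = (int)(rest % ny);
    int i = (int)(rest / ny);
    bool ismax = true;
    for (int m = 0; m < 26 && ismax; ++m) {
      int kk = k + NB26.dz[m], jj = j + NB26.dy[m], ii = i + NB26.dx[m];
      if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
        continue;
      R_xlen_t u = kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii);
      if (domain[u] && values[u] > values[v]) ismax = false;
    }
    out[v] = ismax;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Voxels of `a` that are 26-adjacent to at least one voxel of `b`.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".adjacent_to_cpp")]]
LogicalVector adjacent_to_cpp(LogicalVector a, LogicalVector b,
                              IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, FALSE);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!a[v]) continue;
    int k = (int)(v % nz);
    R_xlen_t rest = v / nz;
    int j = (int)(rest % ny);
    int i = (int)(rest / ny);
    for (int m = 0; m < 26; ++m) {
      int kk = k + NB26.dz[m], jj = j + NB26.dy[m], ii = i + NB26.dx[m];
      if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
        continue;
      R_xlen_t u = kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii);
      if (b[u]) { out[v] = TRUE; break; }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Crofton transition counts: for each label 1..n_labels and each direction
// offset (rows of `offsets`, (dz,dy,dx) in voxels), the number of ordered
// voxel pairs (v, v + offset) such that exactly one of the pair carries the
// label.  Voxels outside the volume count as background, so surfaces at the
// image border are included.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".crofton_counts_cpp")]]
IntegerMatrix crofton_counts_cpp(IntegerVector labels, IntegerVector dims,
                                 int n_labels, IntegerMatrix offsets) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int nd = offsets.nrow();
  IntegerMatrix out(n_labels, nd);
  for (int d = 0; d < nd; ++d) {
    const int oz = offsets(d, 0), oy = offsets(d, 1), ox = offsets(d, 2);
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j)
        for (int k = 0; k < nz; ++k) {
          R_xlen_t v = k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
          int lv = labels[v];
          int kk = k + oz, jj = j + oy, ii = i + ox;
          int lu = 0;
          bool inside = (kk >= 0 && kk < nz && jj >= 0 && jj < ny &&
                         ii >= 0 && ii < nx);
          if (inside)
            lu = labels[kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii)];
          if (lv == lu) continue;
          if (lv > 0) out(lv - 1, d) += 1;
          if (lu > 0) out(lu - 1, d) += 1;
          // pairs straddling the border are visited once (from the inside
          // voxel); interior pairs are visited once in this scan direction.
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching-tetrahedra surface area of the iso-surface {field == level}.
// Each grid cell (cube of 8 voxel centres) is split into 6 tetrahedra;
// within a tetrahedron the iso-surface is the plane cut given by linear
// interpolation along edges.  Coordinates are physical (z*dz, y*dy, x*dx).
// ---------------------------------------------------------------------------
static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Collect the marching-tetrahedra triangle soup into a shared-vertex mesh
// and (optionally) apply Taubin lambda/mu smoothing, which flattens the
// voxel staircase without the volume shrinkage of plain Laplacian
// smoothing; returns the total triangle area.  With n_iter = 0 this is the
// raw iso-surface area.
struct MeshAccum {
  std::unordered_map<uint64_t, int> vindex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri; // triples of vertex ids

  int add_vertex(const double p[3]) {
    // identical crossings are computed from identical endpoint coordinates,
    // so exact dedup only needs a quantum below the minimum vertex
    // separation (~0.25 * min spacing); 1/64 um is ample for real spacings
    uint64_t qa = (uint64_t)std::llround(p[0] * 64.0);
    uint64_t qb = (uint64_t)std::llround(p[1] * 64.0);
    uint64_t qc = (uint64_t)std::llround(p[2] * 64.0);
    uint64_t key = (qa & 0x1FFFFF) | ((qb & 0x1FFFFF) << 21) |
                   ((qc & 0x1FFFFF) << 42);
    auto it = vindex.find(key);
    if (it != vindex.end()) return it->second;
    int id = (int)vx.size();
    vindex.emplace(key, id);
    vx.push_back(p[0]); vy.push_back(p[1]); vz.push_back(p[2]);
    return id;
  }
  void add_tri(const double a[3], const double b[3], const double c[3]) {
    int ia = add_vertex(a), ib = add_vertex(b), ic = add_vertex(c);
    if (ia == ib || ib == ic || ia == ic) return;
    tri.push_back(ia); tri.push_back(ib); tri.push_back(ic);
  }
};

static double mesh_total_area(MeshAccum& M, int n_iter, double lambda,
                              double mu) {
  const int nv = (int)M.vx.size();
  if (n_iter > 0 && nv > 0) {
    // vertex adjacency from triangle edges
    std::vector<std::vector<int>> adj(nv);
    auto link = [&](int a, int b) {
      adj[a].push_back(b);
      adj[b].push_back(a);
    };
    for (size_t t = 0; t < M.tri.size(); t += 3) {
      link(M.tri[t], M.tri[t + 1]);
      link(M.tri[t + 1], M.tri[t + 2]);
      link(M.tri[t], M.tri[t + 2]);
    }
    for (int v = 0; v < nv; ++v) {
      std::sort(adj[v].begin(), adj[v].end());
      adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
    }
    std::vector<double> nx_(nv), ny_(nv), nz_(nv);
    for (int it = 0; it < 2 * n_iter; ++it) {
      double f = (it % 2 == 0) ? lambda : mu;
      for (int v = 0; v < nv; ++v) {
        if (adj[v].empty()) { nx_[v] = M.vx[v]; ny_[v] = M.vy[v];
                              nz_[v] = M.vz[v]; continue; }
        double sx = 0, sy = 0, sz = 0;
        for (int u : adj[v]) { sx += M.vx[u]; sy += M.vy[u]; sz += M.vz[u]; }
        double k = 1.0 / adj[v].size();
        nx_[v] = M.vx[v] + f * (sx * k - M.vx[v]);
        ny_[v] = M.vy[v] + f * (sy * k - M.vy[v]);
        nz_[v] = M.vz[v] + f * (sz * k - M.vz[v]);
      }
      M.vx.swap(nx_); M.vy.swap(ny_); M.vz.swap(nz_);
    }
  }
  double total = 0.0;
  for (size_t t = 0; t < M.tri.size(); t += 3) {
    double a[3] = {M.vx[M.tri[t]], M.vy[M.tri[t]], M.vz[M.tri[t]]};
    double b[3] = {M.vx[M.tri[t + 1]], M.vy[M.tri[t + 1]], M.vz[M.tri[t + 1]]};
    double c[3] = {M.vx[M.tri[t + 2]], M.vy[M.tri[t + 2]], M.vz[M.tri[t + 2]]};
    total += tri_area(a, b, c);
  }
  return total;
}

// [[Rcpp::export(name = ".mesh_area_cpp")]]
double mesh_area_cpp(NumericVector field, IntegerVector dims,
                     NumericVector spacing, double level,
                     int n_iter = 0, double lambda = 0.5, double mu = -0.53) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  // 6-tetrahedra decomposition of the unit cube (corner ids 0..7 with
  // corner c = (cz, cy, cx) bits: c = cz + 2*cy + 4*cx)
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  static const int CZ[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int CX[8] = {0, 0, 0, 0, 1, 1, 1, 1};

  MeshAccum M;
  double val[8];
  double crd[8][3];
  for (int i = 0; i + 1 < nx; ++i)
    for (int j = 0; j + 1 < ny; ++j)
      for (int k = 0; k + 1 < nz; ++k) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          int kk = k + CZ[c], jj = j + CY[c], ii = i + CX[c];
          val[c] = field[kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii)];
          crd[c][0] = kk * spacing[0];
          crd[c][1] = jj * spacing[1];
          crd[c][2] = ii * spacing[2];
          if (val[c] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int nab = 0;
          for (int c = 0; c < 4; ++c)
            if (val[T[c]] > level) ++nab;
          if (nab == 0 || nab == 4) continue;
          // collect intersection points on edges crossing the level
          double pts[4][3];
          int np = 0;
          for (int a = 0; a < 4; ++a)
            for (int b = a + 1; b < 4; ++b) {
              double va = val[T[a]], vb = val[T[b]];
              if ((va > level) == (vb > level)) continue;
              double tt = (level - va) / (vb - va);
              for (int d = 0; d < 3; ++d)
                pts[np][d] = crd[T[a]][d] + tt * (crd[T[b]][d] - crd[T[a]][d]);
              ++np;
            }
          if (np == 3) {
            M.add_tri(pts[0], pts[1], pts[2]);
          } else if (np == 4) {
            // quad: the enumeration order above always puts the two points
            // sharing no tetrahedron vertex at positions 0 and 3, so (0,3)
            // is a diagonal of the cyclic quad 0-1-3-2
            M.add_tri(pts[0], pts[1], pts[3]);
            M.add_tri(pts[0], pts[3], pts[2]);
          }
        }
      }
  return mesh_total_area(M, n_iter, lambda, mu);
}
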
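// Low-level voxel/mesh kernels: connected components, anisotropic Euclidean
// distance transform, maximal-inscribed-sphere local thickness, weighted
// grid geodesics, marching-tetrahedra isosurfacing, separable Gaussian
// smoothing, gridded nearest-neighbour surface distances, sphere painting.
// All physical quantities are in mm; arrays use R's column-major layout with
// dims (n1, n2, n3) and axis 1 the longitudinal axis.
#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// 26-neighbourhood offsets (excluding self)
static void neighbours26(std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        if (di || dj || dk) off.push_back({di, dj, dk});
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  if (connectivity == 26) {
    neighbours26(off);
  } else {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  }
  int next = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx]) continue;
    ++next;
    lab[idx] = next;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int i = cur % n1, j = (cur / n1) % n2, k = cur / (n1 * n2);
      for (const auto& o : off) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
          continue;
        int nb = lin(ii, jj, kk, n1, n2);
        if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// 1D squared distance transform (Felzenszwalb-Huttenlocher) on samples at
// positions idx * s.  f: input squared values; d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double s, int n) {
  const double INF = 1e300;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    while (true) {
      double vs = v[k] * s;
      double sep = (f[q] - f[v[k]] + qs * qs - vs * vs) / (2.0 * (qs - vs));
      if (sep <= z[k]) {
        if (k == 0) { v[0] = q; break; }  // q dominates everything so far
        --k;
      } else {
        ++k; v[k] = q; z[k] = sep; z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * s;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// Squared Euclidean distance from every voxel to the nearest background
// voxel centre, with anisotropic spacing (mm).  Background voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  const double INF = 1e30;   // effectively infinite vs any mm^2 distance
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = fg[i] ? INF : 0.0;
  // axis 1
  {
    std::vector<double> f(n1), d(n1);
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j) {
        int base = lin(0, j, k, n1, n2);
        for (int i = 0; i < n1; ++i) f[i] = g[base + i];
        dt1d(f, d, spacing[0], n1);
        for (int i = 0; i < n1; ++i) g[base + i] = d[i];
      }
  }
  // axis 2
  {
    std::vector<double> f(n2), d(n2);
    for (int k = 0; k < n3; ++k)
      for (int i = 0; i < n1; ++i) {
        for (int j = 0; j < n2; ++j) f[j] = g[lin(i, j, k, n1, n2)];
        dt1d(f, d, spacing[1], n2);
        for (int j = 0; j < n2; ++j) g[lin(i, j, k, n1, n2)] = d[j];
      }
  }
  // axis 3
  {
    std::vector<double> f(n3), d(n3);
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        for (int k = 0; k < n3; ++k) f[k] = g[lin(i, j, k, n1, n2)];
        dt1d(f, d, spacing[2], n3);
        for (int k = 0; k < n3; ++k) g[lin(i, j, k, n1, n2)] = d[k];
      }
  }
  return g;
}

// Hildebrand-Ruegsegger local thickness: for each foreground voxel the
// diameter of the largest inscribed sphere (centred at any foreground voxel,
// radius = distance to nearest background voxel centre) that contains it.
// Spheres whose ball is contained in a neighbour's ball are skipped.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector fg, IntegerVector dims,
                                  NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  NumericVector d2 = cpp_edt_sq(fg, dims, spacing);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = fg[i] ? std::sqrt(d2[i]) : 0.0;
  NumericVector th(n, 0.0);
  std::vector<std::array<int,3>> off;
  neighbours26(off);
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  for (int idx = 0; idx < n; ++idx) {
    if (!fg[idx]) continue;
    const double rp = r[idx];
    int i = idx % n1, j = (idx / n1) % n2, k = idx / (n1 * n2);
    // redundancy check: some neighbour's sphere strictly contains this one
    bool redundant = false;
    for (const auto& o : off) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
        continue;
      int nb = lin(ii, jj, kk, n1, n2);
      if (!fg[nb]) continue;
      double dd = std::sqrt(o[0]*o[0]*s1*s1 + o[1]*o[1]*s2*s2 +
                            o[2]*o[2]*s3*s3);
      if (r[nb] >= rp + dd) { redundant = true; break; }
    }
    if (redundant) continue;
    const int b1 = (int)std::ceil(rp / s1 + 1e-9),
              b2 = (int)std::ceil(rp / s2 + 1e-9),
              b3 = (int)std::ceil(rp / s3 + 1e-9);
    // tiny slack so voxels exactly on the sphere survive rounding
    const double rp2 = (rp + 1e-12) * (rp + 1e-12);
    for (int dk = -b3; dk <= b3; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= n3) continue;
      double zz = dk * s3 * dk * s3;
      for (int dj = -b2; dj <= b2; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= n2) continue;
        double yz = zz + dj * s2 * dj * s2;
        if (yz > rp2) continue;
        for (int di = -b1; di <= b1; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= n1) continue;
          if (yz + di * s1 * di * s1 > rp2) continue;
          int x = lin(ii, jj, kk, n1, n2);
          if (fg[x] && th[x] < 2.0 * rp) th[x] = 2.0 * rp;
        }
      }
    }
  }
  return th;
}

// Dijkstra over the 26-connected foreground grid.  Edge weight is the
// Euclidean step length (mm) times the mean of the endpoint node costs.
// Returns distances (Inf where unreachable) and 1-based parent indices.
// [[Rcpp::export]]
List cpp_grid_geodesic(LogicalVector fg, IntegerVector dims,
                       NumericVector spacing, int source,
                       NumericVector nodecost) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int n = n1 * n2 * n3;
  NumericVector dist(n, R_PosInf);
  IntegerVector parent(n, NA_INTEGER);
  std::vector<std::array<int,3>> off;
  neighbours26(off);
  std::vector<double> step(off.size());
  for (size_t t = 0; t < off.size(); ++t)
    step[t] = std::sqrt(off[t][0]*off[t][0]*spacing[0]*spacing[0] +
                        off[t][1]*off[t][1]*spacing[1]*spacing[1] +
                        off[t][2]*off[t][2]*spacing[2]*spacing[2]);
  typedef std::pair<double,int> Q;
  std::priority_queue<Q, std::vector<Q>, std::greater<Q>> pq;
  int s0 = source - 1;
  dist[s0] = 0.0;
  pq.push({0.0, s0});
  while (!pq.empty()) {
    double du = pq.top().first; int u = pq.top().second; pq.pop();
    if (du > dist[u]) continue;
    int i = u % n1, j = (u / n1) % n2, k = u / (n1 * n2);
    for (size_t t = 0; t < off.size(); ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
        continue;
      int v = lin(ii, jj, kk, n1, n2);
      if (!fg[v]) continue;
      double w = du + step[t] * 0.5 * (nodecost[u] + nodecost[v]);
      if (w < dist[v]) {
        dist[v] = w;
        parent[v] = u + 1;
        pq.push({w, v});
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}

// Marching tetrahedra isosurface of a scalar field sampled at voxel centres.
// Each grid cell is split into 6 tetrahedra around the main diagonal.
// Triangles are oriented with normals pointing toward low field values
// (outward when the structure has high values).  Vertices are de-duplicated
// by the grid edge they interpolate.
// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dims,
                             double level, NumericVector spacing,
                             NumericVector origin) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  static const int corner_off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  std::unordered_map<uint64_t,int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  auto corner_id = [&](int ci[3]) -> uint64_t {
    return (uint64_t)lin(ci[0], ci[1], ci[2], n1, n2);
  };
  auto get_vertex = [&](int a[3], int b[3], double fa, double fb) -> int {
    uint64_t ia = corner_id(a), ib = corner_id(b);
    uint64_t key = ia < ib ? ia * (uint64_t)(n1) * n2 * n3 + ib
                           : ib * (uint64_t)(n1) * n2 * n3 + ia;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double p[3];
    p[0] = origin[0] + (a[0] + t * (b[0] - a[0])) * spacing[0];
    p[1] = origin[1] + (a[1] + t * (b[1] - a[1])) * spacing[1];
    p[2] = origin[2] + (a[2] + t * (b[2] - a[2])) * spacing[2];
    int id = (int)vx.size();
    vx.push_back(p[0]); vy.push_back(p[1]); vz.push_back(p[2]);
    edge_vertex[key] = id;
    return id;
  };
  auto emit = [&](int va, int vb, int vc, const double in_pt[3],
                  const double out_pt[3]) {
    // orient so the normal points from inside (high field) to outside
    double ax = vx[vb]-vx[va], ay = vy[vb]-vy[va], az = vz[vb]-vz[va];
    double bx = vx[vc]-vx[va], by = vy[vc]-vy[va], bz = vz[vc]-vz[va];
    double nx = ay*bz - az*by, ny = az*bx - ax*bz, nz = ax*by - ay*bx;
    double dx = out_pt[0]-in_pt[0], dy = out_pt[1]-in_pt[1],
           dz = out_pt[2]-in_pt[2];
    if (nx*dx + ny*dy + nz*dz < 0) std::swap(vb, vc);
    f0.push_back(va + 1); f1.push_back(vb + 1); f2.push_back(vc + 1);
  };

  int ci[8][3];
  double fv[8], cpos[8][3];
  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          ci[c][0] = i + corner_off[c][0];
          ci[c][1] = j + corner_off[c][1];
          ci[c][2] = k + corner_off[c][2];
          fv[c] = field[lin(ci[c][0], ci[c][1], ci[c][2], n1, n2)];
          if (fv[c] >= level) any_in = true; else any_out = true;
          for (int d = 0; d < 3; ++d)
            cpos[c][d] = origin[d] + ci[c][d] * spacing[d];
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int idx4[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (fv[idx4[c]] >= level) ins[ni++] = idx4[c];
            else outs[no++] = idx4[c];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? ins[0] : outs[0];
            int* base = (ni == 1) ? outs : ins;
            int v0 = get_vertex(ci[apex], ci[base[0]], fv[apex], fv[base[0]]);
            int v1 = get_vertex(ci[apex], ci[base[1]], fv[apex], fv[base[1]]);
            int v2 = get_vertex(ci[apex], ci[base[2]], fv[apex], fv[base[2]]);
            const double* ip = (ni == 1) ? cpos[ins[0]] : cpos[ins[0]];
            const double* op = (ni == 1) ? cpos[outs[0]] : cpos[outs[0]];
            emit(v0, v1, v2, ip, op);
          } else { // 2 in, 2 out -> quad
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int vac = get_vertex(ci[a], ci[c], fv[a], fv[c]);
            int vad = get_vertex(ci[a], ci[d], fv[a], fv[d]);
            int vbc = get_vertex(ci[b], ci[c], fv[b], fv[c]);
            int vbd = get_vertex(ci[b], ci[d], fv[b], fv[d]);
            emit(vac, vad, vbd, cpos[a], cpos[c]);
            emit(vac, vbd, vbc, cpos[a], cpos[c]);
          }
        }
      }
  int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v) { V(v,0)=vx[v]; V(v,1)=vy[v]; V(v,2)=vz[v]; }
  for (int f = 0; f < nf; ++f) { F(f,0)=f0[f]; F(f,1)=f1[f]; F(f,2)=f2[f]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Separable Gaussian smoothing, sigma in voxels per axis, reflecting borders.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector a, IntegerVector dims,
                         NumericVector sigma) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector cur = clone(a), nxt(a.size());
  const int nn[3] = {n1, n2, n3};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double sum = 0.0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + rad];
    }
    for (auto& v : ker) v /= sum;
    int len = nn[ax];
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int pos = (ax == 0) ? i : (ax == 1) ? j : k;
          double acc = 0.0;
          for (int t = -rad; t <= rad; ++t) {
            int q = pos + t;
            if (q < 0) q = -q - 1;
            if (q >= len) q = 2 * len - q - 1;
            int ii = (ax == 0) ? q : i, jj = (ax == 1) ? q : j,
                kk = (ax == 2) ? q : k;
            acc += ker[t + rad] * cur[lin(ii, jj, kk, n1, n2)];
          }
          nxt[lin(i, j, k, n1, n2)] = acc;
        }
    std::swap(cur, nxt);
  }
  return cur;
}

// Nearest-neighbour distance from each query point to the reference point
// set, via a uniform grid hash with the given cell size (mm).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix query, NumericMatrix ref,
                          double cell) {
  const int nq = query.nrow(), nr = ref.nrow();
  NumericVector out(nq, R_PosInf);
  if (nr == 0) return out;
  double mn[3];
  for (int d = 0; d < 3; ++d) {
    mn[d] = ref(0, d);
    for (int i = 1; i < nr; ++i) if (ref(i, d) < mn[d]) mn[d] = ref(i, d);
  }
  auto cellkey = [&](int cx, int cy, int cz) -> uint64_t {
    return ((uint64_t)(uint32_t)(cx + 1000000) << 42) ^
           ((uint64_t)(uint32_t)(cy + 1000000) << 21) ^
           (uint64_t)(uint32_t)(cz + 1000000);
  };
  std::unordered_map<uint64_t, std::vector<int>> grid;
  grid.reserve(nr * 2);
  std::vector<int> cc(3 * nr);
  for (int i = 0; i < nr; ++i) {
    for (int d = 0; d < 3; ++d)
      cc[3*i + d] = (int)std::floor((ref(i, d) - mn[d]) / cell);
    grid[cellkey(cc[3*i], cc[3*i+1], cc[3*i+2])].push_back(i);
  }
  int maxshell = 2;
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d)
      if (cc[3*i + d] > maxshell) maxshell = cc[3*i + d];
  maxshell += 2;
  for (int q = 0; q < nq; ++q) {
    double px = query(q,0), py = query(q,1), pz = query(q,2);
    int qc[3];
    qc[0] = (int)std::floor((px - mn[0]) / cell);
    qc[1] = (int)std::floor((py - mn[1]) / cell);
    qc[2] = (int)std::floor((pz - mn[2]) / cell);
    double best = R_PosInf;
    for (int shell = 0; shell <= maxshell; ++shell) {
      if (best <= (double)(shell - 1) * cell && shell > 0) break;
      for (int dz = -shell; dz <= shell; ++dz)
        for (int dy = -shell; dy <= shell; ++dy)
          for (int dx = -shell; dx <= shell; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)))
                != shell) continue;
            auto it = grid.find(cellkey(qc[0]+dx, qc[1]+dy, qc[2]+dz));
            if (it == grid.end()) continue;
            for (int id : it->second) {
              double ddx = ref(id,0)-px, ddy = ref(id,1)-py,
                     ddz = ref(id,2)-pz;
              double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
              if (d2 < best * best) best = std::sqrt(d2);
            }
          }
    }
    out[q] = best;
  }
  return out;
}

// Union of spheres of the given radius around a polyline's sample points;
// used to rasterise tubular phantoms.
// [[Rcpp::export]]
LogicalVector cpp_paint_spheres(NumericMatrix centers, double radius,
                                IntegerVector dims, NumericVector spacing,
                                NumericVector origin) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector mask(n1 * n2 * n3, false);
  const double r2 = radius * radius;
  for (int c = 0; c < centers.nrow(); ++c) {
    double p1 = centers(c,0), p2 = centers(c,1), p3 = centers(c,2);
    int i0 = (int)std::floor((p1 - radius - origin[0]) / spacing[0]);
    int i1 = (int)std::ceil ((p1 + radius - origin[0]) / spacing[0]);
    int j0 = (int)std::floor((p2 - radius - origin[1]) / spacing[1]);
    int j1 = (int)std::ceil ((p2 + radius - origin[1]) / spacing[1]);
    int k0 = (int)std::floor((p3 - radius - origin[2]) / spacing[2]);
    int k1 = (int)std::ceil ((p3 + radius - origin[2]) / spacing[2]);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 >= n1) i1 = n1 - 1; if (j1 >= n2) j1 = n2 - 1;
    if (k1 >= n3) k1 = n3 - 1;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * spacing[2] - p3;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing[1] - p2;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * spacing[0] - p1;
          if (dx * dx + dyz <= r2) mask[lin(i, j, k, n1, n2)] = true;
        }
      }
    }
  }
  return mask;
}
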
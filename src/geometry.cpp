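// Geometry kernels: polygon rasterization, nearest-neighbor queries,
// isosurface extraction (marching tetrahedra), Laplacian mesh smoothing.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Even-odd scanline fill of a closed polygon given in (row, col) coordinates
// (1-based, matching R pixel indices). A pixel is filled when its center lies
// inside the polygon.
// [[Rcpp::export(name = ".fill_polygon_cpp")]]
LogicalMatrix fill_polygon_cpp(NumericMatrix poly, int nrow, int ncol) {
  int k = poly.nrow();
  LogicalMatrix out(nrow, ncol);
  if (k < 3) return out;
  std::vector<double> xs;
  for (int r = 1; r <= nrow; ++r) {
    xs.clear();
    double rr = (double)r;
    for (int i = 0; i < k; ++i) {
      int j = (i + 1) % k;
      double r1 = poly(i, 0), c1 = poly(i, 1);
      double r2 = poly(j, 0), c2 = poly(j, 1);
      // half-open rule on the row axis avoids double-counting vertices
      if ((r1 <= rr && rr < r2) || (r2 <= rr && rr < r1)) {
        xs.push_back(c1 + (rr - r1) * (c2 - c1) / (r2 - r1));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int c0 = (int)std::ceil(xs[p]);
      int c1 = (int)std::floor(xs[p + 1]);
      if (c0 < 1) c0 = 1;
      if (c1 > ncol) c1 = ncol;
      for (int c = c0; c <= c1; ++c) out(r - 1, c - 1) = true;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// For each source pixel, the nearest target pixel within `radius` (Euclidean
// pixel distance); ties broken by smallest (row, col). Returns 1-based index
// into tgt, or NA when no candidate lies within the radius.
// [[Rcpp::export(name = ".prop_nn_cpp")]]
IntegerVector prop_nn_cpp(IntegerMatrix src, IntegerMatrix tgt, double radius) {
  int n = src.nrow(), m = tgt.nrow();
  IntegerVector out(n, NA_INTEGER);
  double r2max = radius * radius;
  for (int i = 0; i < n; ++i) {
    double best = r2max + 1e-9;
    int best_j = -1;
    for (int j = 0; j < m; ++j) {
      double dr = src(i, 0) - tgt(j, 0);
      double dc = src(i, 1) - tgt(j, 1);
      double d2 = dr * dr + dc * dc;
      if (d2 > r2max) continue;
      bool better = d2 < best - 1e-12;
      if (!better && std::fabs(d2 - best) <= 1e-12 && best_j >= 0) {
        // tie: smallest (row, col)
        if (tgt(j, 0) < tgt(best_j, 0) ||
            (tgt(j, 0) == tgt(best_j, 0) && tgt(j, 1) < tgt(best_j, 1)))
          better = true;
      }
      if (better) { best = d2; best_j = j; }
    }
    if (best_j >= 0) out[i] = best_j + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Minimal 3D kd-tree for nearest and fixed-radius queries.
namespace {

struct KDTree {
  const double* pts;  // n x 3, column-major (R matrix)
  int n;
  std::vector<int> idx;

  KDTree(const double* p, int n_) : pts(p), n(n_), idx(n_) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n, 0);
  }
  inline double coord(int i, int d) const { return pts[i + d * n]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int d = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, d) < coord(b, d); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void nearest(const double* q, int lo, int hi, int depth,
               double& best, int& best_i) const {
    if (hi <= lo) return;
    int d = depth % 3;
    int mid = (lo + hi) / 2;
    int i = idx[mid];
    double dx = q[0] - coord(i, 0), dy = q[1] - coord(i, 1),
           dz = q[2] - coord(i, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best) { best = d2; best_i = i; }
    double diff = q[d] - coord(i, d);
    if (diff < 0) {
      nearest(q, lo, mid, depth + 1, best, best_i);
      if (diff * diff < best) nearest(q, mid + 1, hi, depth + 1, best, best_i);
    } else {
      nearest(q, mid + 1, hi, depth + 1, best, best_i);
      if (diff * diff < best) nearest(q, lo, mid, depth + 1, best, best_i);
    }
  }

  void radius_accum(const double* q, double r2, int lo, int hi, int depth,
                    double* sum, int& count) const {
    if (hi <= lo) return;
    int d = depth % 3;
    int mid = (lo + hi) / 2;
    int i = idx[mid];
    double dx = q[0] - coord(i, 0), dy = q[1] - coord(i, 1),
           dz = q[2] - coord(i, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 <= r2) {
      sum[0] += coord(i, 0); sum[1] += coord(i, 1); sum[2] += coord(i, 2);
      ++count;
    }
    double diff = q[d] - coord(i, d);
    if (diff < 0) {
      radius_accum(q, r2, lo, mid, depth + 1, sum, count);
      if (diff * diff <= r2) radius_accum(q, r2, mid + 1, hi, depth + 1, sum, count);
    } else {
      radius_accum(q, r2, mid + 1, hi, depth + 1, sum, count);
      if (diff * diff <= r2) radius_accum(q, r2, lo, mid, depth + 1, sum, count);
    }
  }
};

}  // namespace

// Nearest reference point for each query point.
// Returns list(index = 1-based indices, dist = Euclidean distances).
// [[Rcpp::export(name = ".nn1_cpp")]]
List nn1_cpp(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  KDTree tree(REAL(ref), nr);
  IntegerVector index(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    double best = R_PosInf;
    int best_i = -1;
    tree.nearest(q, 0, nr, 0, best, best_i);
    index[i] = best_i + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = index, _["dist"] = dist);
}

// Mean of all reference points within `radius` of each query point.
// Returns list(count, mean) with mean rows NaN where count == 0.
// [[Rcpp::export(name = ".radius_mean_cpp")]]
List radius_mean_cpp(NumericMatrix query, NumericMatrix ref, double radius) {
  int nq = query.nrow(), nr = ref.nrow();
  KDTree tree(REAL(ref), nr);
  IntegerVector count(nq);
  NumericMatrix mean(nq, 3);
  double r2 = radius * radius;
  for (int i = 0; i < nq; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    double sum[3] = { 0.0, 0.0, 0.0 };
    int cnt = 0;
    tree.radius_accum(q, r2, 0, nr, 0, sum, cnt);
    count[i] = cnt;
    if (cnt > 0) {
      mean(i, 0) = sum[0] / cnt; mean(i, 1) = sum[1] / cnt;
      mean(i, 2) = sum[2] / cnt;
    } else {
      mean(i, 0) = mean(i, 1) = mean(i, 2) = NA_REAL;
    }
  }
  return List::create(_["count"] = count, _["mean"] = mean);
}

// ---------------------------------------------------------------------------
// Isosurface extraction by marching tetrahedra on a (slice, row, col) scalar
// field. Each lattice cube is split into the six tetrahedra sharing its main
// diagonal; the split uses the same global diagonals on shared faces, so the
// resulting surface is watertight. Vertices are welded by the lattice edge
// they interpolate. Coordinates: x = ox + (r-1)*dr, y = oy + (c-1)*dc,
// z = oz + (s-1)*ds (1-based indices; here 0-based internally with origin at
// index 0).
namespace {

struct MTBuilder {
  const double* f;
  int ns, nr, nc;
  double level;
  double ds, drr, dcc, ox, oy, oz;
  std::vector<double> verts;           // x,y,z triples
  std::vector<int> faces;              // 0-based vertex index triples
  std::unordered_map<uint64_t, int> edge_map;

  inline double val(int s, int r, int c) const {
    return f[s + (int64_t)ns * (r + (int64_t)nr * c)];
  }
  inline int64_t node_id(int s, int r, int c) const {
    return s + (int64_t)ns * (r + (int64_t)nr * c);
  }
  inline void node_pos(int s, int r, int c, double* p) const {
    p[0] = ox + r * drr; p[1] = oy + c * dcc; p[2] = oz + s * ds;
  }

  int edge_vertex(const int* a, const int* b) {
    int64_t ia = node_id(a[0], a[1], a[2]);
    int64_t ib = node_id(b[0], b[1], b[2]);
    uint64_t key = ia < ib
        ? ((uint64_t)ia << 32) | (uint64_t)ib
        : ((uint64_t)ib << 32) | (uint64_t)ia;
    auto it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    double va = val(a[0], a[1], a[2]), vb = val(b[0], b[1], b[2]);
    double t = (level - va) / (vb - va);
    double pa[3], pb[3];
    node_pos(a[0], a[1], a[2], pa);
    node_pos(b[0], b[1], b[2], pb);
    int id = (int)(verts.size() / 3);
    for (int d = 0; d < 3; ++d) verts.push_back(pa[d] + t * (pb[d] - pa[d]));
    edge_map[key] = id;
    return id;
  }

  void add_tri(int v0, int v1, int v2, const double* inside_ref) {
    // orient so the normal points away from the inside of the surface
    const double* a = &verts[3 * v0];
    const double* b = &verts[3 * v1];
    const double* c = &verts[3 * v2];
    double u[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    double v[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
    double nrm[3] = { u[1] * v[2] - u[2] * v[1],
                      u[2] * v[0] - u[0] * v[2],
                      u[0] * v[1] - u[1] * v[0] };
    double cen[3] = { (a[0] + b[0] + c[0]) / 3.0 - inside_ref[0],
                      (a[1] + b[1] + c[1]) / 3.0 - inside_ref[1],
                      (a[2] + b[2] + c[2]) / 3.0 - inside_ref[2] };
    double dot = nrm[0] * cen[0] + nrm[1] * cen[1] + nrm[2] * cen[2];
    if (dot >= 0) {
      faces.push_back(v0); faces.push_back(v1); faces.push_back(v2);
    } else {
      faces.push_back(v0); faces.push_back(v2); faces.push_back(v1);
    }
  }

  void do_tet(const int corners[4][3]) {
    double v[4];
    bool in[4];
    int nin = 0;
    for (int i = 0; i < 4; ++i) {
      v[i] = val(corners[i][0], corners[i][1], corners[i][2]);
      in[i] = v[i] > level;
      if (in[i]) ++nin;
    }
    if (nin == 0 || nin == 4) return;
    int ins[4], outs[4];
    int a = 0, bnum = 0;
    for (int i = 0; i < 4; ++i) (in[i] ? ins[a++] : outs[bnum++]) = i;

    // reference point on the inside for orientation
    double ref[3] = { 0, 0, 0 };
    for (int i = 0; i < nin; ++i) {
      double p[3];
      node_pos(corners[ins[i]][0], corners[ins[i]][1], corners[ins[i]][2], p);
      for (int d = 0; d < 3; ++d) ref[d] += p[d] / nin;
    }

    if (nin == 1) {
      int e0 = edge_vertex(corners[ins[0]], corners[outs[0]]);
      int e1 = edge_vertex(corners[ins[0]], corners[outs[1]]);
      int e2 = edge_vertex(corners[ins[0]], corners[outs[2]]);
      add_tri(e0, e1, e2, ref);
    } else if (nin == 3) {
      int e0 = edge_vertex(corners[outs[0]], corners[ins[0]]);
      int e1 = edge_vertex(corners[outs[0]], corners[ins[1]]);
      int e2 = edge_vertex(corners[outs[0]], corners[ins[2]]);
      add_tri(e0, e1, e2, ref);
    } else {  // nin == 2: quad split into two triangles
      int e00 = edge_vertex(corners[ins[0]], corners[outs[0]]);
      int e01 = edge_vertex(corners[ins[0]], corners[outs[1]]);
      int e11 = edge_vertex(corners[ins[1]], corners[outs[1]]);
      int e10 = edge_vertex(corners[ins[1]], corners[outs[0]]);
      add_tri(e00, e01, e11, ref);
      add_tri(e00, e11, e10, ref);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".mtet_isosurface_cpp")]]
List mtet_isosurface_cpp(NumericVector field, IntegerVector dims, double level,
                         NumericVector spacing, NumericVector origin) {
  MTBuilder mb;
  mb.f = REAL(field);
  mb.ns = dims[0]; mb.nr = dims[1]; mb.nc = dims[2];
  mb.level = level;
  mb.ds = spacing[0]; mb.drr = spacing[1]; mb.dcc = spacing[2];
  mb.oz = origin[2]; mb.ox = origin[0]; mb.oy = origin[1];

  // cube corner offsets, ordered around the 0 -> 6 main diagonal:
  // 0=(0,0,0) 1=(1,0,0) 2=(1,1,0) 3=(0,1,0) 4=(0,0,1) 5=(1,0,1) 6=(1,1,1) 7=(0,1,1)
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
  };

  for (int c = 0; c < mb.nc - 1; ++c)
    for (int r = 0; r < mb.nr - 1; ++r)
      for (int s = 0; s < mb.ns - 1; ++s) {
        // skip cubes with all corners on one side (fast path)
        bool any_in = false, any_out = false;
        int corner_pos[8][3];
        for (int k = 0; k < 8; ++k) {
          corner_pos[k][0] = s + off[k][2];
          corner_pos[k][1] = r + off[k][0];
          corner_pos[k][2] = c + off[k][1];
          double v = mb.val(corner_pos[k][0], corner_pos[k][1], corner_pos[k][2]);
          if (v > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int tc[4][3];
          for (int k = 0; k < 4; ++k)
            for (int d = 0; d < 3; ++d) tc[k][d] = corner_pos[tets[t][k]][d];
          mb.do_tet(tc);
        }
      }

  int nv = (int)(mb.verts.size() / 3);
  int nf = (int)(mb.faces.size() / 3);
  NumericMatrix vertices(nv, 3);
  for (int i = 0; i < nv; ++i) {
    vertices(i, 0) = mb.verts[3 * i];
    vertices(i, 1) = mb.verts[3 * i + 1];
    vertices(i, 2) = mb.verts[3 * i + 2];
  }
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = mb.faces[3 * i] + 1;
    faces(i, 1) = mb.faces[3 * i + 1] + 1;
    faces(i, 2) = mb.faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = vertices, _["faces"] = faces);
}

// ---------------------------------------------------------------------------
// Uniform Laplacian smoothing: v <- v + factor * (mean(neighbors) - v).
// [[Rcpp::export(name = ".laplacian_smooth_cpp")]]
NumericMatrix laplacian_smooth_cpp(NumericMatrix vertices, IntegerMatrix faces,
                                   int iterations, double factor) {
  int nv = vertices.nrow(), nf = faces.nrow();
  std::vector<std::vector<int> > adj(nv);
  for (int i = 0; i < nf; ++i) {
    int a = faces(i, 0) - 1, b = faces(i, 1) - 1, c = faces(i, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  NumericMatrix cur = clone(vertices);
  NumericMatrix nxt(nv, 3);
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < nv; ++i) {
      if (adj[i].empty()) {
        nxt(i, 0) = cur(i, 0); nxt(i, 1) = cur(i, 1); nxt(i, 2) = cur(i, 2);
        continue;
      }
      double m[3] = { 0, 0, 0 };
      for (int j : adj[i]) {
        m[0] += cur(j, 0); m[1] += cur(j, 1); m[2] += cur(j, 2);
      }
      double k = (double)adj[i].size();
      for (int d = 0; d < 3; ++d)
        nxt(i, d) = cur(i, d) + factor * (m[d] / k - cur(i, d));
    }
    std::swap(cur, nxt);
  }
  return cur;
}
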
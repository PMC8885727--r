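// 3D geometry kernels: Voronoi cell volumes by half-space clipping,
// incremental convex hull, and fixed-radius neighbour graph components.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <queue>
#include <cmath>
#include <algorithm>
#include <functional>
#include <limits>

using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a[1] * b[2] - a[2] * b[1], a[2] * b[0] - a[0] * b[2],
          a[0] * b[1] - a[1] * b[0]};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// ---------------------------------------------------------------------------
// Convex polyhedron as a vertex list plus faces (each a vertex-index loop).
// Used for Voronoi cells: start from a bounding cube, clip by bisector planes.
// ---------------------------------------------------------------------------
struct Polyhedron {
  std::vector<Vec3> verts;
  std::vector<std::vector<int> > faces;
  bool empty() const { return faces.empty(); }
};

static Polyhedron make_cube(const Vec3 &lo, const Vec3 &hi) {
  Polyhedron p;
  p.verts = {
      {lo[0], lo[1], lo[2]}, {hi[0], lo[1], lo[2]}, {hi[0], hi[1], lo[2]},
      {lo[0], hi[1], lo[2]}, {lo[0], lo[1], hi[2]}, {hi[0], lo[1], hi[2]},
      {hi[0], hi[1], hi[2]}, {lo[0], hi[1], hi[2]}};
  p.faces = {{0, 1, 2, 3}, {4, 5, 6, 7}, {0, 1, 5, 4},
             {2, 3, 7, 6}, {1, 2, 6, 5}, {0, 3, 7, 4}};
  return p;
}

// Clip polyhedron to half-space n.x <= c.  eps is an absolute tolerance on
// the plane distance (coordinates are in nm; eps scales with the scene).
// Vertices are append-only (dead vertices stay in the vertex list and are
// simply no longer referenced by any face); only faces crossing the plane
// are rebuilt, which keeps the per-clip cost proportional to the cut size.
struct ClipScratch {
  std::vector<double> d;
  std::vector<int> cap;
  std::vector<std::array<int, 3> > edge_cut;   // (a, b, new vertex index)
  std::vector<std::pair<double, int> > ang;
  std::vector<std::vector<int> > nfaces;
  std::vector<int> remap;
};

// drop vertices no longer referenced by any face (the vertex list is
// append-only during clipping and would otherwise grow linearly with the
// number of cutting planes)
static void compact_polyhedron(Polyhedron &p, ClipScratch &s) {
  s.remap.assign(p.verts.size(), -1);
  std::vector<Vec3> nv;
  nv.reserve(p.verts.size());
  for (auto &face : p.faces) {
    for (int &v : face) {
      if (s.remap[v] < 0) {
        s.remap[v] = (int)nv.size();
        nv.push_back(p.verts[v]);
      }
      v = s.remap[v];
    }
  }
  p.verts.swap(nv);
}

// returns true when the plane actually cut the cell
static bool clip_polyhedron(Polyhedron &p, const Vec3 &n, double c, double eps,
                            ClipScratch &s) {
  const int nv = (int)p.verts.size();
  s.d.resize(nv);
  bool any_out = false, any_in = false;
  for (int i = 0; i < nv; ++i) {
    s.d[i] = dot(n, p.verts[i]) - c;
    if (s.d[i] > eps) any_out = true; else any_in = true;
  }
  if (!any_out) return false;         // fully inside, unchanged
  if (!any_in) {                      // fully outside
    p.verts.clear();
    p.faces.clear();
    return true;
  }
  // the sign test above includes dead vertices; confirm on live ones
  any_out = any_in = false;
  for (auto &face : p.faces) {
    for (int v : face) {
      if (s.d[v] > eps) any_out = true; else any_in = true;
    }
    if (any_out && any_in) break;
  }
  if (!any_out) return false;
  if (!any_in) { p.verts.clear(); p.faces.clear(); return true; }

  s.cap.clear();
  s.edge_cut.clear();
  auto cut_edge = [&](int a, int b) -> int {
    int u = std::min(a, b), v = std::max(a, b);
    for (auto &e : s.edge_cut) {
      if (e[0] == u && e[1] == v) return e[2];
    }
    double t = s.d[a] / (s.d[a] - s.d[b]);
    Vec3 w = {p.verts[a][0] + t * (p.verts[b][0] - p.verts[a][0]),
              p.verts[a][1] + t * (p.verts[b][1] - p.verts[a][1]),
              p.verts[a][2] + t * (p.verts[b][2] - p.verts[a][2])};
    int idx = (int)p.verts.size();
    p.verts.push_back(w);
    s.d.push_back(0.0);
    s.edge_cut.push_back({u, v, idx});
    return idx;
  };

  s.nfaces.clear();
  for (auto &face : p.faces) {
    const int m = (int)face.size();
    bool f_out = false, f_in = false;
    for (int v : face) {
      if (s.d[v] > eps) f_out = true; else f_in = true;
    }
    if (!f_out) {                     // untouched face: move as-is
      s.nfaces.push_back(std::move(face));
      continue;
    }
    if (!f_in) continue;              // fully clipped away
    std::vector<int> nf;
    nf.reserve(m + 2);
    for (int i = 0; i < m; ++i) {
      int a = face[i], b = face[(i + 1) % m];
      bool ain = s.d[a] <= eps, bin = s.d[b] <= eps;
      if (ain) nf.push_back(a);
      if (ain != bin && std::abs(s.d[a] - s.d[b]) > 0) {
        int cutv = cut_edge(a, b);
        nf.push_back(cutv);
        s.cap.push_back(cutv);
      }
    }
    if ((int)nf.size() >= 3) s.nfaces.push_back(std::move(nf));
  }
  // build the cap face: order plane vertices by angle around their centroid
  std::sort(s.cap.begin(), s.cap.end());
  s.cap.erase(std::unique(s.cap.begin(), s.cap.end()), s.cap.end());
  if ((int)s.cap.size() >= 3) {
    Vec3 cen = {0, 0, 0};
    for (int v : s.cap)
      for (int k = 0; k < 3; ++k) cen[k] += p.verts[v][k];
    for (int k = 0; k < 3; ++k) cen[k] /= s.cap.size();
    double nn = norm(n);
    Vec3 un = {n[0] / nn, n[1] / nn, n[2] / nn};
    Vec3 ref = std::abs(un[0]) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
    Vec3 ax = cross(un, ref);
    double an = norm(ax);
    ax = {ax[0] / an, ax[1] / an, ax[2] / an};
    Vec3 ay = cross(un, ax);
    s.ang.clear();
    for (int v : s.cap) {
      Vec3 r = sub(p.verts[v], cen);
      s.ang.push_back({std::atan2(dot(r, ay), dot(r, ax)), v});
    }
    std::sort(s.ang.begin(), s.ang.end());
    std::vector<int> capface;
    capface.reserve(s.ang.size());
    for (auto &pr : s.ang) capface.push_back(pr.second);
    s.nfaces.push_back(std::move(capface));
  }
  p.faces.swap(s.nfaces);
  if (p.verts.size() > 48) compact_polyhedron(p, s);
  return true;
}

// Volume of a convex polyhedron: sum of pyramids from an interior point,
// with face normals oriented away from it (robust to face winding). Only
// vertices referenced by faces count (the vertex list is append-only).
static double polyhedron_volume(const Polyhedron &p) {
  if (p.faces.empty()) return 0.0;
  Vec3 o = {0, 0, 0};
  size_t nref = 0;
  for (auto &face : p.faces)
    for (int v : face) {
      for (int k = 0; k < 3; ++k) o[k] += p.verts[v][k];
      ++nref;
    }
  if (nref < 4) return 0.0;
  for (int k = 0; k < 3; ++k) o[k] /= nref;
  double vol = 0.0;
  for (auto &face : p.faces) {
    // Newell normal and face point
    Vec3 nrm = {0, 0, 0};
    const int m = (int)face.size();
    for (int i = 0; i < m; ++i) {
      const Vec3 &a = p.verts[face[i]];
      const Vec3 &b = p.verts[face[(i + 1) % m]];
      nrm[0] += (a[1] - b[1]) * (a[2] + b[2]);
      nrm[1] += (a[2] - b[2]) * (a[0] + b[0]);
      nrm[2] += (a[0] - b[0]) * (a[1] + b[1]);
    }
    double area2 = norm(nrm);
    if (area2 <= 0) continue;
    Vec3 fp = sub(p.verts[face[0]], o);
    double h = dot(nrm, fp) / area2;   // signed height from interior point
    vol += std::abs(h) * (area2 / 2.0) / 3.0;
  }
  return vol;
}

// ---------------------------------------------------------------------------
// Uniform grid for neighbour queries
// ---------------------------------------------------------------------------
struct PointGrid {
  Vec3 lo;
  double h;
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;
  PointGrid(const std::vector<Vec3> &pts, double cell) {
    const int n = (int)pts.size();
    lo = {R_PosInf, R_PosInf, R_PosInf};
    Vec3 hi = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], pts[i][k]);
        hi[k] = std::max(hi[k], pts[i][k]);
      }
    h = cell;
    nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / h) + 1);
    ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / h) + 1);
    nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / h) + 1);
    // cap the grid size for very fine cells on large extents
    double max_cells = 2.5e7;
    double total = (double)nx * ny * nz;
    if (total > max_cells) {
      double f = std::cbrt(total / max_cells);
      h *= f;
      nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / h) + 1);
      ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / h) + 1);
      nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / h) + 1);
    }
    cells.resize((size_t)nx * ny * nz);
    for (int i = 0; i < n; ++i) cells[cell_of(pts[i])].push_back(i);
  }
  inline int clampi(int v, int m) const { return std::max(0, std::min(v, m - 1)); }
  inline size_t cell_of(const Vec3 &p) const {
    int cx = clampi((int)std::floor((p[0] - lo[0]) / h), nx);
    int cy = clampi((int)std::floor((p[1] - lo[1]) / h), ny);
    int cz = clampi((int)std::floor((p[2] - lo[2]) / h), nz);
    return ((size_t)cz * ny + cy) * nx + cx;
  }
  double mean_occupancy() const {
    size_t nonempty = 0, total = 0;
    for (auto &c : cells) {
      if (!c.empty()) { ++nonempty; total += c.size(); }
    }
    return nonempty ? (double)total / nonempty : 0.0;
  }
};


// ---------------------------------------------------------------------------
// Static kd-tree with best-first (exact distance order) neighbour streaming
// ---------------------------------------------------------------------------
struct KDTree {
  struct Node {
    int lo, hi;          // index range in idx
    int left, right;     // children (-1 for leaf)
    Vec3 blo, bhi;       // bounding box
  };
  const std::vector<Vec3> &P;
  std::vector<int> idx;
  std::vector<Node> nodes;
  explicit KDTree(const std::vector<Vec3> &pts) : P(pts) {
    idx.resize(P.size());
    for (size_t i = 0; i < P.size(); ++i) idx[i] = (int)i;
    if (!P.empty()) build(0, (int)P.size());
  }
  int build(int lo, int hi) {
    Node nd;
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
    nd.blo = {R_PosInf, R_PosInf, R_PosInf};
    nd.bhi = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = lo; i < hi; ++i)
      for (int k = 0; k < 3; ++k) {
        nd.blo[k] = std::min(nd.blo[k], P[idx[i]][k]);
        nd.bhi[k] = std::max(nd.bhi[k], P[idx[i]][k]);
      }
    int me = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo > 16) {
      int dim = 0;
      double best = -1;
      for (int k = 0; k < 3; ++k) {
        double e = nd.bhi[k] - nd.blo[k];
        if (e > best) { best = e; dim = k; }
      }
      int mid = (lo + hi) / 2;
      std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                       [&](int a, int b) { return P[a][dim] < P[b][dim]; });
      int l = build(lo, mid);
      int r = build(mid, hi);
      nodes[me].left = l;
      nodes[me].right = r;
    }
    return me;
  }
  static double box_dist2(const Node &nd, const Vec3 &q) {
    double d2 = 0;
    for (int k = 0; k < 3; ++k) {
      double d = std::max(std::max(nd.blo[k] - q[k], q[k] - nd.bhi[k]), 0.0);
      d2 += d * d;
    }
    return d2;
  }
};

// streams neighbours of q in exact non-decreasing distance order
struct KNNStream {
  const KDTree &T;
  Vec3 q;
  // entries: (dist2, id); id >= 0 is a point, id < 0 encodes node -(id+1)
  std::priority_queue<std::pair<double, int>,
                      std::vector<std::pair<double, int> >,
                      std::greater<std::pair<double, int> > > heap;
  KNNStream(const KDTree &tree, const Vec3 &query) : T(tree), q(query) {
    if (!T.nodes.empty()) heap.push({KDTree::box_dist2(T.nodes[0], q), -1});
  }
  // returns (dist, point index) or (-1, -1) when exhausted
  std::pair<double, int> next() {
    while (!heap.empty()) {
      auto e = heap.top();
      heap.pop();
      if (e.second >= 0) return {std::sqrt(e.first), e.second};
      const KDTree::Node &nd = T.nodes[-(e.second + 1)];
      if (nd.left < 0) {
        for (int i = nd.lo; i < nd.hi; ++i) {
          int j = T.idx[i];
          Vec3 d = sub(T.P[j], q);
          heap.push({dot(d, d), j});
        }
      } else {
        heap.push({KDTree::box_dist2(T.nodes[nd.left], q), -(nd.left + 1)});
        heap.push({KDTree::box_dist2(T.nodes[nd.right], q), -(nd.right + 1)});
      }
    }
    return {-1.0, -1};
  }
};

// [[Rcpp::export(name = ".voronoi_cell_volumes_cpp")]]
List voronoi_cell_volumes_cpp(NumericMatrix pts, double pad,
                              LogicalVector is_hull) {
  const int n = pts.nrow();
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  Vec3 lo = {R_PosInf, R_PosInf, R_PosInf}, hi = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], P[i][k]);
      hi[k] = std::max(hi[k], P[i][k]);
    }
  Vec3 blo = {lo[0] - pad, lo[1] - pad, lo[2] - pad};
  Vec3 bhi = {hi[0] + pad, hi[1] + pad, hi[2] + pad};
  double diag = norm(sub(bhi, blo));
  double eps = 1e-12 * diag;

  KDTree tree(P);

  NumericVector volumes(n);
  LogicalVector bounded(n);
  LogicalVector interior(n);
  std::vector<std::vector<int> > neighbours(n);   // active Voronoi neighbours

  std::vector<std::array<double, 5> > cut_planes;   // (j, n, c) per cutting plane
  ClipScratch scratch;
  for (int i = 0; i < n; ++i) {
    const Vec3 &pi = P[i];
    // the cell starts as the global padded cube; candidates arrive in
    // exact distance order, so the nearest planes close the cell quickly
    // and the 2R termination bound collapses with it
    Polyhedron cellp = make_cube(blo, bhi);
    cut_planes.clear();
    Vec3 cb_lo, cb_hi;
    // max distance from pi to any live cell vertex, plus the cell bbox
    // (for O(1) candidate-plane rejection)
    auto update_bounds = [&]() {
      double r2 = 0;
      cb_lo = {R_PosInf, R_PosInf, R_PosInf};
      cb_hi = {R_NegInf, R_NegInf, R_NegInf};
      for (auto &face : cellp.faces)
        for (int v : face) {
          const Vec3 &vv = cellp.verts[v];
          Vec3 dv = sub(vv, pi);
          r2 = std::max(r2, dot(dv, dv));
          for (int k = 0; k < 3; ++k) {
            cb_lo[k] = std::min(cb_lo[k], vv[k]);
            cb_hi[k] = std::max(cb_hi[k], vv[k]);
          }
        }
      return std::sqrt(r2);
    };
    double R = update_bounds();
    KNNStream stream(tree, pi);
    while (true) {
      auto cand = stream.next();
      if (cand.second < 0 || cand.first > 2.0 * R) break;
      int j = cand.second;
      if (j == i || cand.first <= eps) continue;
      const Vec3 &pj = P[j];
      Vec3 nn = sub(pj, pi);
      double c = (dot(pj, pj) - dot(pi, pi)) / 2.0;
      // support of the cell bbox in direction nn: if the plane cannot
      // reach the box, it cannot cut the cell
      double support = 0;
      for (int k = 0; k < 3; ++k)
        support += std::max(nn[k] * cb_lo[k], nn[k] * cb_hi[k]);
      if (support <= c + eps) continue;
      bool cut = clip_polyhedron(cellp, nn, c, eps, scratch);
      if (cut) {
        cut_planes.push_back({(double)j, nn[0], nn[1], nn[2], c});
        if (cellp.empty()) break;
        R = update_bounds();
      }
    }
    if (cellp.empty()) {
      volumes[i] = 0.0;
      bounded[i] = false;
      continue;
    }
    // hull-boundary points have genuinely unbounded cells; all other cells
    // are finite, but cells with vertices outside the data bounding box are
    // flagged non-interior for the summary densities
    bool unbounded = is_hull[i] || cellp.empty();
    bool escapes_bbox = false;
    double touch_tol = std::max(1e-9 * diag, 1e-9);
    if (!unbounded) {
      for (auto &face : cellp.faces) {
        for (int vi : face) {
          const Vec3 &v = cellp.verts[vi];
          for (int k = 0; k < 3; ++k) {
            if (v[k] < lo[k] - touch_tol || v[k] > hi[k] + touch_tol)
              escapes_bbox = true;
          }
        }
        if (escapes_bbox) break;
      }
    }
    bounded[i] = !unbounded;
    interior[i] = !unbounded && !escapes_bbox;
    volumes[i] = unbounded ? 0.0 : polyhedron_volume(cellp);
    // record which cutting planes survive as faces of the final cell:
    // these are the point's Voronoi neighbours
    for (auto &pl : cut_planes) {
      Vec3 nn = {pl[1], pl[2], pl[3]};
      double c = pl[4];
      double tol = 1e-7 * diag * std::max(norm(nn), 1e-12);
      bool active = false;
      for (auto &face : cellp.faces) {
        for (int vi : face) {
          if (std::abs(dot(nn, cellp.verts[vi]) - c) <= tol) {
            active = true;
            break;
          }
        }
        if (active) break;
      }
      if (active) neighbours[i].push_back((int)pl[0]);
    }
  }
  // first-rank density: the median inverse cell volume over the cell and
  // its Voronoi neighbours (bounded cells only). The median is the robust
  // local estimate: a cluster-shell cell bulging into empty space inherits
  // its dense neighbourhood, while a single huge cell cannot poison the
  // density of the points around it, and a genuinely sparse neighbourhood
  // stays sparse. On a regular grid it equals 1 / V exactly.
  NumericVector rank_density(n);
  std::vector<double> dens;
  for (int i = 0; i < n; ++i) {
    dens.clear();
    if (bounded[i] && volumes[i] > 0) dens.push_back(1.0 / volumes[i]);
    for (int j : neighbours[i]) {
      if (bounded[j] && volumes[j] > 0) dens.push_back(1.0 / volumes[j]);
    }
    if (dens.empty()) {
      rank_density[i] = 0.0;
    } else {
      size_t m = dens.size() / 2;
      std::nth_element(dens.begin(), dens.begin() + m, dens.end());
      double med = dens[m];
      if (dens.size() % 2 == 0) {
        double lo_half = *std::max_element(dens.begin(), dens.begin() + m);
        med = (med + lo_half) / 2.0;
      }
      rank_density[i] = med;
    }
  }
  return List::create(_["volume"] = volumes, _["bounded"] = bounded,
                      _["interior"] = interior,
                      _["rank_density"] = rank_density);
}

// ---------------------------------------------------------------------------
// Incremental 3D convex hull: volume plus outward facet planes.
// ---------------------------------------------------------------------------
struct HullFace {
  int a, b, c;
  Vec3 n;       // outward normal (unit)
  double off;   // plane offset: n.x <= off inside
  bool alive;
};

// [[Rcpp::export(name = ".convex_hull_3d_cpp")]]
List convex_hull_3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  auto P = [&](int i) -> Vec3 { return {pts(i, 0), pts(i, 1), pts(i, 2)}; };
  double scale = 0.0;
  Vec3 lo = {R_PosInf, R_PosInf, R_PosInf}, hi = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], pts(i, k));
      hi[k] = std::max(hi[k], pts(i, k));
    }
  for (int k = 0; k < 3; ++k) scale = std::max(scale, hi[k] - lo[k]);
  double eps = std::max(1e-12, 1e-10 * std::max(scale, 1.0));

  List degenerate = List::create(
      _["volume"] = NA_REAL, _["degenerate"] = true,
      _["facets"] = NumericMatrix(0, 4));
  if (n < 4) return degenerate;

  // initial simplex: spread points
  int i0 = 0, i1 = -1;
  double best = -1;
  for (int i = 1; i < n; ++i) {
    double d = norm(sub(P(i), P(i0)));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= eps) return degenerate;
  int i2 = -1;
  best = -1;
  Vec3 e1 = sub(P(i1), P(i0));
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(e1, sub(P(i), P(i0))));
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps * norm(e1)) return degenerate;
  Vec3 nrm0 = cross(e1, sub(P(i2), P(i0)));
  int i3 = -1;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::abs(dot(nrm0, sub(P(i), P(i0))));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps * norm(nrm0)) return degenerate;   // coplanar

  std::vector<HullFace> faces;
  Vec3 cen = {0, 0, 0};
  int init[4] = {i0, i1, i2, i3};
  for (int k = 0; k < 4; ++k)
    for (int d = 0; d < 3; ++d) cen[d] += P(init[k])[d] / 4.0;
  auto add_face = [&](int a, int b, int c) {
    Vec3 nn = cross(sub(P(b), P(a)), sub(P(c), P(a)));
    double ln = norm(nn);
    if (ln <= 0) return;
    nn = {nn[0] / ln, nn[1] / ln, nn[2] / ln};
    double off = dot(nn, P(a));
    if (dot(nn, cen) > off) {        // flip outward
      nn = {-nn[0], -nn[1], -nn[2]};
      off = -off;
      std::swap(b, c);
    }
    faces.push_back({a, b, c, nn, off, true});
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    Vec3 p = P(i);
    std::vector<int> visible;
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (dot(faces[f].n, p) - faces[f].off > eps) visible.push_back(f);
    }
    if (visible.empty()) continue;
    // horizon edges: edges of visible faces shared with exactly one visible face
    std::map<std::pair<int, int>, int> edge_count;
    std::map<std::pair<int, int>, std::pair<int, int> > edge_dir;
    for (int f : visible) {
      int vs[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        std::pair<int, int> key(std::min(u, v), std::max(u, v));
        edge_count[key]++;
        edge_dir[key] = {u, v};
      }
      faces[f].alive = false;
    }
    for (auto &kv : edge_count) {
      if (kv.second != 1) continue;
      auto dir = edge_dir[kv.first];
      add_face(dir.first, dir.second, i);
    }
  }

  double vol = 0.0;
  int nf = 0;
  for (auto &f : faces) if (f.alive) ++nf;
  NumericMatrix facets(nf, 4);
  int r = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    // signed tetra from centroid
    Vec3 a = sub(P(f.a), cen), b = sub(P(f.b), cen), c = sub(P(f.c), cen);
    vol += std::abs(dot(a, cross(b, c))) / 6.0;
    facets(r, 0) = f.n[0];
    facets(r, 1) = f.n[1];
    facets(r, 2) = f.n[2];
    facets(r, 3) = f.off;
    ++r;
  }
  return List::create(_["volume"] = vol, _["degenerate"] = false,
                      _["facets"] = facets);
}

// ---------------------------------------------------------------------------
// Connected components of the fixed-radius neighbour graph (union-find).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".link_components_cpp")]]
IntegerVector link_components_cpp(NumericMatrix pts, double maxdist) {
  const int n = pts.nrow();
  IntegerVector comp(n);
  if (n == 0) return comp;
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  };
  PointGrid grid(P, std::max(maxdist, 1e-9));
  double d2 = maxdist * maxdist;
  for (int i = 0; i < n; ++i) {
    int cx = grid.clampi((int)std::floor((P[i][0] - grid.lo[0]) / grid.h), grid.nx);
    int cy = grid.clampi((int)std::floor((P[i][1] - grid.lo[1]) / grid.h), grid.ny);
    int cz = grid.clampi((int)std::floor((P[i][2] - grid.lo[2]) / grid.h), grid.nz);
    for (int dz = -1; dz <= 1; ++dz) {
      int z = cz + dz;
      if (z < 0 || z >= grid.nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cy + dy;
        if (y < 0 || y >= grid.ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int x = cx + dx;
          if (x < 0 || x >= grid.nx) continue;
          for (int j : grid.cells[((size_t)z * grid.ny + y) * grid.nx + x]) {
            if (j <= i) continue;
            double ddx = P[i][0] - P[j][0];
            double ddy = P[i][1] - P[j][1];
            double ddz = P[i][2] - P[j][2];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= d2) unite(i, j);
          }
        }
      }
    }
  }
  std::map<int, int> relabel;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) {
      int id = (int)relabel.size() + 1;
      relabel[r] = id;
      comp[i] = id;
    } else {
      comp[i] = it->second;
    }
  }
  return comp;
}
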
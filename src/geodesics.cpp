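// Geodesic distance backends on triangulated surfaces.
//
// All routines are intrinsic: a mesh enters as triangle connectivity plus
// per-triangle side lengths, so periodic (minimal-image) planar meshes can be
// handled by the same code path as embedded closed surfaces.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <map>
#include <utility>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct P2 {
  double x, y;
};

static inline double dist2d(const P2 &a, const P2 &b) {
  return std::hypot(a.x - b.x, a.y - b.y);
}

static inline double cross2(const P2 &o, const P2 &a, const P2 &b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

// Planar wavefront update at C from support vertices P, Q with values dP, dQ.
// b = |CP|, a = |CQ|, c = |PQ|.  Returns INF when the causality condition
// fails (the characteristic does not cross the open segment PQ).
static double tri_update(double dP, double dQ, double b, double a, double c) {
  if (!R_FINITE(dP) || !R_FINITE(dQ) || c <= 0) return INF;
  double nx = (dQ - dP) / c;
  if (std::fabs(nx) >= 1.0) return INF;
  double ny = std::sqrt(1.0 - nx * nx);
  double xC = (b * b + c * c - a * a) / (2.0 * c);
  double h2 = b * b - xC * xC;
  double yC = h2 > 0 ? std::sqrt(h2) : 0.0;
  if (yC <= 0) return INF;
  double xstar = xC - nx * (yC / ny);
  if (xstar <= 0.0 || xstar >= c) return INF;
  return dP + nx * xC + ny * yC;
}

// One update configuration for a (triangle, corner) pair: support vertex ids
// and the side lengths of the (possibly virtual, unfolded) triangle.
struct UpdPair {
  int p, q;        // support vertex ids
  double b, a, c;  // |C-p|, |C-q|, |p-q|
};

class FmmMesh {
public:
  int nv;
  std::vector<std::array<int, 3>> tri;
  std::vector<std::array<double, 3>> len;  // len[k][j] = edge opposite corner j
  // adjacency
  std::vector<std::vector<std::pair<int, int>>> vert_tris;  // (tri, corner)
  std::vector<std::vector<std::pair<int, double>>> vert_nbr; // (vertex, length)
  std::map<std::pair<int, int>, std::array<int, 2>> edge_tris;
  // per (tri, corner): update configurations (virtual splits for obtuse)
  std::vector<std::array<std::vector<UpdPair>, 3>> pairs;

  FmmMesh(int nv_, const IntegerMatrix &T, const NumericMatrix &L)
      : nv(nv_) {
    int m = T.nrow();
    tri.resize(m);
    len.resize(m);
    vert_tris.assign(nv, {});
    vert_nbr.assign(nv, {});
    for (int k = 0; k < m; ++k) {
      for (int j = 0; j < 3; ++j) {
        tri[k][j] = T(k, j);
        len[k][j] = L(k, j);
        vert_tris[T(k, j)].push_back({k, j});
      }
      for (int j = 0; j < 3; ++j) {
        int a = tri[k][(j + 1) % 3], b = tri[k][(j + 2) % 3];
        add_edge(a, b, k, len[k][j]);
      }
    }
    dedup_neighbours();
    build_pairs();
  }

  void add_edge(int a, int b, int k, double l) {
    std::pair<int, int> key(std::min(a, b), std::max(a, b));
    auto it = edge_tris.find(key);
    if (it == edge_tris.end()) {
      edge_tris[key] = {k, -1};
      vert_nbr[a].push_back({b, l});
      vert_nbr[b].push_back({a, l});
    } else if (it->second[1] == -1 && it->second[0] != k) {
      it->second[1] = k;
    }
  }

  void dedup_neighbours() {
    for (int v = 0; v < nv; ++v) {
      auto &nb = vert_nbr[v];
      std::sort(nb.begin(), nb.end());
      nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    }
  }

  int other_tri(int a, int b, int k) const {
    std::pair<int, int> key(std::min(a, b), std::max(a, b));
    auto it = edge_tris.find(key);
    if (it == edge_tris.end()) return -1;
    if (it->second[0] == k) return it->second[1];
    if (it->second[1] == k) return it->second[0];
    return -1;
  }

  // side length between vertices a,b inside triangle k
  double side_len(int k, int a, int b) const {
    for (int j = 0; j < 3; ++j) {
      int p = tri[k][(j + 1) % 3], q = tri[k][(j + 2) % 3];
      if ((p == a && q == b) || (p == b && q == a)) return len[k][j];
    }
    return NA_REAL;
  }

  int apex(int k, int a, int b) const {
    for (int j = 0; j < 3; ++j)
      if (tri[k][j] != a && tri[k][j] != b) return tri[k][j];
    return -1;
  }

  // Recursively unfold across the window edge (w1,w2) (2D positions pw1,pw2;
  // previous flattened apex at popp) to split the wedge at C (cpos) bounded
  // by directions to (idL,pL) and (idR,pR) into near-acute support pairs.
  // (cnL,cnR) is the CCW cone of directions from C that pass through every
  // window unfolded so far; pairs are only emitted when the whole sub-wedge
  // lies inside it, so virtual support segments are genuine surface paths.
  void cover(const P2 &cpos, int idL, P2 pL, int idR, P2 pR, int w1, P2 pw1,
             int w2, P2 pw2, const P2 &popp, int k, P2 cnL, P2 cnR, int depth,
             std::vector<UpdPair> &out) {
    P2 dL = {pL.x - cpos.x, pL.y - cpos.y};
    P2 dR = {pR.x - cpos.x, pR.y - cpos.y};
    bool in_cone = ccw_ge(cnL, dL) && ccw_ge(dL, cnR) &&
                   ccw_ge(cnL, dR) && ccw_ge(dR, cnR);
    bool wide = angle_wide(cpos, pL, pR);
    if (!wide || depth <= 0 || k < 0) {
      if (in_cone)
        out.push_back({idL, idR, dist2d(cpos, pL), dist2d(cpos, pR),
                       dist2d(pL, pR)});
      return;
    }
    int x = apex(k, w1, w2);
    double l1 = side_len(k, w1, x), l2 = side_len(k, w2, x);
    P2 px = place(pw1, pw2, l1, l2, popp);
    double sL = cross2(cpos, pL, px), sR = cross2(cpos, px, pR);
    double orient = cross2(cpos, pL, pR);
    bool inside;
    if (orient >= 0) inside = (sL > 0 && sR > 0);
    else inside = (sL < 0 && sR < 0);
    P2 dw1 = {pw1.x - cpos.x, pw1.y - cpos.y};
    P2 dw2 = {pw2.x - cpos.x, pw2.y - cpos.y};
    P2 dx = {px.x - cpos.x, px.y - cpos.y};
    if (inside) {
      P2 cl = cnL, cr = cnR;
      if (cone_intersect(cl, cr, dw1, dx))
        cover(cpos, idL, pL, x, px, w1, pw1, x, px, pw2,
              other_tri(w1, x, k), cl, cr, depth - 1, out);
      cl = cnL; cr = cnR;
      if (cone_intersect(cl, cr, dx, dw2))
        cover(cpos, x, px, idR, pR, x, px, w2, pw2, pw1,
              other_tri(x, w2, k), cl, cr, depth - 1, out);
    } else {
      bool beyond_left;  // x falls outside the wedge past the L boundary
      if (orient >= 0) beyond_left = (sL <= 0);
      else beyond_left = (sL >= 0);
      if (beyond_left) {
        P2 cl = cnL, cr = cnR;
        if (cone_intersect(cl, cr, dx, dw2))
          cover(cpos, idL, pL, idR, pR, x, px, w2, pw2, pw1,
                other_tri(x, w2, k), cl, cr, depth - 1, out);
      } else {
        P2 cl = cnL, cr = cnR;
        if (cone_intersect(cl, cr, dw1, dx))
          cover(cpos, idL, pL, idR, pR, w1, pw1, x, px, pw2,
                other_tri(w1, x, k), cl, cr, depth - 1, out);
      }
    }
  }

  // place apex with distances l1,l2 from p1,p2 on the side opposite popp
  static P2 place(const P2 &p1, const P2 &p2, double l1, double l2,
                  const P2 &popp) {
    double w = dist2d(p1, p2);
    double ux = (p2.x - p1.x) / w, uy = (p2.y - p1.y) / w;
    double xi = (l1 * l1 + w * w - l2 * l2) / (2.0 * w);
    double h2 = l1 * l1 - xi * xi;
    double eta = h2 > 0 ? std::sqrt(h2) : 0.0;
    // normal (-uy, ux); pick sign away from popp
    double side = (popp.x - p1.x) * (-uy) + (popp.y - p1.y) * ux;
    double sgn = side > 0 ? -1.0 : 1.0;
    return {p1.x + xi * ux + sgn * eta * (-uy),
            p1.y + xi * uy + sgn * eta * ux};
  }

  // split wedges wider than ~75 degrees: keeps every update direction well
  // inside some support pair, which tightens the first-order error constant
  static bool angle_wide(const P2 &c, const P2 &p, const P2 &q) {
    double ux = p.x - c.x, uy = p.y - c.y, vx = q.x - c.x, vy = q.y - c.y;
    double d = ux * vx + uy * vy;
    return d < 0.2588 * std::sqrt((ux * ux + uy * uy) * (vx * vx + vy * vy));
  }

  void build_pairs() {
    int m = tri.size();
    pairs.resize(m);
    for (int k = 0; k < m; ++k) {
      for (int j = 0; j < 3; ++j) {
        int C = tri[k][j];
        int A = tri[k][(j + 1) % 3], B = tri[k][(j + 2) % 3];
        double c = len[k][j];                 // |AB|
        double b = side_len(k, C, A);         // |CA|
        double a = side_len(k, C, B);         // |CB|
        double cosC = (a * a + b * b - c * c) / (2.0 * a * b);
        pairs[k][j].push_back({A, B, b, a, c});
        if (cosC < 0.2588) {
          // wide wedge: add unfolded support pairs across AB
          P2 pA = {0.0, 0.0}, pB = {c, 0.0};
          double xC = (b * b + c * c - a * a) / (2.0 * c);
          double h2 = b * b - xC * xC;
          P2 pC = {xC, h2 > 0 ? std::sqrt(h2) : 0.0};
          P2 cnL = {pA.x - pC.x, pA.y - pC.y};
          P2 cnR = {pB.x - pC.x, pB.y - pC.y};
          if (!ccw_ge(cnL, cnR)) std::swap(cnL, cnR);
          cover(pC, A, pA, B, pB, A, pA, B, pB, pC,
                other_tri(A, B, k), cnL, cnR, 12, pairs[k][j]);
        }
      }
    }
  }

  static inline bool ccw_ge(const P2 &u, const P2 &v) {
    return u.x * v.y - u.y * v.x >= -1e-12;
  }

  // Exact polyhedral distances in a small patch around a source vertex:
  // depth-limited unfolding of triangle chains with visibility-cone pruning
  // (directions from the source that pass through every window so far).
  // Removes the large relative error of the two-point update right next to
  // a point source.
  void exact_patch(int src, double *d,
                   std::priority_queue<std::pair<double, int>,
                                       std::vector<std::pair<double, int>>,
                                       std::greater<std::pair<double, int>>> &heap,
                   double rho) const {
    long budget = 200000;
    for (const auto &tk : vert_tris[src]) {
      int k = tk.first, j = tk.second;
      int A = tri[k][(j + 1) % 3], B = tri[k][(j + 2) % 3];
      double b = side_len(k, src, A), a = side_len(k, src, B), c = len[k][j];
      double cosg = (a * a + b * b - c * c) / (2.0 * a * b);
      cosg = std::max(-1.0, std::min(1.0, cosg));
      double g = std::acos(cosg);
      P2 pA = {b, 0.0}, pB = {a * std::cos(g), a * std::sin(g)};
      if (b < d[A]) { d[A] = b; heap.push({b, A}); }
      if (a < d[B]) { d[B] = a; heap.push({a, B}); }
      chase(A, pA, B, pB, pA, pB, other_tri(A, B, k), {0.0, 0.0}, 64, rho,
            budget, d, heap);
    }
  }

  // distance from the origin to segment (p, q)
  static double seg_dist0(const P2 &p, const P2 &q) {
    double vx = q.x - p.x, vy = q.y - p.y;
    double t = -(p.x * vx + p.y * vy) / (vx * vx + vy * vy);
    t = std::max(0.0, std::min(1.0, t));
    return std::hypot(p.x + t * vx, p.y + t * vy);
  }

  static bool arc_contains(const P2 &A, const P2 &B, const P2 &v) {
    return ccw_ge(A, v) && ccw_ge(v, B);
  }

  // intersect the CCW direction interval [L, R] with the interval subtended
  // by (p, q); returns false when empty. Both arcs are < pi wide, but they
  // may lie on opposite sides of the circle (curled-back developments), so
  // candidate endpoints are verified to lie inside BOTH input arcs --
  // pairwise cross tests alone are unreliable for near-antipodal directions.
  static bool cone_intersect(P2 &L, P2 &R, P2 p, P2 q) {
    if (!ccw_ge(p, q)) std::swap(p, q);
    P2 L0 = L, R0 = R;
    P2 Ln = ccw_ge(L0, p) ? p : L0;
    P2 Rn = ccw_ge(q, R0) ? q : R0;
    if (!ccw_ge(Ln, Rn)) return false;
    if (!arc_contains(L0, R0, Ln) || !arc_contains(p, q, Ln)) return false;
    if (!arc_contains(L0, R0, Rn) || !arc_contains(p, q, Rn)) return false;
    L = Ln;
    R = Rn;
    return true;
  }

  void chase(int a_id, P2 pa, int b_id, P2 pb, P2 coneL, P2 coneR, int k,
             P2 popp, int depth, double rho, long &budget, double *d,
             std::priority_queue<std::pair<double, int>,
                                 std::vector<std::pair<double, int>>,
                                 std::greater<std::pair<double, int>>> &heap)
      const {
    if (k < 0 || depth <= 0 || --budget <= 0) return;
    if (seg_dist0(pa, pb) > rho) return;
    int x = apex(k, a_id, b_id);
    double l1 = side_len(k, a_id, x), l2 = side_len(k, b_id, x);
    P2 px = place(pa, pb, l1, l2, popp);
    if (ccw_ge(coneL, px) && ccw_ge(px, coneR)) {
      double dist = std::hypot(px.x, px.y);
      if (dist < d[x]) {
        d[x] = dist;
        heap.push({dist, x});
      }
    }
    P2 nl = coneL, nr = coneR;
    if (cone_intersect(nl, nr, pa, px))
      chase(a_id, pa, x, px, nl, nr, other_tri(a_id, x, k), pb, depth - 1,
            rho, budget, d, heap);
    nl = coneL; nr = coneR;
    if (cone_intersect(nl, nr, px, pb))
      chase(x, px, b_id, pb, nl, nr, other_tri(x, b_id, k), pa, depth - 1,
            rho, budget, d, heap);
  }

  double patch_radius = 1.5;

  // single-source fast marching
  void run(int src, double *d) const {
    std::vector<char> frozen(nv, 0);
    for (int i = 0; i < nv; ++i) d[i] = INF;
    d[src] = 0.0;
    typedef std::pair<double, int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> heap;
    heap.push({0.0, src});
    // exact local initialisation: 1-ring via edge lengths plus exact
    // unfolded (continuous-Dijkstra) distances within a fixed metric radius,
    // so that near-field accuracy does not depend on the mesh resolution
    exact_patch(src, d, heap, patch_radius);
    while (!heap.empty()) {
      QE top = heap.top();
      heap.pop();
      int v = top.second;
      if (frozen[v]) continue;
      frozen[v] = 1;
      // relax neighbours of v
      for (const auto &tk : vert_tris[v]) {
        int k = tk.first;
        for (int j = 0; j < 3; ++j) {
          int w = tri[k][j];
          if (w == v || frozen[w]) continue;
          double cand = d[w];
          for (const auto &nb : vert_nbr[w])
            if (!std::isinf(d[nb.first]))
              cand = std::min(cand, d[nb.first] + nb.second);
          for (const auto &up : pairs[k][j]) {
            cand = std::min(cand, tri_update(d[up.p], d[up.q], up.b, up.a,
                                             up.c));
            // relaxation through (possibly virtual, unfolded) support edges
            if (R_FINITE(d[up.p])) cand = std::min(cand, d[up.p] + up.b);
            if (R_FINITE(d[up.q])) cand = std::min(cand, d[up.q] + up.a);
          }
          if (cand < d[w]) {
            d[w] = cand;
            heap.push({cand, w});
          }
        }
      }
    }
  }
};

// [[Rcpp::export]]
NumericMatrix fmm_mesh_cpp(int nv, IntegerMatrix tri, NumericMatrix len,
                           IntegerVector sources, double patch_radius) {
  FmmMesh mesh(nv, tri, len);
  mesh.patch_radius = patch_radius;
  int ns = sources.size();
  NumericMatrix out(nv, ns);
  std::vector<double> d(nv);
  for (int s = 0; s < ns; ++s) {
    mesh.run(sources[s], d.data());
    for (int i = 0; i < nv; ++i) out(i, s) = d[i];
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix dijkstra_mesh_cpp(int nv, IntegerMatrix tri, NumericMatrix len,
                                IntegerVector sources) {
  // undirected edge graph from the triangulation
  std::vector<std::vector<std::pair<int, double>>> adj(nv);
  std::map<std::pair<int, int>, bool> seen;
  for (int k = 0; k < tri.nrow(); ++k) {
    for (int j = 0; j < 3; ++j) {
      int a = tri(k, (j + 1) % 3), b = tri(k, (j + 2) % 3);
      std::pair<int, int> key(std::min(a, b), std::max(a, b));
      if (!seen[key]) {
        seen[key] = true;
        adj[a].push_back({b, len(k, j)});
        adj[b].push_back({a, len(k, j)});
      }
    }
  }
  int ns = sources.size();
  NumericMatrix out(nv, ns);
  typedef std::pair<double, int> QE;
  for (int s = 0; s < ns; ++s) {
    std::vector<double> d(nv, INF);
    d[sources[s]] = 0.0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> heap;
    heap.push({0.0, sources[s]});
    while (!heap.empty()) {
      QE top = heap.top();
      heap.pop();
      if (top.first > d[top.second] + 1e-15) continue;
      for (const auto &e : adj[top.second]) {
        double nd = top.first + e.second;
        if (nd < d[e.first]) {
          d[e.first] = nd;
          heap.push({nd, e.first});
        }
      }
    }
    for (int i = 0; i < nv; ++i) out(i, s) = d[i];
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// First-order Godunov fast sweeping for the eikonal equation on the torus
// parameter domain: (d_theta / r)^2 + (d_phi / (R + r cos theta))^2 = 1,
// periodic in both angles, point source at grid node (i0, j0).
// [[Rcpp::export]]
NumericMatrix torus_eikonal_cpp(double R, double r, int ntheta, int nphi,
                                int i0, int j0, double tol, int maxit) {
  double dth = 2.0 * M_PI / ntheta, dph = 2.0 * M_PI / nphi;
  std::vector<double> d((size_t)ntheta * nphi, INF);
  std::vector<double> h2(ntheta);  // metric phi-spacing per theta row
  double h1 = r * dth;
  for (int i = 0; i < ntheta; ++i) {
    double th = i * dth;
    h2[i] = (R + r * std::cos(th)) * dph;
  }
  auto idx = [&](int i, int j) {
    return (size_t)((i % ntheta + ntheta) % ntheta) * nphi +
           ((j % nphi + nphi) % nphi);
  };
  d[idx(i0, j0)] = 0.0;
  // exact-ish init in a small flat patch around the source (local metric)
  for (int di = -3; di <= 3; ++di)
    for (int dj = -3; dj <= 3; ++dj) {
      if (di == 0 && dj == 0) continue;
      double a1 = di * h1;
      double a2 = dj * (h2[(i0 + di / 2 + ntheta) % ntheta] + h2[i0]) / 2.0;
      d[idx(i0 + di, j0 + dj)] = std::sqrt(a1 * a1 + a2 * a2);
    }
  for (int it = 0; it < maxit; ++it) {
    double maxchg = 0.0;
    for (int sweep = 0; sweep < 4; ++sweep) {
      int istart = (sweep & 1) ? ntheta - 1 : 0;
      int istep = (sweep & 1) ? -1 : 1;
      int jstart = (sweep & 2) ? nphi - 1 : 0;
      int jstep = (sweep & 2) ? -1 : 1;
      for (int ii = 0, i = istart; ii < ntheta; ++ii, i += istep) {
        double ha = h1, hb = h2[i];
        for (int jj = 0, j = jstart; jj < nphi; ++jj, j += jstep) {
          size_t id = idx(i, j);
          if (id == idx(i0, j0)) continue;
          double a = std::min(d[idx(i - 1, j)], d[idx(i + 1, j)]);
          double b = std::min(d[idx(i, j - 1)], d[idx(i, j + 1)]);
          double x;
          if (!R_FINITE(a) && !R_FINITE(b)) continue;
          if (!R_FINITE(b) || a + ha <= b) x = a + ha;
          else if (!R_FINITE(a) || b + hb <= a) x = b + hb;
          else {
            // solve ((x-a)/ha)^2 + ((x-b)/hb)^2 = 1
            double A = 1.0 / (ha * ha) + 1.0 / (hb * hb);
            double B = -2.0 * (a / (ha * ha) + b / (hb * hb));
            double C = a * a / (ha * ha) + b * b / (hb * hb) - 1.0;
            double disc = B * B - 4.0 * A * C;
            if (disc < 0) disc = 0;
            x = (-B + std::sqrt(disc)) / (2.0 * A);
            if (x < std::max(a, b)) x = std::min(a + ha, b + hb);
          }
          if (x < d[id]) {
            maxchg = std::max(maxchg, d[id] - x);
            d[id] = x;
          }
        }
      }
    }
    if (maxchg < tol) break;
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(ntheta, nphi);
  for (int i = 0; i < ntheta; ++i)
    for (int j = 0; j < nphi; ++j) out(i, j) = d[idx(i, j)];
  return out;
}

// Periodic bicubic (Catmull-Rom) interpolation of a field sampled on a
// uniform periodic (theta, phi) grid with theta_i = i*2pi/n1, phi_j = j*2pi/n2.
// [[Rcpp::export]]
NumericVector bicubic_periodic_cpp(NumericMatrix f, NumericVector theta,
                                   NumericVector phi) {
  int n1 = f.nrow(), n2 = f.ncol(), nq = theta.size();
  double d1 = 2.0 * M_PI / n1, d2 = 2.0 * M_PI / n2;
  NumericVector out(nq);
  auto wrap = [](int i, int n) { return (i % n + n) % n; };
  auto cr = [](double p0, double p1, double p2, double p3, double t) {
    return p1 + 0.5 * t * (p2 - p0 +
           t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
           t * (3.0 * (p1 - p2) + p3 - p0)));
  };
  for (int q = 0; q < nq; ++q) {
    double x = theta[q] / d1, y = phi[q] / d2;
    int i1 = (int)std::floor(x), j1 = (int)std::floor(y);
    double tx = x - i1, ty = y - j1;
    double col[4];
    for (int a = -1; a <= 2; ++a) {
      int i = wrap(i1 + a, n1);
      double p0 = f(i, wrap(j1 - 1, n2)), p1 = f(i, wrap(j1, n2)),
             p2 = f(i, wrap(j1 + 1, n2)), p3 = f(i, wrap(j1 + 2, n2));
      col[a + 1] = cr(p0, p1, p2, p3, ty);
    }
    out[q] = cr(col[0], col[1], col[2], col[3], tx);
  }
  return out;
}
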
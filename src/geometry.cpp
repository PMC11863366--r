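// Geometric kernel: incremental 3D Delaunay triangulation (Bowyer-Watson),
// boundary facet extraction for hull / alpha complexes, point-to-mesh
// distances, point location, alpha-threshold scans and periodic
// single-linkage clustering.
//
// Degeneracy policy: MD lattice fixtures contain exactly cospherical and
// coplanar point groups, which double-precision predicates cannot order.
// All combinatorial decisions (conflict sets, walk orientation, facet
// orientation, point location) are therefore made on deterministically
// joggled coordinates, while every metric quantity (volume, area,
// distance) is evaluated on the original coordinates. A watertightness
// self-check (tetrahedron volume sum vs divergence-theorem volume of the
// boundary) guards each build; on failure the joggle is escalated and the
// triangulation rebuilt.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
#include <queue>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small vector helpers and predicates
// ---------------------------------------------------------------------------

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dist2(const double* a, const double* b) {
  double d0 = a[0] - b[0], d1 = a[1] - b[1], d2 = a[2] - b[2];
  return d0 * d0 + d1 * d1 + d2 * d2;
}

// orient3d: dot(cross(b-a, c-a), d-a); > 0 when d lies on the normal side
// of triangle (a,b,c)
static inline double orient3d(const double* a, const double* b,
                              const double* c, const double* d) {
  double ab[3], ac[3], ad[3], n[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(d, a, ad);
  vcross(ab, ac, n);
  return vdot(n, ad);
}

static inline double det3(double a00, double a01, double a02,
                          double a10, double a11, double a12,
                          double a20, double a21, double a22) {
  return a00 * (a11 * a22 - a12 * a21)
       - a01 * (a10 * a22 - a12 * a20)
       + a02 * (a10 * a21 - a11 * a20);
}

// insphere determinant, coordinates translated to p; the sign convention
// (inside positive vs negative) is calibrated once per build on the super
// tetrahedron and its centroid
static double insphere_det(const double* a, const double* b, const double* c,
                           const double* d, const double* p) {
  double m[4][4];
  const double* q[4] = { a, b, c, d };
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 3; ++j) m[i][j] = q[i][j] - p[j];
    m[i][3] = m[i][0] * m[i][0] + m[i][1] * m[i][1] + m[i][2] * m[i][2];
  }
  double det = 0;
  for (int i = 0; i < 4; ++i) {
    int r[3], k = 0;
    for (int j = 0; j < 4; ++j) if (j != i) r[k++] = j;
    double minor = det3(m[r[0]][0], m[r[0]][1], m[r[0]][2],
                        m[r[1]][0], m[r[1]][1], m[r[1]][2],
                        m[r[2]][0], m[r[2]][1], m[r[2]][2]);
    det += ((i % 2) ? -1.0 : 1.0) * m[i][3] * minor;
  }
  return det;
}

// circumsphere center and squared radius; false when nearly degenerate
static bool circumsphere(const double* a, const double* b, const double* c,
                         const double* d, double* center, double* r2) {
  double ba[3], ca[3], da[3];
  vsub(b, a, ba); vsub(c, a, ca); vsub(d, a, da);
  double la = vdot(ba, ba), lb = vdot(ca, ca), lc = vdot(da, da);
  double det = det3(ba[0], ba[1], ba[2], ca[0], ca[1], ca[2],
                    da[0], da[1], da[2]);
  double scale = std::max({ la, lb, lc });
  if (det == 0.0 || std::fabs(det) < 1e-30 * scale * std::sqrt(scale))
    return false;
  double inv = 0.5 / det;
  double x = (la * (ca[1] * da[2] - ca[2] * da[1])
            - ba[1] * (lb * da[2] - ca[2] * lc)
            + ba[2] * (lb * da[1] - ca[1] * lc)) * inv;
  double y = (ba[0] * (lb * da[2] - lc * ca[2])
            - la * (ca[0] * da[2] - ca[2] * da[0])
            + ba[2] * (ca[0] * lc - lb * da[0])) * inv;
  double z = (ba[0] * (ca[1] * lc - lb * da[1])
            - ba[1] * (ca[0] * lc - lb * da[0])
            + la * (ca[0] * da[1] - ca[1] * da[0])) * inv;
  center[0] = a[0] + x; center[1] = a[1] + y; center[2] = a[2] + z;
  *r2 = x * x + y * y + z * z;
  return true;
}

static inline double tet_volume(const double* a, const double* b,
                                const double* c, const double* d) {
  return std::fabs(orient3d(a, b, c, d)) / 6.0;
}

// deterministic pseudo-random in (-1, 1); independent of R's RNG state
static inline double hash_noise(int i, int j) {
  double s = std::sin(i * 12.9898 + j * 78.233 + 0.5) * 43758.5453123;
  return 2.0 * (s - std::floor(s)) - 1.0;
}

// ---------------------------------------------------------------------------
// Bowyer-Watson incremental Delaunay
// ---------------------------------------------------------------------------

struct Tet {
  int v[4];
  int adj[4];  // neighbour opposite v[i]; -1 = none
  bool alive;
};

struct Triangulation {
  std::vector<std::array<double, 3>> pts;  // joggled coordinates (+4 super)
  std::vector<Tet> tets;
  int n;             // number of real points
  double inSign;     // calibrated insphere sign convention

  const double* P(int i) const { return pts[i].data(); }

  bool conflicts(const Tet& t, const double* p) const {
    return inSign * insphere_det(P(t.v[0]), P(t.v[1]), P(t.v[2]),
                                 P(t.v[3]), p) > 0;
  }
};

// face key: sorted vertex triple packed into 64 bits (vertex ids < 2^21)
static inline uint64_t face_key(int a, int b, int c) {
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
  return ((uint64_t)a << 42) | ((uint64_t)b << 21) | (uint64_t)c;
}

// create a positively oriented tetrahedron
static void make_tet(Triangulation& T, Tet& t, int a, int b, int c, int d) {
  if (orient3d(T.P(a), T.P(b), T.P(c), T.P(d)) < 0) std::swap(c, d);
  t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
  t.adj[0] = t.adj[1] = t.adj[2] = t.adj[3] = -1;
  t.alive = true;
}

// walk-based location of a tetrahedron containing p; -1 on failure
static int walk_locate(const Triangulation& T, const double* p, int hint) {
  int cur = hint;
  size_t steps = 0, maxSteps = T.tets.size() * 4 + 64;
  while (cur >= 0 && steps++ < maxSteps) {
    if (!T.tets[cur].alive) { cur = -1; break; }
    const Tet& t = T.tets[cur];
    int next = -1;
    for (int i = 0; i < 4; ++i) {
      int f0 = t.v[(i + 1) % 4], f1 = t.v[(i + 2) % 4], f2 = t.v[(i + 3) % 4];
      double od = orient3d(T.P(f0), T.P(f1), T.P(f2), T.P(t.v[i]));
      double op = orient3d(T.P(f0), T.P(f1), T.P(f2), p);
      if (od * op < 0) { next = t.adj[i]; break; }
    }
    if (next == -1) return cur;
    cur = next;
  }
  // fallback: linear scan over alive tetrahedra
  for (size_t k = 0; k < T.tets.size(); ++k) {
    if (!T.tets[k].alive) continue;
    const Tet& t = T.tets[k];
    bool inside = true;
    for (int i = 0; i < 4 && inside; ++i) {
      int f0 = t.v[(i + 1) % 4], f1 = t.v[(i + 2) % 4], f2 = t.v[(i + 3) % 4];
      double od = orient3d(T.P(f0), T.P(f1), T.P(f2), T.P(t.v[i]));
      double op = orient3d(T.P(f0), T.P(f1), T.P(f2), p);
      if (od * op < 0) inside = false;
    }
    if (inside) return (int)k;
  }
  return -1;
}

// insert point idx; false on irrecoverable failure (retry with new joggle)
static bool insert_point(Triangulation& T, int idx, int& hint) {
  const double* p = T.P(idx);
  int loc = walk_locate(T, p, hint);
  if (loc < 0) return false;

  // conflict cavity: BFS over face-adjacent tetrahedra whose circumsphere
  // strictly contains p
  std::vector<int> cavity;
  std::vector<char> inCavity(T.tets.size(), 0);
  std::queue<int> q;
  q.push(loc); inCavity[loc] = 1;
  while (!q.empty()) {
    int c = q.front(); q.pop();
    cavity.push_back(c);
    for (int i = 0; i < 4; ++i) {
      int nb = T.tets[c].adj[i];
      if (nb >= 0 && !inCavity[nb] && T.tets[nb].alive &&
          T.conflicts(T.tets[nb], p)) {
        inCavity[nb] = 1; q.push(nb);
      }
    }
  }

  // boundary faces; absorb neighbours until the cavity is star-shaped
  // around p (every wall strictly visible from p)
  struct BFace { int a, b, c; int outside; };
  std::vector<BFace> bfaces;
  bool changed = true;
  size_t guard = 0, guardMax = T.tets.size() + 64;
  while (changed && guard++ < guardMax) {
    changed = false;
    bfaces.clear();
    for (size_t ci = 0; ci < cavity.size(); ++ci) {
      int c = cavity[ci];
      const Tet& t = T.tets[c];
      for (int i = 0; i < 4; ++i) {
        int nb = t.adj[i];
        if (nb >= 0 && inCavity[nb]) continue;
        int f0 = t.v[(i + 1) % 4], f1 = t.v[(i + 2) % 4],
            f2 = t.v[(i + 3) % 4];
        double od = orient3d(T.P(f0), T.P(f1), T.P(f2), T.P(t.v[i]));
        double op = orient3d(T.P(f0), T.P(f1), T.P(f2), p);
        if (od * op <= 0) {
          if (nb >= 0 && T.tets[nb].alive) {
            inCavity[nb] = 1;
            cavity.push_back(nb);
            changed = true;
            break;
          }
          return false;  // wall on the outer boundary: cannot expand
        }
        bfaces.push_back({ f0, f1, f2, nb });
      }
      if (changed) break;
    }
  }
  if (changed || bfaces.empty()) return false;

  for (int c : cavity) T.tets[c].alive = false;

  // one new tetrahedron per boundary face
  std::unordered_map<uint64_t, std::pair<int, int>> open;  // face->(tet,slot)
  open.reserve(bfaces.size() * 3);
  int first = -1;
  for (const BFace& f : bfaces) {
    Tet nt;
    make_tet(T, nt, f.a, f.b, f.c, idx);
    int id = (int)T.tets.size();
    T.tets.push_back(nt);
    if (first < 0) first = id;
    Tet& t = T.tets[id];
    for (int i = 0; i < 4; ++i) {
      if (t.v[i] == idx) {
        // outer face: wire to the surviving neighbour and back
        t.adj[i] = f.outside;
        if (f.outside >= 0) {
          Tet& o = T.tets[f.outside];
          uint64_t key = face_key(f.a, f.b, f.c);
          for (int j = 0; j < 4; ++j) {
            int g0 = o.v[(j + 1) % 4], g1 = o.v[(j + 2) % 4],
                g2 = o.v[(j + 3) % 4];
            if (face_key(g0, g1, g2) == key) { o.adj[j] = id; break; }
          }
        }
      } else {
        // internal face (contains idx): pair up via hashing
        int g0 = t.v[(i + 1) % 4], g1 = t.v[(i + 2) % 4],
            g2 = t.v[(i + 3) % 4];
        uint64_t key = face_key(g0, g1, g2);
        auto it = open.find(key);
        if (it == open.end()) {
          open[key] = std::make_pair(id, i);
        } else {
          t.adj[i] = it->second.first;
          T.tets[it->second.first].adj[it->second.second] = id;
          open.erase(it);
        }
      }
    }
  }
  if (!open.empty()) return false;  // cavity boundary was not watertight
  hint = first;
  return true;
}

static bool build_delaunay(Triangulation& T, const NumericMatrix& pts,
                           double joggle) {
  int n = pts.nrow();
  T.n = n;
  T.pts.assign(n + 4, { 0.0, 0.0, 0.0 });
  double lo[3] = { R_PosInf, R_PosInf, R_PosInf };
  double hi[3] = { R_NegInf, R_NegInf, R_NegInf };
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j) + joggle * hash_noise(i + 1, j + 1);
      T.pts[i][j] = v;
      lo[j] = std::min(lo[j], v);
      hi[j] = std::max(hi[j], v);
    }
  }
  double ctr[3], diag = 0;
  for (int j = 0; j < 3; ++j) {
    ctr[j] = 0.5 * (lo[j] + hi[j]);
    diag += (hi[j] - lo[j]) * (hi[j] - lo[j]);
  }
  diag = std::sqrt(diag);
  double R = 100.0 * std::max(diag, 1.0);
  const double dirs[4][3] = { { 1, 1, 1 }, { 1, -1, -1 },
                              { -1, 1, -1 }, { -1, -1, 1 } };
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 3; ++j)
      T.pts[n + k][j] = ctr[j] + R * dirs[k][j] / std::sqrt(3.0);

  T.tets.clear();
  Tet super;
  make_tet(T, super, n, n + 1, n + 2, n + 3);
  T.tets.push_back(super);

  // calibrate the insphere sign convention: the super tetrahedron's
  // centroid is strictly inside its circumsphere
  T.inSign = 1.0;
  double cen[3] = { ctr[0], ctr[1], ctr[2] };
  double s = insphere_det(T.P(super.v[0]), T.P(super.v[1]),
                          T.P(super.v[2]), T.P(super.v[3]), cen);
  if (s < 0) T.inSign = -1.0;
  else if (s == 0) return false;

  // spatially sorted insertion order (coarse lexicographic grid cells)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int G = std::max(1, (int)std::floor(std::cbrt((double)n / 8.0)));
  std::vector<uint64_t> key(n);
  for (int i = 0; i < n; ++i) {
    uint64_t k = 0;
    for (int j = 0; j < 3; ++j) {
      double f = (hi[j] > lo[j]) ? (T.pts[i][j] - lo[j]) / (hi[j] - lo[j])
                                 : 0.5;
      int g = std::min(G - 1, (int)(f * G));
      k = k * (uint64_t)G + (uint64_t)g;
    }
    key[i] = k;
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return key[a] < key[b]; });

  int hint = 0;
  for (int i = 0; i < n; ++i) {
    if (!insert_point(T, order[i], hint)) return false;
    if (hint >= (int)T.tets.size()) hint = (int)T.tets.size() - 1;
  }

  // watertightness self-check on the joggled coordinates: the summed
  // volume of finite tetrahedra must equal the divergence-theorem volume
  // of the finite boundary
  double vTet = 0, vDiv = 0, scale3 = diag * diag * diag;
  for (const Tet& t : T.tets) {
    if (!t.alive) continue;
    bool finite = t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n;
    if (!finite) continue;
    vTet += tet_volume(T.P(t.v[0]), T.P(t.v[1]), T.P(t.v[2]), T.P(t.v[3]));
  }
  for (size_t k = 0; k < T.tets.size(); ++k) {
    const Tet& t = T.tets[k];
    if (!t.alive) continue;
    bool finite = t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n;
    if (!finite) continue;
    for (int i = 0; i < 4; ++i) {
      int nb = t.adj[i];
      bool nbFinite = false;
      if (nb >= 0 && T.tets[nb].alive) {
        const Tet& o = T.tets[nb];
        nbFinite = o.v[0] < n && o.v[1] < n && o.v[2] < n && o.v[3] < n;
      }
      if (nbFinite) continue;
      int f0 = t.v[(i + 1) % 4], f1 = t.v[(i + 2) % 4], f2 = t.v[(i + 3) % 4];
      // orient outward (away from the opposite vertex), then add the
      // signed origin-pyramid volume a . (b x c) / 6
      double od = orient3d(T.P(f0), T.P(f1), T.P(f2), T.P(t.v[i]));
      if (od > 0) std::swap(f1, f2);
      double bc[3];
      vcross(T.P(f1), T.P(f2), bc);
      vDiv += vdot(T.P(f0), bc) / 6.0;
    }
  }
  if (!(std::fabs(vTet - vDiv) <= 1e-9 * std::max(vTet, 1e-9 * scale3)))
    return false;
  return true;
}

// [[Rcpp::export]]
List cpp_delaunay(NumericMatrix pts, double joggle) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D triangulation");
  Triangulation T;
  double jog = (joggle > 0) ? joggle : 1e-4;
  bool ok = false;
  // escalate the joggle on the rare failure of the inexact predicates
  for (int attempt = 0; attempt < 4 && !ok; ++attempt) {
    ok = build_delaunay(T, pts, jog);
    if (!ok) jog *= 100.0;
  }
  if (!ok) stop("Delaunay triangulation failed (degenerate input?)");

  std::vector<int> keep;
  std::vector<int> newId(T.tets.size(), 0);
  for (size_t k = 0; k < T.tets.size(); ++k) {
    const Tet& t = T.tets[k];
    if (!t.alive) continue;
    if (t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n) {
      newId[k] = (int)keep.size() + 1;
      keep.push_back((int)k);
    }
  }
  int m = (int)keep.size();
  IntegerMatrix tets(m, 4), adj(m, 4);
  NumericVector radius(m), volume(m);
  NumericMatrix qpoints(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) qpoints(i, j) = T.pts[i][j];
  for (int r = 0; r < m; ++r) {
    const Tet& t = T.tets[keep[r]];
    for (int i = 0; i < 4; ++i) {
      tets(r, i) = t.v[i] + 1;
      adj(r, i) = (t.adj[i] >= 0) ? newId[t.adj[i]] : 0;
    }
    // circumradius on the joggled coordinates (the triangulation's own
    // geometry); metric volume on the originals
    double cc[3], r2;
    if (circumsphere(T.P(t.v[0]), T.P(t.v[1]), T.P(t.v[2]), T.P(t.v[3]),
                     cc, &r2)) {
      radius[r] = std::sqrt(r2);
    } else {
      radius[r] = R_PosInf;
    }
    double P[4][3];
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 3; ++j) P[i][j] = pts(t.v[i], j);
    volume[r] = tet_volume(P[0], P[1], P[2], P[3]);
  }
  return List::create(_["tets"] = tets, _["adj"] = adj,
                      _["radius"] = radius, _["volume"] = volume,
                      _["qpoints"] = qpoints, _["joggle"] = jog);
}

// ---------------------------------------------------------------------------
// boundary facets of a tetrahedron subset, oriented outward
// ---------------------------------------------------------------------------

// orientation decided on qpts (joggled); facet indices refer to the shared
// point numbering
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_facets(IntegerMatrix tets, IntegerMatrix adj,
                                  LogicalVector interior,
                                  NumericMatrix qpts) {
  int m = tets.nrow();
  std::vector<std::array<int, 3>> out;
  for (int t = 0; t < m; ++t) {
    if (!interior[t]) continue;
    for (int i = 0; i < 4; ++i) {
      int nb = adj(t, i);
      if (nb > 0 && interior[nb - 1]) continue;
      int f0 = tets(t, (i + 1) % 4), f1 = tets(t, (i + 2) % 4),
          f2 = tets(t, (i + 3) % 4);
      int vi = tets(t, i);
      double A[3], B[3], C[3], D[3];
      for (int j = 0; j < 3; ++j) {
        A[j] = qpts(f0 - 1, j); B[j] = qpts(f1 - 1, j);
        C[j] = qpts(f2 - 1, j); D[j] = qpts(vi - 1, j);
      }
      // outward: the tet's own vertex vi must lie on the negative side
      if (orient3d(A, B, C, D) > 0) std::swap(f1, f2);
      out.push_back({ f0, f1, f2 });
    }
  }
  IntegerMatrix res((int)out.size(), 3);
  for (size_t k = 0; k < out.size(); ++k)
    for (int j = 0; j < 3; ++j) res((int)k, j) = out[k][j];
  return res;
}

// ---------------------------------------------------------------------------
// point-to-triangle-mesh distances
// ---------------------------------------------------------------------------

// closest-point-on-triangle squared distance (Ericson, Real-Time Collision
// Detection, ch. 5)
static double tri_dist2(const double* p, const double* a, const double* b,
                        const double* c) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return vdot(ap, ap);
  double bp[3];
  vsub(p, b, bp);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return vdot(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    double q[3] = { a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2] };
    return dist2(p, q);
  }
  double cp[3];
  vsub(p, c, cp);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return vdot(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    double q[3] = { a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2] };
    return dist2(p, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = { b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                    b[2] + w * (c[2] - b[2]) };
    return dist2(p, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = { a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
                  a[2] + ab[2] * v + ac[2] * w };
  return dist2(p, q);
}

// minimum distance from each query point to a set of triangles, O(F) per
// query with a centroid-radius lower-bound cull
// [[Rcpp::export]]
NumericVector cpp_dist_to_facets(NumericMatrix query, NumericMatrix pts,
                                 IntegerMatrix facets) {
  int nq = query.nrow(), nf = facets.nrow();
  if (nf == 0) stop("mesh has no boundary facets");
  std::vector<double> fx(nf * 9), cen(nf * 3), rad(nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int v = facets(f, k) - 1;
      for (int j = 0; j < 3; ++j) fx[f * 9 + k * 3 + j] = pts(v, j);
    }
    double* c = &cen[f * 3];
    c[0] = c[1] = c[2] = 0;
    for (int k = 0; k < 3; ++k)
      for (int j = 0; j < 3; ++j) c[j] += fx[f * 9 + k * 3 + j] / 3.0;
    double r2 = 0;
    for (int k = 0; k < 3; ++k)
      r2 = std::max(r2, dist2(c, &fx[f * 9 + k * 3]));
    rad[f] = std::sqrt(r2);
  }
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double p[3] = { query(q, 0), query(q, 1), query(q, 2) };
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double dc = std::sqrt(dist2(p, &cen[f * 3])) - rad[f];
      if (dc > 0 && dc * dc >= best) continue;
      double d2 = tri_dist2(p, &fx[f * 9], &fx[f * 9 + 3], &fx[f * 9 + 6]);
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// maximum signed plane offset over outward-oriented facets; <= 0 inside
// (convex meshes only)
// [[Rcpp::export]]
NumericVector cpp_halfspace_offset(NumericMatrix query, NumericMatrix pts,
                                   IntegerMatrix facets) {
  int nq = query.nrow(), nf = facets.nrow();
  std::vector<double> nrm(nf * 3), off(nf);
  for (int f = 0; f < nf; ++f) {
    double A[3], B[3], C[3];
    for (int j = 0; j < 3; ++j) {
      A[j] = pts(facets(f, 0) - 1, j);
      B[j] = pts(facets(f, 1) - 1, j);
      C[j] = pts(facets(f, 2) - 1, j);
    }
    double ab[3], ac[3], nv[3];
    vsub(B, A, ab); vsub(C, A, ac); vcross(ab, ac, nv);
    double len = std::sqrt(vdot(nv, nv));
    if (len <= 0) len = 1;
    for (int j = 0; j < 3; ++j) nrm[f * 3 + j] = nv[j] / len;
    off[f] = vdot(&nrm[f * 3], A);
  }
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double p[3] = { query(q, 0), query(q, 1), query(q, 2) };
    double mx = R_NegInf;
    for (int f = 0; f < nf; ++f) {
      double d = vdot(&nrm[f * 3], p) - off[f];
      if (d > mx) mx = d;
    }
    out[q] = mx;
  }
  return out;
}

// ---------------------------------------------------------------------------
// point location in the (convex) finite Delaunay triangulation
// ---------------------------------------------------------------------------

// 1-based index of a tetrahedron containing each query point, 0 outside
// [[Rcpp::export]]
IntegerVector cpp_locate(NumericMatrix query, NumericMatrix pts,
                         IntegerMatrix tets, IntegerMatrix adj) {
  int nq = query.nrow(), m = tets.nrow();
  if (m == 0) stop("empty triangulation");
  IntegerVector out(nq);
  int hint = 0;
  for (int q = 0; q < nq; ++q) {
    double p[3] = { query(q, 0), query(q, 1), query(q, 2) };
    int cur = hint;
    int res = 0;
    int steps = 0, maxSteps = 4 * m + 64;
    while (steps++ < maxSteps) {
      int next = -2;
      for (int i = 0; i < 4; ++i) {
        double F[3][3], D[3];
        for (int j = 0; j < 3; ++j) {
          F[0][j] = pts(tets(cur, (i + 1) % 4) - 1, j);
          F[1][j] = pts(tets(cur, (i + 2) % 4) - 1, j);
          F[2][j] = pts(tets(cur, (i + 3) % 4) - 1, j);
          D[j] = pts(tets(cur, i) - 1, j);
        }
        double od = orient3d(F[0], F[1], F[2], D);
        double op = orient3d(F[0], F[1], F[2], p);
        if (od * op < 0) {
          next = adj(cur, i) - 1;
          break;
        }
      }
      if (next == -2) { res = cur + 1; break; }  // contained
      if (next == -1) { res = 0; break; }        // left the convex hull
      cur = next;
    }
    if (steps >= maxSteps) {
      res = 0;
      for (int t = 0; t < m && res == 0; ++t) {
        bool inside = true;
        for (int i = 0; i < 4 && inside; ++i) {
          double F[3][3], D[3];
          for (int j = 0; j < 3; ++j) {
            F[0][j] = pts(tets(t, (i + 1) % 4) - 1, j);
            F[1][j] = pts(tets(t, (i + 2) % 4) - 1, j);
            F[2][j] = pts(tets(t, (i + 3) % 4) - 1, j);
            D[j] = pts(tets(t, i) - 1, j);
          }
          double od = orient3d(F[0], F[1], F[2], D);
          double op = orient3d(F[0], F[1], F[2], p);
          if (od * op < 0) inside = false;
        }
        if (inside) res = t + 1;
      }
    }
    out[q] = res;
    if (res > 0) hint = res - 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// alpha-threshold scan
// ---------------------------------------------------------------------------

struct UnionFind {
  std::vector<int> parent, rank_;
  void init(int n) {
    parent.resize(n); rank_.assign(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) rank_[a]++;
    return true;
  }
};

// components and vertex coverage as tetrahedra are admitted in order of
// increasing circumradius
// [[Rcpp::export]]
List cpp_alpha_scan(IntegerMatrix tets, IntegerMatrix adj,
                    NumericVector radius, int nvert) {
  int m = tets.nrow();
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return radius[a] < radius[b]; });
  UnionFind uf; uf.init(m);
  std::vector<char> added(m, 0), seen(nvert, 0);
  int ncomp = 0, ncov = 0;
  NumericVector rOut(m);
  IntegerVector comps(m), covered(m);
  for (int k = 0; k < m; ++k) {
    int t = order[k];
    added[t] = 1;
    ncomp++;
    for (int i = 0; i < 4; ++i) {
      int nb = adj(t, i);
      if (nb > 0 && added[nb - 1]) {
        if (uf.unite(t, nb - 1)) ncomp--;
      }
      int v = tets(t, i) - 1;
      if (!seen[v]) { seen[v] = 1; ncov++; }
    }
    rOut[k] = radius[t];
    comps[k] = ncomp;
    covered[k] = ncov;
  }
  return List::create(_["radius"] = rOut, _["components"] = comps,
                      _["covered"] = covered);
}

// connected solid components of an interior tetrahedron subset
// [[Rcpp::export]]
IntegerVector cpp_tet_components(IntegerMatrix tets, IntegerMatrix adj,
                                 LogicalVector interior) {
  int m = tets.nrow();
  UnionFind uf; uf.init(m);
  for (int t = 0; t < m; ++t) {
    if (!interior[t]) continue;
    for (int i = 0; i < 4; ++i) {
      int nb = adj(t, i);
      if (nb > 0 && interior[nb - 1]) uf.unite(t, nb - 1);
    }
  }
  IntegerVector lab(m);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int t = 0; t < m; ++t) {
    if (!interior[t]) { lab[t] = 0; continue; }
    int r = uf.find(t);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[t] = next; }
    else lab[t] = it->second;
  }
  return lab;
}

// ---------------------------------------------------------------------------
// periodic single-linkage clustering (cell list + union-find)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(NumericMatrix pts, NumericVector box,
                                 double cutoff) {
  int n = pts.nrow();
  if (n == 0) return IntegerVector(0);
  double L[3] = { box[0], box[1], box[2] };
  std::vector<double> w(n * 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double x = pts(i, j);
      x -= L[j] * std::floor(x / L[j]);
      w[i * 3 + j] = x;
    }
  int nc[3];
  for (int j = 0; j < 3; ++j)
    nc[j] = std::min(64, std::max(1, (int)std::floor(L[j] / cutoff)));
  double cw[3];
  for (int j = 0; j < 3; ++j) cw[j] = L[j] / nc[j];
  int ncells = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int>> cells(ncells);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int j = 0; j < 3; ++j) {
      c[j] = (int)(w[i * 3 + j] / cw[j]);
      if (c[j] >= nc[j]) c[j] = nc[j] - 1;
    }
    cells[(c[2] * nc[1] + c[1]) * nc[0] + c[0]].push_back(i);
  }
  UnionFind uf; uf.init(n);
  double cut2 = cutoff * cutoff;
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int cid = (cz * nc[1] + cy) * nc[0] + cx;
        const std::vector<int>& A = cells[cid];
        if (A.empty()) continue;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ox = (cx + dx + nc[0]) % nc[0];
              int oy = (cy + dy + nc[1]) % nc[1];
              int oz = (cz + dz + nc[2]) % nc[2];
              int oid = (oz * nc[1] + oy) * nc[0] + ox;
              if (oid < cid) continue;  // each unordered cell pair once
              const std::vector<int>& B = cells[oid];
              for (int a : A)
                for (int b : B) {
                  if (oid == cid && b <= a) continue;
                  double d2 = 0;
                  for (int j = 0; j < 3; ++j) {
                    double d = w[a * 3 + j] - w[b * 3 + j];
                    d -= L[j] * std::round(d / L[j]);
                    d2 += d * d;
                  }
                  if (d2 <= cut2) uf.unite(a, b);
                }
            }
      }
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
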
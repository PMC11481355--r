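// Geometric core: incremental 3D Delaunay triangulation (Bowyer-Watson),
// vdW-weighted tangent spheres with empty-interior check, and
// Shrake-Rupley solvent-accessible surface areas.
//
// All coordinates are Cartesian angstroms. The triangulation applies a
// deterministic sub-microangstrom symbolic jitter so that exactly regular
// inputs (lattices) do not produce degenerate circumspheres; reported
// circumcenters therefore differ from the exact ones by < 1e-5 A.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef std::array<double, 3> P3;

static inline double d2(const P3 &a, const P3 &b) {
  const double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// deterministic hash -> uniform in [-1, 1]
static inline double hash_unit(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  x = x ^ (x >> 31);
  return 2.0 * (double)(x >> 11) / 9007199254740992.0 - 1.0;
}

struct Tet {
  int v[4];     // vertex indices
  int nb[4];    // neighbour opposite v[i], -1 if none
  double cc[3]; // circumcenter
  double r2;    // squared circumradius
  bool alive;
};

// 3x3 linear solve by Cramer's rule; returns false when near-singular
static bool solve3(const double A[3][3], const double b[3], double x[3]) {
  const double det =
      A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
      A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
      A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-9) return false;
  double M[3][3];
  M[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
  M[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) / det;
  M[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
  M[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) / det;
  M[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
  M[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) / det;
  M[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
  M[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) / det;
  M[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
  for (int i = 0; i < 3; ++i)
    x[i] = M[i][0] * b[0] + M[i][1] * b[1] + M[i][2] * b[2];
  return true;
}

static bool circumsphere(const std::vector<P3> &P, int a, int b, int c, int d,
                         double cc[3], double &r2) {
  double A[3][3], rhs[3];
  const P3 &pa = P[a];
  const int idx[3] = {b, c, d};
  const double na = pa[0] * pa[0] + pa[1] * pa[1] + pa[2] * pa[2];
  for (int i = 0; i < 3; ++i) {
    const P3 &p = P[idx[i]];
    for (int j = 0; j < 3; ++j) A[i][j] = 2.0 * (p[j] - pa[j]);
    rhs[i] = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] - na;
  }
  if (!solve3(A, rhs, cc)) return false;
  P3 ccp = {cc[0], cc[1], cc[2]};
  r2 = d2(ccp, pa);
  return true;
}

// [[Rcpp::export]]
List delaunay3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("delaunay3d: need at least 4 points");

  std::vector<P3> P((size_t)n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j) + 1e-6 * hash_unit((uint64_t)(i * 3 + j));
      P[i][j] = v;
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  }
  double m[3], R = 1.0;
  for (int j = 0; j < 3; ++j) {
    m[j] = 0.5 * (lo[j] + hi[j]);
    R = std::max(R, hi[j] - lo[j]);
  }
  const double S = 1000.0 * R;
  const double dirs[4][3] = {{1, 1, 1}, {1, -1, -1}, {-1, 1, -1}, {-1, -1, 1}};
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 3; ++j)
      P[n + k][j] = m[j] + S * dirs[k][j] / std::sqrt(3.0);

  std::vector<Tet> T;
  T.reserve((size_t)8 * n + 16);
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    for (int i = 0; i < 4; ++i) t0.nb[i] = -1;
    if (!circumsphere(P, t0.v[0], t0.v[1], t0.v[2], t0.v[3], t0.cc, t0.r2))
      stop("delaunay3d: degenerate bounding tetrahedron");
    t0.alive = true;
    T.push_back(t0);
  }

  std::vector<int> stack, cavity, bface_t, bface_i;
  std::vector<char> incav;

  for (int ip = 0; ip < n; ++ip) {
    const P3 &p = P[ip];
    // seed: any live tet whose circumsphere contains p (linear scan,
    // newest first -- spatial locality of lattice-ish inputs makes this fast)
    int seed = -1;
    for (int t = (int)T.size() - 1; t >= 0; --t) {
      if (!T[t].alive) continue;
      P3 cc = {T[t].cc[0], T[t].cc[1], T[t].cc[2]};
      if (d2(p, cc) < T[t].r2 - 1e-9) { seed = t; break; }
    }
    if (seed < 0) stop("delaunay3d: insertion point outside triangulation");

    // carve cavity by BFS over in-circumsphere tets
    cavity.clear();
    incav.assign(T.size(), 0);
    stack.clear();
    stack.push_back(seed);
    incav[seed] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int f = 0; f < 4; ++f) {
        int u = T[t].nb[f];
        if (u < 0 || incav[u] || !T[u].alive) continue;
        P3 cc = {T[u].cc[0], T[u].cc[1], T[u].cc[2]};
        if (d2(p, cc) < T[u].r2 - 1e-9) { incav[u] = 1; stack.push_back(u); }
      }
    }
    // boundary faces
    bface_t.clear(); bface_i.clear();
    for (size_t k = 0; k < cavity.size(); ++k) {
      int t = cavity[k];
      for (int f = 0; f < 4; ++f) {
        int u = T[t].nb[f];
        if (u < 0 || !incav[u]) { bface_t.push_back(t); bface_i.push_back(f); }
      }
      T[t].alive = false;
    }
    // retriangulate: new tet per boundary face; side faces matched by
    // shared edge (the inserted point is common to all side faces)
    std::unordered_map<uint64_t, std::pair<int, int>> edge_map;
    std::vector<int> created;
    for (size_t k = 0; k < bface_t.size(); ++k) {
      int t = bface_t[k], f = bface_i[k];
      int fv[3]; int c = 0;
      for (int j = 0; j < 4; ++j) if (j != f) fv[c++] = T[t].v[j];
      Tet nt;
      nt.v[0] = ip; nt.v[1] = fv[0]; nt.v[2] = fv[1]; nt.v[3] = fv[2];
      int outside = T[t].nb[f];
      nt.nb[0] = outside;
      nt.nb[1] = nt.nb[2] = nt.nb[3] = -1;
      if (!circumsphere(P, nt.v[0], nt.v[1], nt.v[2], nt.v[3], nt.cc, nt.r2))
        stop("delaunay3d: degenerate tetrahedron during insertion");
      nt.alive = true;
      int ti = (int)T.size();
      T.push_back(nt);
      created.push_back(ti);
      if (outside >= 0) { // repoint the outside tet at the new one
        for (int g = 0; g < 4; ++g)
          if (T[outside].nb[g] == t) { T[outside].nb[g] = ti; break; }
      }
      // side faces: opposite fv[j] is (ip, other two) keyed by that edge
      for (int j = 1; j <= 3; ++j) {
        int e1 = nt.v[j == 1 ? 2 : 1];
        int e2 = nt.v[j == 3 ? 2 : 3];
        if (e1 > e2) std::swap(e1, e2);
        uint64_t key = ((uint64_t)(uint32_t)e1 << 32) | (uint32_t)e2;
        auto it = edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = std::make_pair(ti, j);
        } else {
          T[ti].nb[j] = it->second.first;
          T[it->second.first].nb[it->second.second] = ti;
          edge_map.erase(it);
        }
      }
    }
    if (!edge_map.empty())
      stop("delaunay3d: cavity boundary not closed (degenerate input)");
  }

  // keep tets with no super vertex; remap indices (1-based for R)
  std::vector<int> newid(T.size(), 0);
  int nk = 0;
  for (size_t t = 0; t < T.size(); ++t) {
    if (!T[t].alive) continue;
    bool super = false;
    for (int j = 0; j < 4; ++j) if (T[t].v[j] >= n) super = true;
    if (!super) newid[t] = ++nk;
  }
  IntegerMatrix tets(nk, 4), adj(nk, 4);
  NumericMatrix circ(nk, 3);
  NumericVector cr(nk);
  for (size_t t = 0; t < T.size(); ++t) {
    int id = newid[t];
    if (id == 0) continue;
    for (int j = 0; j < 4; ++j) {
      tets(id - 1, j) = T[t].v[j] + 1;
      int u = T[t].nb[j];
      adj(id - 1, j) = (u >= 0 && T[u].alive) ? newid[u] : 0;
    }
    for (int j = 0; j < 3; ++j) circ(id - 1, j) = T[t].cc[j];
    cr[id - 1] = std::sqrt(T[t].r2);
  }
  return List::create(_["tets"] = tets, _["adj"] = adj,
                      _["circ"] = circ, _["circ_r"] = cr);
}

// ---------------------------------------------------------------------------
// uniform cell grid for fixed-radius neighbour queries

struct Grid {
  double lo[3], cell;
  int dim[3];
  std::vector<std::vector<int>> bins;
  const NumericMatrix *pts;

  void build(const NumericMatrix &p, double cell_size) {
    pts = &p;
    cell = cell_size;
    double hi[3];
    for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
    for (int i = 0; i < p.nrow(); ++i)
      for (int j = 0; j < 3; ++j) {
        lo[j] = std::min(lo[j], p(i, j));
        hi[j] = std::max(hi[j], p(i, j));
      }
    for (int j = 0; j < 3; ++j)
      dim[j] = std::max(1, (int)std::floor((hi[j] - lo[j]) / cell) + 1);
    bins.assign((size_t)dim[0] * dim[1] * dim[2], {});
    for (int i = 0; i < p.nrow(); ++i) bins[index_of(p(i, 0), p(i, 1), p(i, 2))].push_back(i);
  }
  inline int clampi(int v, int n) const { return v < 0 ? 0 : (v >= n ? n - 1 : v); }
  inline size_t index_of(double x, double y, double z) const {
    int ix = clampi((int)std::floor((x - lo[0]) / cell), dim[0]);
    int iy = clampi((int)std::floor((y - lo[1]) / cell), dim[1]);
    int iz = clampi((int)std::floor((z - lo[2]) / cell), dim[2]);
    return ((size_t)ix * dim[1] + iy) * dim[2] + iz;
  }
  template <typename F>
  void visit(double x, double y, double z, double radius, F f) const {
    int c0[3], c1[3];
    const double q[3] = {x, y, z};
    for (int j = 0; j < 3; ++j) {
      c0[j] = clampi((int)std::floor((q[j] - radius - lo[j]) / cell), dim[j]);
      c1[j] = clampi((int)std::floor((q[j] + radius - lo[j]) / cell), dim[j]);
    }
    for (int ix = c0[0]; ix <= c1[0]; ++ix)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int iz = c0[2]; iz <= c1[2]; ++iz) {
          const std::vector<int> &b = bins[((size_t)ix * dim[1] + iy) * dim[2] + iz];
          for (size_t k = 0; k < b.size(); ++k) f(b[k]);
        }
  }
};

// Tangent sphere of four vdW spheres: |c - a_i| = r + w_i. Returns all real
// solutions with r in [rmin, rmax] whose interior contains no other atom
// (to tolerance `tol`). `quads` is 1-based.
// [[Rcpp::export]]
List tangent_spheres_cpp(NumericMatrix pts, NumericVector vdw,
                         IntegerMatrix quads, double rmin, double rmax,
                         double tol = 1e-6) {
  const int nq = quads.nrow();
  double wmax = 0.0;
  for (int i = 0; i < vdw.size(); ++i) wmax = std::max(wmax, vdw[i]);
  Grid grid;
  grid.build(pts, std::max(2.0, rmax + wmax));

  std::vector<double> cx, cy, cz, rr;
  std::vector<int> qi;
  int n_degenerate = 0;
  for (int q = 0; q < nq; ++q) {
    int a[4];
    for (int j = 0; j < 4; ++j) a[j] = quads(q, j) - 1;
    double A[3][3], b0[3], b1[3];
    const double *p0 = &pts(a[0], 0);
    double pa[3] = {pts(a[0], 0), pts(a[0], 1), pts(a[0], 2)};
    (void)p0;
    const double w0 = vdw[a[0]];
    const double na = pa[0] * pa[0] + pa[1] * pa[1] + pa[2] * pa[2];
    for (int i = 0; i < 3; ++i) {
      int ai = a[i + 1];
      double pi_[3] = {pts(ai, 0), pts(ai, 1), pts(ai, 2)};
      double wi = vdw[ai];
      for (int j = 0; j < 3; ++j) A[i][j] = 2.0 * (pi_[j] - pa[j]);
      b0[i] = pi_[0] * pi_[0] + pi_[1] * pi_[1] + pi_[2] * pi_[2] - na -
              (wi * wi - w0 * w0);
      b1[i] = -2.0 * (wi - w0);
    }
    double c0[3], c1[3];
    if (!solve3(A, b0, c0)) { ++n_degenerate; continue; } // coplanar, skipped
    if (!solve3(A, b1, c1)) { ++n_degenerate; continue; }
    // |c0 + r c1 - pa|^2 = (r + w0)^2
    double dvec[3] = {c0[0] - pa[0], c0[1] - pa[1], c0[2] - pa[2]};
    const double qa = c1[0] * c1[0] + c1[1] * c1[1] + c1[2] * c1[2] - 1.0;
    const double qb = 2.0 * (dvec[0] * c1[0] + dvec[1] * c1[1] + dvec[2] * c1[2] - w0);
    const double qc = dvec[0] * dvec[0] + dvec[1] * dvec[1] + dvec[2] * dvec[2] - w0 * w0;
    double roots[2]; int nroots = 0;
    if (std::fabs(qa) < 1e-12) {
      if (std::fabs(qb) > 1e-12) roots[nroots++] = -qc / qb;
    } else {
      const double disc = qb * qb - 4.0 * qa * qc;
      if (disc >= 0.0) {
        const double sq = std::sqrt(disc);
        roots[nroots++] = (-qb - sq) / (2.0 * qa);
        roots[nroots++] = (-qb + sq) / (2.0 * qa);
      }
    }
    for (int s = 0; s < nroots; ++s) {
      const double r = roots[s];
      if (!(r >= rmin && r <= rmax)) continue;
      const double c[3] = {c0[0] + r * c1[0], c0[1] + r * c1[1], c0[2] + r * c1[2]};
      bool empty = true;
      grid.visit(c[0], c[1], c[2], r + wmax, [&](int j) {
        if (!empty) return;
        if (j == a[0] || j == a[1] || j == a[2] || j == a[3]) return;
        const double dx = c[0] - pts(j, 0), dy = c[1] - pts(j, 1), dz = c[2] - pts(j, 2);
        const double lim = r + vdw[j] - tol;
        if (dx * dx + dy * dy + dz * dz < lim * lim) empty = false;
      });
      if (!empty) continue;
      cx.push_back(c[0]); cy.push_back(c[1]); cz.push_back(c[2]);
      rr.push_back(r); qi.push_back(q + 1);
    }
  }
  const int m = (int)rr.size();
  NumericMatrix centers(m, 3);
  NumericVector radius(m);
  IntegerVector quad(m);
  for (int i = 0; i < m; ++i) {
    centers(i, 0) = cx[i]; centers(i, 1) = cy[i]; centers(i, 2) = cz[i];
    radius[i] = rr[i]; quad[i] = qi[i];
  }
  return List::create(_["center"] = centers, _["radius"] = radius,
                      _["quad"] = quad, _["n_degenerate"] = n_degenerate);
}

// Shrake-Rupley SASA with a deterministic golden-spiral point set.
// [[Rcpp::export]]
NumericVector shrake_rupley_cpp(NumericMatrix pts, NumericVector radii,
                                double probe = 1.4, int n_points = 256) {
  const int n = pts.nrow();
  NumericVector area(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  Grid grid;
  grid.build(pts, std::max(2.0, 2.0 * (rmax + probe)));

  std::vector<P3> dirs(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double y = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double rad = std::sqrt(std::max(0.0, 1.0 - y * y));
    const double th = golden * k;
    dirs[k] = {rad * std::cos(th), y, rad * std::sin(th)};
  }

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    const double ci[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    nbr.clear();
    grid.visit(ci[0], ci[1], ci[2], Ri + rmax + probe, [&](int j) {
      if (j == i) return;
      const double Rj = radii[j] + probe;
      const double dx = ci[0] - pts(j, 0), dy = ci[1] - pts(j, 1), dz = ci[2] - pts(j, 2);
      if (dx * dx + dy * dy + dz * dz < (Ri + Rj) * (Ri + Rj)) nbr.push_back(j);
    });
    int freect = 0;
    for (int k = 0; k < n_points; ++k) {
      const double q[3] = {ci[0] + Ri * dirs[k][0], ci[1] + Ri * dirs[k][1],
                           ci[2] + Ri * dirs[k][2]};
      bool freep = true;
      for (size_t t = 0; t < nbr.size(); ++t) {
        const int j = nbr[t];
        const double Rj = radii[j] + probe;
        const double dx = q[0] - pts(j, 0), dy = q[1] - pts(j, 1), dz = q[2] - pts(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { freep = false; break; }
      }
      if (freep) ++freect;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)freect / n_points;
  }
  return area;
}
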
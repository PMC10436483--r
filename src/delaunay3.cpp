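// 3D Delaunay triangulation: incremental Bowyer-Watson with a symbolic
// infinite ("ghost") vertex covering the outside of the convex hull.
// Points are inserted in Morton order; the conflict region is grown by BFS
// and repaired (enlarged) whenever a would-be new tetrahedron is flat or
// inverted.  Unrecoverable near-degeneracies trigger a deterministic
// joggle-and-retry with increasing magnitude.

#include <Rcpp.h>

#include <cstdint>
#include <stdexcept>
#include <unordered_map>
#include <vector>

#include "predicates.h"

namespace {

constexpr int INF = -1;

struct Tet {
  int v[4];
  int nb[4];  // neighbour opposite v[i]
};

// canonical outward-face slot tables: face f_i of (v0,v1,v2,v3) has the
// remaining vertex v_i on its positive side when the tet is positively
// oriented
const int FACE[4][3] = {{1, 3, 2}, {0, 2, 3}, {0, 3, 1}, {0, 1, 2}};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct geom_failure : std::runtime_error {
  geom_failure(const char* w) : std::runtime_error(w) {}
};

class Delaunay3 {
 public:
  std::vector<double> pts;  // 3n
  int n;
  std::vector<Tet> tets;
  std::vector<char> alive;
  std::vector<uint32_t> mark;
  std::vector<int> freelist;
  uint32_t epoch = 0;
  int hint = 0;

  const double* P(int i) const { return &pts[3 * (size_t)i]; }
  bool ghost(const Tet& t) const {
    return t.v[0] == INF || t.v[1] == INF || t.v[2] == INF || t.v[3] == INF;
  }

  int alloc(int a, int b, int c, int d) {
    int id;
    if (!freelist.empty()) {
      id = freelist.back();
      freelist.pop_back();
    } else {
      id = (int)tets.size();
      tets.push_back(Tet());
      alive.push_back(0);
      mark.push_back(0);
    }
    Tet& t = tets[id];
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
    alive[id] = 1;
    mark[id] = 0;
    return id;
  }

  // does point p lie inside the circumdisk of coplanar triangle (a,b,c)?
  bool in_circumdisk(const double* a, const double* b, const double* c,
                     const double* p) const {
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double w[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double nrm[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                     u[0] * w[1] - u[1] * w[0]};
    double v2[3] = {nrm[1] * u[2] - nrm[2] * u[1], nrm[2] * u[0] - nrm[0] * u[2],
                    nrm[0] * u[1] - nrm[1] * u[0]};
    double lu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    double lv = std::sqrt(v2[0] * v2[0] + v2[1] * v2[1] + v2[2] * v2[2]);
    if (lu == 0 || lv == 0) return false;
    auto proj = [&](const double* x, double* out) {
      double d[3] = {x[0] - a[0], x[1] - a[1], x[2] - a[2]};
      out[0] = (d[0] * u[0] + d[1] * u[1] + d[2] * u[2]) / lu;
      out[1] = (d[0] * v2[0] + d[1] * v2[1] + d[2] * v2[2]) / lv;
    };
    double A[2], B[2], C[2], E[2];
    proj(a, A); proj(b, B); proj(c, C); proj(p, E);
    int s = vc::orient2d(A, B, C);
    if (s == 0) return false;
    int ic = vc::incircle2d(A, B, C, E);
    return s > 0 ? ic > 0 : ic < 0;
  }

  bool conflict(int ti, const double* p) const {
    const Tet& t = tets[ti];
    int k = -1;
    for (int i = 0; i < 4; ++i)
      if (t.v[i] == INF) { k = i; break; }
    if (k < 0)
      return vc::insphere(P(t.v[0]), P(t.v[1]), P(t.v[2]), P(t.v[3]), p) > 0;
    const double* w0 = P(t.v[FACE[k][0]]);
    const double* w1 = P(t.v[FACE[k][1]]);
    const double* w2 = P(t.v[FACE[k][2]]);
    int s = vc::orient3d(w0, w1, w2, p);
    if (s > 0) return true;
    if (s < 0) return false;
    return in_circumdisk(w0, w1, w2, p);
  }

  int locate_conflict(const double* p) {
    int t = alive[hint] ? hint : -1;
    if (t < 0)
      for (size_t i = 0; i < tets.size(); ++i)
        if (alive[i]) { t = (int)i; break; }
    size_t limit = 4 * tets.size() + 64;
    for (size_t steps = 0; steps < limit; ++steps) {
      const Tet& T = tets[t];
      if (ghost(T)) {
        if (conflict(t, p)) return t;
        // step back inside through the real facet and keep walking
        int k = 0;
        while (T.v[k] != INF) ++k;
        int in = T.nb[k];
        if (in < 0 || !alive[in] || ghost(tets[in])) break;
        t = in;
        continue;
      }
      bool moved = false;
      for (int j = 0; j < 4; ++j) {
        int i = (int)((j + steps) & 3);
        const double* f0 = P(T.v[FACE[i][0]]);
        const double* f1 = P(T.v[FACE[i][1]]);
        const double* f2 = P(T.v[FACE[i][2]]);
        if (vc::orient3d(f0, f1, f2, p) < 0) {
          int nt = T.nb[i];
          if (nt < 0 || !alive[nt]) continue;
          if (ghost(tets[nt])) {
            if (conflict(nt, p)) return nt;
            continue;
          }
          t = nt;
          moved = true;
          break;
        }
      }
      if (!moved) {
        if (conflict(t, p)) return t;
        break;
      }
    }
    // exhaustive fallback (degenerate walks only)
    for (size_t i = 0; i < tets.size(); ++i)
      if (alive[i] && conflict((int)i, p)) return (int)i;
    throw geom_failure("no conflicting cell found");
  }

  void insert(int pid) {
    const double* p = P(pid);
    int seed = locate_conflict(p);
    ++epoch;
    std::vector<int> cav;
    std::vector<int> stack{seed};
    mark[seed] = epoch;
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      cav.push_back(t);
      for (int i = 0; i < 4; ++i) {
        int nb = tets[t].nb[i];
        if (nb < 0 || mark[nb] == epoch) continue;
        if (conflict(nb, p)) {
          mark[nb] = epoch;
          stack.push_back(nb);
        }
      }
    }
    // collect boundary, enlarging the cavity while some new tet would be
    // flat/inverted
    std::vector<std::pair<int, int>> boundary;
    for (size_t guard = 0; guard <= tets.size(); ++guard) {
      boundary.clear();
      bool bad = false;
      for (size_t ci = 0; ci < cav.size(); ++ci) {
        int t = cav[ci];
        for (int i = 0; i < 4; ++i) {
          int nb = tets[t].nb[i];
          if (nb >= 0 && mark[nb] == epoch) continue;
          int w0 = tets[t].v[FACE[i][0]];
          int w1 = tets[t].v[FACE[i][1]];
          int w2 = tets[t].v[FACE[i][2]];
          if (w0 != INF && w1 != INF && w2 != INF &&
              vc::orient3d(P(w0), P(w1), P(w2), p) <= 0) {
            if (nb < 0) throw geom_failure("cavity spilled past hull");
            mark[nb] = epoch;
            cav.push_back(nb);
            bad = true;
          } else {
            boundary.push_back({t, i});
          }
        }
      }
      if (!bad) break;
      if (guard == tets.size()) throw geom_failure("cavity repair diverged");
    }
    if (boundary.empty()) throw geom_failure("empty cavity boundary");
    // build new tets
    std::unordered_map<uint64_t, std::pair<int, int>> open;
    open.reserve(2 * boundary.size());
    int last = -1;
    for (auto& bf : boundary) {
      int t = bf.first, i = bf.second;
      int w[3] = {tets[t].v[FACE[i][0]], tets[t].v[FACE[i][1]],
                  tets[t].v[FACE[i][2]]};
      int L = tets[t].nb[i];
      int nt = alloc(w[0], w[1], w[2], pid);
      tets[nt].nb[3] = L;
      if (L >= 0) {
        for (int j = 0; j < 4; ++j)
          if (tets[L].nb[j] == t) { tets[L].nb[j] = nt; break; }
      }
      for (int s = 0; s < 3; ++s) {
        int a = w[(s + 1) % 3], b = w[(s + 2) % 3];
        if (a > b) std::swap(a, b);
        uint64_t key =
            ((uint64_t)(uint32_t)(a + 2) << 32) | (uint32_t)(b + 2);
        auto it = open.find(key);
        if (it == open.end()) {
          open[key] = {nt, s};
        } else {
          tets[nt].nb[s] = it->second.first;
          tets[it->second.first].nb[it->second.second] = nt;
          open.erase(it);
        }
      }
      if (last < 0 || (w[0] != INF && w[1] != INF && w[2] != INF)) last = nt;
    }
    if (!open.empty()) throw geom_failure("unmatched cavity faces");
    for (int t : cav) {
      alive[t] = 0;
      freelist.push_back(t);
    }
    hint = last;
  }

  void build(const std::vector<int>& order) {
    // initial tet: first 4 affinely independent points in insertion order
    int i0 = order[0], i1 = -1, i2 = -1, i3 = -1;
    size_t k = 1;
    for (; k < order.size(); ++k) {
      int c = order[k];
      if (P(c)[0] != P(i0)[0] || P(c)[1] != P(i0)[1] || P(c)[2] != P(i0)[2]) {
        i1 = c;
        ++k;
        break;
      }
    }
    if (i1 < 0) throw geom_failure("degenerate: all points coincide");
    for (; k < order.size(); ++k) {
      int c = order[k];
      long double u0 = (long double)P(i1)[0] - P(i0)[0],
                  u1 = (long double)P(i1)[1] - P(i0)[1],
                  u2 = (long double)P(i1)[2] - P(i0)[2];
      long double w0 = (long double)P(c)[0] - P(i0)[0],
                  w1 = (long double)P(c)[1] - P(i0)[1],
                  w2 = (long double)P(c)[2] - P(i0)[2];
      long double c0 = u1 * w2 - u2 * w1, c1 = u2 * w0 - u0 * w2,
                  c2 = u0 * w1 - u1 * w0;
      if (c0 != 0 || c1 != 0 || c2 != 0) {
        i2 = c;
        ++k;
        break;
      }
    }
    if (i2 < 0) throw geom_failure("degenerate: all points collinear");
    for (; k < order.size(); ++k) {
      int c = order[k];
      int s = vc::orient3d(P(i0), P(i1), P(i2), P(c));
      if (s != 0) {
        if (s < 0) std::swap(i1, i2);
        i3 = c;
        break;
      }
    }
    if (i3 < 0) throw geom_failure("degenerate: all points coplanar");

    int t0 = alloc(i0, i1, i2, i3);
    int g[4];
    for (int i = 0; i < 4; ++i) {
      int w0 = tets[t0].v[FACE[i][0]], w1 = tets[t0].v[FACE[i][1]],
          w2 = tets[t0].v[FACE[i][2]];
      g[i] = alloc(w1, w0, w2, INF);  // reversed face + INF
      tets[g[i]].nb[3] = t0;
      tets[t0].nb[i] = g[i];
    }
    // link ghost-ghost faces by shared real edge
    std::unordered_map<uint64_t, std::pair<int, int>> open;
    for (int i = 0; i < 4; ++i) {
      for (int s = 0; s < 3; ++s) {
        int a = tets[g[i]].v[(s + 1) % 3], b = tets[g[i]].v[(s + 2) % 3];
        if (a > b) std::swap(a, b);
        uint64_t key =
            ((uint64_t)(uint32_t)(a + 2) << 32) | (uint32_t)(b + 2);
        auto it = open.find(key);
        if (it == open.end()) {
          open[key] = {g[i], s};
        } else {
          tets[g[i]].nb[s] = it->second.first;
          tets[it->second.first].nb[it->second.second] = g[i];
          open.erase(it);
        }
      }
    }
    if (!open.empty()) throw geom_failure("initial hull linking failed");
    hint = t0;
    for (size_t m = 1; m < order.size(); ++m) {
      int c = order[m];
      if (c == i1 || c == i2 || c == i3) continue;
      insert(c);
    }
  }
};

std::vector<int> morton_order(const std::vector<double>& pts, int n) {
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = pts[3 * (size_t)i + d];
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  std::vector<uint64_t> key(n);
  for (int i = 0; i < n; ++i) {
    uint64_t code = 0;
    for (int d = 0; d < 3; ++d) {
      double span = hi[d] - lo[d];
      double f = span > 0 ? (pts[3 * (size_t)i + d] - lo[d]) / span : 0.0;
      uint64_t q = (uint64_t)(f * 2097151.0);  // 21 bits
      // interleave
      uint64_t x = q;
      x = (x | (x << 32)) & 0x1f00000000ffffULL;
      x = (x | (x << 16)) & 0x1f0000ff0000ffULL;
      x = (x | (x << 8)) & 0x100f00f00f00f00fULL;
      x = (x | (x << 4)) & 0x10c30c30c30c30c3ULL;
      x = (x | (x << 2)) & 0x1249249249249249ULL;
      code |= x << d;
    }
    key[i] = code;
  }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return key[a] < key[b]; });
  return ord;
}

}  // namespace

// [[Rcpp::export(name = ".dt3_build")]]
Rcpp::List dt3_build(Rcpp::NumericMatrix coords) {
  int n = coords.nrow();
  if (coords.ncol() != 3) Rcpp::stop("coords must have 3 columns");
  std::vector<double> base(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) base[3 * (size_t)i + d] = coords(i, d);
  double diag = 0;
  {
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = base[3 * (size_t)i + d];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    for (int d = 0; d < 3; ++d)
      diag += (hi[d] - lo[d]) * (hi[d] - lo[d]);
    diag = std::sqrt(diag);
    if (diag == 0) diag = 1.0;
  }
  std::vector<int> order = morton_order(base, n);
  const double jog[4] = {0.0, 1e-10, 1e-8, 1e-6};
  std::string lasterr;
  for (int attempt = 0; attempt < 4; ++attempt) {
    Delaunay3 D;
    D.n = n;
    D.pts = base;
    if (attempt > 0) {
      double mag = jog[attempt] * diag;
      for (size_t i = 0; i < D.pts.size(); ++i) {
        uint64_t h = splitmix64(i * 4u + (uint64_t)attempt);
        double u = (double)(h >> 11) * (1.0 / 9007199254740992.0);  // [0,1)
        D.pts[i] += (2.0 * u - 1.0) * mag;
      }
    }
    try {
      D.build(order);
    } catch (const geom_failure& e) {
      lasterr = e.what();
      if (attempt == 3 ||
          std::string(e.what()).find("degenerate") != std::string::npos)
        Rcpp::stop("Delaunay construction failed: %s", e.what());
      continue;
    }
    // finalize
    std::vector<int> finite;
    finite.reserve(D.tets.size());
    for (size_t i = 0; i < D.tets.size(); ++i)
      if (D.alive[i] && !D.ghost(D.tets[i])) finite.push_back((int)i);
    size_t m = finite.size();
    Rcpp::IntegerMatrix simp((int)m, 4);
    for (size_t s = 0; s < m; ++s)
      for (int j = 0; j < 4; ++j) simp((int)s, j) = D.tets[finite[s]].v[j] + 1;
    // one-ring adjacency from finite simplices
    std::vector<std::vector<int>> nbr(n);
    for (size_t s = 0; s < m; ++s) {
      const Tet& t = D.tets[finite[s]];
      for (int a = 0; a < 4; ++a)
        for (int b = a + 1; b < 4; ++b) {
          int p = t.v[a], q = t.v[b];
          bool have = false;
          for (int x : nbr[p])
            if (x == q) { have = true; break; }
          if (!have) {
            nbr[p].push_back(q);
            nbr[q].push_back(p);
          }
        }
    }
    size_t tot = 0;
    for (int i = 0; i < n; ++i) {
      std::sort(nbr[i].begin(), nbr[i].end());
      tot += nbr[i].size();
    }
    Rcpp::IntegerVector start(n + 1), idx((R_xlen_t)tot);
    R_xlen_t pos = 0;
    for (int i = 0; i < n; ++i) {
      start[i] = (int)(pos + 1);
      for (int x : nbr[i]) idx[pos++] = x + 1;
    }
    start[n] = (int)(pos + 1);
    return Rcpp::List::create(
        Rcpp::Named("simplices") = simp, Rcpp::Named("ring_start") = start,
        Rcpp::Named("ring_idx") = idx, Rcpp::Named("joggle_attempt") = attempt,
        Rcpp::Named("n") = n);
  }
  Rcpp::stop("Delaunay construction failed: %s", lasterr.c_str());
}
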
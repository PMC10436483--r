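// 2D Delaunay triangulation: incremental Bowyer-Watson with a ghost vertex,
// mirroring the 3D implementation (Morton insertion order, filtered
// predicates, cavity repair, deterministic joggle retry).

#include <Rcpp.h>

#include <cstdint>
#include <stdexcept>
#include <unordered_map>
#include <vector>

#include "predicates.h"

namespace {

constexpr int INF = -1;

struct Tri {
  int v[3];
  int nb[3];
};

const int FACE2[3][2] = {{1, 2}, {2, 0}, {0, 1}};

inline uint64_t splitmix64_2(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct geom_failure2 : std::runtime_error {
  geom_failure2(const char* w) : std::runtime_error(w) {}
};

class Delaunay2 {
 public:
  std::vector<double> pts;  // 2n
  int n;
  std::vector<Tri> tris;
  std::vector<char> alive;
  std::vector<uint32_t> mark;
  std::vector<int> freelist;
  uint32_t epoch = 0;
  int hint = 0;

  const double* P(int i) const { return &pts[2 * (size_t)i]; }
  bool ghost(const Tri& t) const {
    return t.v[0] == INF || t.v[1] == INF || t.v[2] == INF;
  }

  int alloc(int a, int b, int c) {
    int id;
    if (!freelist.empty()) {
      id = freelist.back();
      freelist.pop_back();
    } else {
      id = (int)tris.size();
      tris.push_back(Tri());
      alive.push_back(0);
      mark.push_back(0);
    }
    Tri& t = tris[id];
    t.v[0] = a; t.v[1] = b; t.v[2] = c;
    t.nb[0] = t.nb[1] = t.nb[2] = -1;
    alive[id] = 1;
    mark[id] = 0;
    return id;
  }

  bool conflict(int ti, const double* p) const {
    const Tri& t = tris[ti];
    int k = -1;
    for (int i = 0; i < 3; ++i)
      if (t.v[i] == INF) { k = i; break; }
    if (k < 0)
      return vc::incircle2d(P(t.v[0]), P(t.v[1]), P(t.v[2]), p) > 0;
    const double* a = P(t.v[FACE2[k][0]]);
    const double* b = P(t.v[FACE2[k][1]]);
    int s = vc::orient2d(a, b, p);
    if (s > 0) return true;
    if (s < 0) return false;
    long double ux = (long double)b[0] - a[0], uy = (long double)b[1] - a[1];
    long double tt = ((long double)p[0] - a[0]) * ux +
                     ((long double)p[1] - a[1]) * uy;
    return tt > 0 && tt < ux * ux + uy * uy;
  }

  int locate_conflict(const double* p) {
    int t = (hint >= 0 && hint < (int)tris.size() && alive[hint]) ? hint : -1;
    if (t < 0)
      for (size_t i = 0; i < tris.size(); ++i)
        if (alive[i]) { t = (int)i; break; }
    size_t limit = 4 * tris.size() + 64;
    for (size_t steps = 0; steps < limit; ++steps) {
      const Tri& T = tris[t];
      if (ghost(T)) {
        if (conflict(t, p)) return t;
        int k = 0;
        while (T.v[k] != INF) ++k;
        int in = T.nb[k];
        if (in < 0 || !alive[in] || ghost(tris[in])) break;
        t = in;
        continue;
      }
      bool moved = false;
      for (int j = 0; j < 3; ++j) {
        int i = (int)((j + steps) % 3);
        const double* f0 = P(T.v[FACE2[i][0]]);
        const double* f1 = P(T.v[FACE2[i][1]]);
        if (vc::orient2d(f0, f1, p) < 0) {
          int nt = T.nb[i];
          if (nt < 0 || !alive[nt]) continue;
          if (ghost(tris[nt])) {
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
    for (size_t i = 0; i < tris.size(); ++i)
      if (alive[i] && conflict((int)i, p)) return (int)i;
    throw geom_failure2("no conflicting cell found");
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
      for (int i = 0; i < 3; ++i) {
        int nb = tris[t].nb[i];
        if (nb < 0 || mark[nb] == epoch) continue;
        if (conflict(nb, p)) {
          mark[nb] = epoch;
          stack.push_back(nb);
        }
      }
    }
    std::vector<std::pair<int, int>> boundary;
    for (size_t guard = 0; guard <= tris.size(); ++guard) {
      boundary.clear();
      bool bad = false;
      for (size_t ci = 0; ci < cav.size(); ++ci) {
        int t = cav[ci];
        for (int i = 0; i < 3; ++i) {
          int nb = tris[t].nb[i];
          if (nb >= 0 && mark[nb] == epoch) continue;
          int w0 = tris[t].v[FACE2[i][0]];
          int w1 = tris[t].v[FACE2[i][1]];
          if (w0 != INF && w1 != INF &&
              vc::orient2d(P(w0), P(w1), p) <= 0) {
            if (nb < 0) throw geom_failure2("cavity spilled past hull");
            mark[nb] = epoch;
            cav.push_back(nb);
            bad = true;
          } else {
            boundary.push_back({t, i});
          }
        }
      }
      if (!bad) break;
      if (guard == tris.size()) throw geom_failure2("cavity repair diverged");
    }
    if (boundary.empty()) throw geom_failure2("empty cavity boundary");
    std::unordered_map<int, std::pair<int, int>> open;
    open.reserve(2 * boundary.size());
    int last = -1;
    for (auto& bf : boundary) {
      int t = bf.first, i = bf.second;
      int w[2] = {tris[t].v[FACE2[i][0]], tris[t].v[FACE2[i][1]]};
      int L = tris[t].nb[i];
      int nt = alloc(w[0], w[1], pid);
      tris[nt].nb[2] = L;
      if (L >= 0) {
        for (int j = 0; j < 3; ++j)
          if (tris[L].nb[j] == t) { tris[L].nb[j] = nt; break; }
      }
      // face opposite slot 0 = (w1, pid): key w1; opposite 1 = (pid, w0): key w0
      for (int s = 0; s < 2; ++s) {
        int key = w[1 - s];
        auto it = open.find(key);
        if (it == open.end()) {
          open[key] = {nt, s};
        } else {
          tris[nt].nb[s] = it->second.first;
          tris[it->second.first].nb[it->second.second] = nt;
          open.erase(it);
        }
      }
      if (last < 0 || (w[0] != INF && w[1] != INF)) last = nt;
    }
    if (!open.empty()) throw geom_failure2("unmatched cavity faces");
    for (int t : cav) {
      alive[t] = 0;
      freelist.push_back(t);
    }
    hint = last;
  }

  void build(const std::vector<int>& order) {
    int i0 = order[0], i1 = -1, i2 = -1;
    size_t k = 1;
    for (; k < order.size(); ++k) {
      int c = order[k];
      if (P(c)[0] != P(i0)[0] || P(c)[1] != P(i0)[1]) {
        i1 = c;
        ++k;
        break;
      }
    }
    if (i1 < 0) throw geom_failure2("degenerate: all points coincide");
    for (; k < order.size(); ++k) {
      int c = order[k];
      int s = vc::orient2d(P(i0), P(i1), P(c));
      if (s != 0) {
        if (s < 0) std::swap(i0, i1);
        i2 = c;
        break;
      }
    }
    if (i2 < 0) throw geom_failure2("degenerate: all points collinear");

    int t0 = alloc(i0, i1, i2);
    int g[3];
    for (int i = 0; i < 3; ++i) {
      int w0 = tris[t0].v[FACE2[i][0]], w1 = tris[t0].v[FACE2[i][1]];
      g[i] = alloc(w1, w0, INF);
      tris[g[i]].nb[2] = t0;
      tris[t0].nb[i] = g[i];
    }
    // ghost-ghost links: faces (v1,INF) key v1 slot 0, (INF,v0) key v0 slot 1
    std::unordered_map<int, std::pair<int, int>> open;
    for (int i = 0; i < 3; ++i) {
      for (int s = 0; s < 2; ++s) {
        int key = tris[g[i]].v[1 - s];
        auto it = open.find(key);
        if (it == open.end()) {
          open[key] = {g[i], s};
        } else {
          tris[g[i]].nb[s] = it->second.first;
          tris[it->second.first].nb[it->second.second] = g[i];
          open.erase(it);
        }
      }
    }
    if (!open.empty()) throw geom_failure2("initial hull linking failed");
    hint = t0;
    for (size_t m = 1; m < order.size(); ++m) {
      int c = order[m];
      if (c == i0 || c == i1 || c == i2) continue;
      insert(c);
    }
  }
};

std::vector<int> morton_order2(const std::vector<double>& pts, int n) {
  double lo[2] = {1e300, 1e300}, hi[2] = {-1e300, -1e300};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 2; ++d) {
      double v = pts[2 * (size_t)i + d];
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  std::vector<uint64_t> key(n);
  for (int i = 0; i < n; ++i) {
    uint64_t code = 0;
    for (int d = 0; d < 2; ++d) {
      double span = hi[d] - lo[d];
      double f = span > 0 ? (pts[2 * (size_t)i + d] - lo[d]) / span : 0.0;
      uint64_t x = (uint64_t)(f * 4294967295.0);
      x = (x | (x << 16)) & 0x0000ffff0000ffffULL;
      x = (x | (x << 8)) & 0x00ff00ff00ff00ffULL;
      x = (x | (x << 4)) & 0x0f0f0f0f0f0f0f0fULL;
      x = (x | (x << 2)) & 0x3333333333333333ULL;
      x = (x | (x << 1)) & 0x5555555555555555ULL;
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

// [[Rcpp::export(name = ".dt2_build")]]
Rcpp::List dt2_build(Rcpp::NumericMatrix coords) {
  int n = coords.nrow();
  if (coords.ncol() != 2) Rcpp::stop("coords must have 2 columns");
  std::vector<double> base(2 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 2; ++d) base[2 * (size_t)i + d] = coords(i, d);
  double diag = 0;
  {
    double lo[2] = {1e300, 1e300}, hi[2] = {-1e300, -1e300};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 2; ++d) {
        double v = base[2 * (size_t)i + d];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    for (int d = 0; d < 2; ++d) diag += (hi[d] - lo[d]) * (hi[d] - lo[d]);
    diag = std::sqrt(diag);
    if (diag == 0) diag = 1.0;
  }
  std::vector<int> order = morton_order2(base, n);
  const double jog[4] = {0.0, 1e-10, 1e-8, 1e-6};
  std::string lasterr;
  for (int attempt = 0; attempt < 4; ++attempt) {
    Delaunay2 D;
    D.n = n;
    D.pts = base;
    if (attempt > 0) {
      double mag = jog[attempt] * diag;
      for (size_t i = 0; i < D.pts.size(); ++i) {
        uint64_t h = splitmix64_2(i * 4u + (uint64_t)attempt + 77777u);
        double u = (double)(h >> 11) * (1.0 / 9007199254740992.0);
        D.pts[i] += (2.0 * u - 1.0) * mag;
      }
    }
    try {
      D.build(order);
    } catch (const geom_failure2& e) {
      lasterr = e.what();
      if (attempt == 3 ||
          std::string(e.what()).find("degenerate") != std::string::npos)
        Rcpp::stop("Delaunay construction failed: %s", e.what());
      continue;
    }
    std::vector<int> finite;
    finite.reserve(D.tris.size());
    for (size_t i = 0; i < D.tris.size(); ++i)
      if (D.alive[i] && !D.ghost(D.tris[i])) finite.push_back((int)i);
    size_t m = finite.size();
    Rcpp::IntegerMatrix simp((int)m, 3);
    for (size_t s = 0; s < m; ++s)
      for (int j = 0; j < 3; ++j) simp((int)s, j) = D.tris[finite[s]].v[j] + 1;
    std::vector<std::vector<int>> nbr(n);
    for (size_t s = 0; s < m; ++s) {
      const Tri& t = D.tris[finite[s]];
      for (int a = 0; a < 3; ++a)
        for (int b = a + 1; b < 3; ++b) {
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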
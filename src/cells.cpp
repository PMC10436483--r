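// Voronoi cell construction by brute-force bisector clipping.
// Each cell starts as the clip box and is cut by the perpendicular bisector
// half-space of every supplied neighbour, nearest first; a bisector whose
// plane lies farther from the generator than the farthest current cell
// vertex cannot cut and ends the loop (sound bound, exact result).
// Face provenance is tracked so that box-clipped (border) cells and
// facet-contributing neighbours can be reported.

#include <Rcpp.h>

#include <algorithm>
#include <cmath>
#include <vector>

namespace {

struct Poly3 {
  std::vector<double> V;            // 3 * nv
  std::vector<std::vector<int>> F;  // CCW-from-outside loops
  std::vector<int> src;             // per face: -1..-6 clip box, else >=0
  bool empty = false;

  void init_box(const double* lo, const double* hi) {
    V.resize(24);
    for (int i = 0; i < 8; ++i) {
      V[3 * i + 0] = (i & 1) ? hi[0] : lo[0];
      V[3 * i + 1] = (i & 2) ? hi[1] : lo[1];
      V[3 * i + 2] = (i & 4) ? hi[2] : lo[2];
    }
    F = {{0, 4, 6, 2}, {1, 3, 7, 5}, {0, 1, 5, 4},
         {2, 6, 7, 3}, {0, 2, 3, 1}, {4, 5, 7, 6}};
    src = {-1, -2, -3, -4, -5, -6};
    empty = false;
  }
};

// clip poly by half-space {x : n.x <= c}, |n| = 1
// returns true if the polytope was modified
bool clip3(Poly3& P, const double* n, double c, int srcid, double eps) {
  size_t nv = P.V.size() / 3;
  static thread_local std::vector<double> d;
  static thread_local std::vector<int> cls;  // -1 in, 0 on, 1 out
  d.resize(nv);
  cls.resize(nv);
  bool any_out = false, any_in = false;
  for (size_t i = 0; i < nv; ++i) {
    double di = n[0] * P.V[3 * i] + n[1] * P.V[3 * i + 1] +
                n[2] * P.V[3 * i + 2] - c;
    d[i] = di;
    cls[i] = di > eps ? 1 : (di < -eps ? -1 : 0);
    if (cls[i] == 1) any_out = true;
    if (cls[i] == -1) any_in = true;
  }
  if (!any_out) return false;
  if (!any_in) {
    P.empty = true;
    return true;
  }
  // cut-edge vertex cache
  std::vector<std::pair<long long, int>> cut;
  auto cut_vertex = [&](int a, int b) -> int {
    long long key = a < b ? ((long long)a << 32) | (unsigned)b
                          : ((long long)b << 32) | (unsigned)a;
    for (auto& kv : cut)
      if (kv.first == key) return kv.second;
    double t = d[a] / (d[a] - d[b]);
    int id = (int)(P.V.size() / 3);
    for (int k = 0; k < 3; ++k)
      P.V.push_back(P.V[3 * a + k] + t * (P.V[3 * b + k] - P.V[3 * a + k]));
    cut.push_back({key, id});
    return id;
  };
  std::vector<std::vector<int>> newF;
  std::vector<int> newsrc;
  std::vector<int> onplane;
  for (size_t f = 0; f < P.F.size(); ++f) {
    const std::vector<int>& loop = P.F[f];
    std::vector<int> out;
    size_t k = loop.size();
    for (size_t i = 0; i < k; ++i) {
      int u = loop[i], v = loop[(i + 1) % k];
      if (cls[u] != 1) out.push_back(u);
      if ((cls[u] == -1 && cls[v] == 1) || (cls[u] == 1 && cls[v] == -1))
        out.push_back(cut_vertex(u, v));
    }
    if (out.size() >= 3) {
      newF.push_back(out);
      newsrc.push_back(P.src[f]);
    }
  }
  P.F.swap(newF);
  P.src.swap(newsrc);
  if (P.F.empty()) {
    P.empty = true;
    return true;
  }
  // cap face: all referenced vertices on the plane, ordered angularly
  {
    std::vector<char> used(P.V.size() / 3, 0);
    for (auto& f : P.F)
      for (int v : f) used[v] = 1;
    d.resize(P.V.size() / 3);
    for (size_t i = nv; i < P.V.size() / 3; ++i) d[i] = 0.0;
    for (size_t i = 0; i < P.V.size() / 3; ++i) {
      if (!used[i]) continue;
      if (i >= nv || std::fabs(d[i]) <= eps) onplane.push_back((int)i);
    }
    if (onplane.size() >= 3) {
      // plane basis
      double e1[3], e2[3];
      double ax = std::fabs(n[0]), ay = std::fabs(n[1]), az = std::fabs(n[2]);
      double ref[3] = {0, 0, 0};
      if (ax <= ay && ax <= az) ref[0] = 1;
      else if (ay <= az) ref[1] = 1;
      else ref[2] = 1;
      e1[0] = n[1] * ref[2] - n[2] * ref[1];
      e1[1] = n[2] * ref[0] - n[0] * ref[2];
      e1[2] = n[0] * ref[1] - n[1] * ref[0];
      double l1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
      for (int k2 = 0; k2 < 3; ++k2) e1[k2] /= l1;
      e2[0] = n[1] * e1[2] - n[2] * e1[1];
      e2[1] = n[2] * e1[0] - n[0] * e1[2];
      e2[2] = n[0] * e1[1] - n[1] * e1[0];
      double cx = 0, cy = 0;
      std::vector<std::pair<double, int>> ang(onplane.size());
      std::vector<double> px(onplane.size()), py(onplane.size());
      for (size_t i = 0; i < onplane.size(); ++i) {
        const double* v = &P.V[3 * (size_t)onplane[i]];
        px[i] = v[0] * e1[0] + v[1] * e1[1] + v[2] * e1[2];
        py[i] = v[0] * e2[0] + v[1] * e2[1] + v[2] * e2[2];
        cx += px[i];
        cy += py[i];
      }
      cx /= onplane.size();
      cy /= onplane.size();
      for (size_t i = 0; i < onplane.size(); ++i)
        ang[i] = {std::atan2(py[i] - cy, px[i] - cx), onplane[i]};
      std::sort(ang.begin(), ang.end());
      std::vector<int> cap(ang.size());
      for (size_t i = 0; i < ang.size(); ++i) cap[i] = ang[i].second;
      // orientation: cap normal must align with +n (outward side of cut)
      // angular order in (e1,e2) basis gives normal e1 x e2 = n, so the
      // CCW order points along +n already; keep as is.
      P.F.push_back(cap);
      P.src.push_back(srcid);
    }
  }
  return true;
}

double volume3(const Poly3& P) {
  size_t nv = P.V.size() / 3;
  double r[3] = {0, 0, 0};
  for (size_t i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) r[k] += P.V[3 * i + k];
  for (int k = 0; k < 3; ++k) r[k] /= (double)nv;
  double vol = 0;
  for (size_t f = 0; f < P.F.size(); ++f) {
    const std::vector<int>& L = P.F[f];
    const double* a = &P.V[3 * (size_t)L[0]];
    double A[3] = {a[0] - r[0], a[1] - r[1], a[2] - r[2]};
    for (size_t i = 1; i + 1 < L.size(); ++i) {
      const double* b = &P.V[3 * (size_t)L[i]];
      const double* c = &P.V[3 * (size_t)L[i + 1]];
      double B[3] = {b[0] - r[0], b[1] - r[1], b[2] - r[2]};
      double C[3] = {c[0] - r[0], c[1] - r[1], c[2] - r[2]};
      vol += A[0] * (B[1] * C[2] - B[2] * C[1]) -
             A[1] * (B[0] * C[2] - B[2] * C[0]) +
             A[2] * (B[0] * C[1] - B[1] * C[0]);
    }
  }
  return vol / 6.0;
}

struct CellRes {
  double size = 0;
  bool touches_clip = false;
  bool outside_data = false;
  int nfacets = 0;
  bool failed = false;
};

// build one 3D cell; nbr_order: neighbour coordinate triples sorted by the
// caller?  No: sorting happens here (distance, then lexicographic).
CellRes build_cell3(const double* p, const double* pts, const int* nbrs,
                    int nn, const double* clip_lo, const double* clip_hi,
                    const double* data_lo, const double* data_hi, double eps,
                    double tol_data, Poly3* keep_poly,
                    std::vector<int>* facet_nbrs) {
  CellRes res;
  std::vector<std::pair<double, int>> ord(nn);
  for (int i = 0; i < nn; ++i) {
    const double* q = pts + 3 * (size_t)nbrs[i];
    double d2 = 0;
    for (int k = 0; k < 3; ++k) d2 += (q[k] - p[k]) * (q[k] - p[k]);
    ord[i] = {d2, nbrs[i]};
  }
  std::sort(ord.begin(), ord.end(), [&](const std::pair<double, int>& a,
                                        const std::pair<double, int>& b) {
    if (a.first != b.first) return a.first < b.first;
    const double* qa = pts + 3 * (size_t)a.second;
    const double* qb = pts + 3 * (size_t)b.second;
    for (int k = 0; k < 3; ++k)
      if (qa[k] != qb[k]) return qa[k] < qb[k];
    return a.second < b.second;
  });
  Poly3 P;
  P.init_box(clip_lo, clip_hi);
  double maxR2 = 0;
  auto upd_maxR2 = [&]() {
    maxR2 = 0;
    std::vector<char> used(P.V.size() / 3, 0);
    for (auto& f : P.F)
      for (int v : f) used[v] = 1;
    for (size_t i = 0; i < P.V.size() / 3; ++i) {
      if (!used[i]) continue;
      double d2 = 0;
      for (int k = 0; k < 3; ++k)
        d2 += (P.V[3 * i + k] - p[k]) * (P.V[3 * i + k] - p[k]);
      if (d2 > maxR2) maxR2 = d2;
    }
  };
  upd_maxR2();
  std::vector<int> srcmap;  // srcid -> original neighbour index
  for (int i = 0; i < nn; ++i) {
    double d2 = ord[i].first;
    if (d2 == 0) {
      res.failed = true;  // coincident generator
      return res;
    }
    if (d2 > 4.0 * maxR2) break;
    const double* q = pts + 3 * (size_t)ord[i].second;
    double nvec[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
    double len = std::sqrt(d2);
    for (int k = 0; k < 3; ++k) nvec[k] /= len;
    double c = 0;
    for (int k = 0; k < 3; ++k) c += nvec[k] * 0.5 * (p[k] + q[k]);
    int srcid = (int)srcmap.size();
    srcmap.push_back(ord[i].second);
    if (clip3(P, nvec, c, srcid, eps)) {
      if (P.empty) {
        res.failed = true;
        return res;
      }
      upd_maxR2();
    }
  }
  res.size = volume3(P);
  std::vector<char> has(srcmap.size(), 0);
  for (size_t f = 0; f < P.F.size(); ++f) {
    if (P.src[f] < 0)
      res.touches_clip = true;
    else if (!has[P.src[f]]) {
      has[P.src[f]] = 1;
      ++res.nfacets;
      if (facet_nbrs) facet_nbrs->push_back(srcmap[P.src[f]]);
    }
  }
  std::vector<char> used(P.V.size() / 3, 0);
  for (auto& f : P.F)
    for (int v : f) used[v] = 1;
  for (size_t i = 0; i < P.V.size() / 3; ++i) {
    if (!used[i]) continue;
    for (int k = 0; k < 3; ++k) {
      if (P.V[3 * i + k] < data_lo[k] - tol_data ||
          P.V[3 * i + k] > data_hi[k] + tol_data) {
        res.outside_data = true;
        break;
      }
    }
    if (res.outside_data) break;
  }
  if (keep_poly) *keep_poly = P;
  return res;
}

// ------------------------------ 2D ------------------------------

struct Poly2 {
  std::vector<double> V;   // 2 * nv, CCW
  std::vector<int> esrc;   // edge i: V[i] -> V[i+1 mod nv]
  bool empty = false;

  void init_box(const double* lo, const double* hi) {
    V = {lo[0], lo[1], hi[0], lo[1], hi[0], hi[1], lo[0], hi[1]};
    esrc = {-1, -2, -3, -4};
    empty = false;
  }
};

bool clip2(Poly2& P, const double* n, double c, int srcid, double eps) {
  size_t nv = P.V.size() / 2;
  std::vector<double> d(nv);
  std::vector<int> cls(nv);
  bool any_out = false, any_in = false;
  for (size_t i = 0; i < nv; ++i) {
    double di = n[0] * P.V[2 * i] + n[1] * P.V[2 * i + 1] - c;
    d[i] = di;
    cls[i] = di > eps ? 1 : (di < -eps ? -1 : 0);
    if (cls[i] == 1) any_out = true;
    if (cls[i] == -1) any_in = true;
  }
  if (!any_out) return false;
  if (!any_in) {
    P.empty = true;
    return true;
  }
  std::vector<double> NV;
  std::vector<int> NS;
  for (size_t i = 0; i < nv; ++i) {
    size_t j = (i + 1) % nv;
    if (cls[i] != 1) {
      NV.push_back(P.V[2 * i]);
      NV.push_back(P.V[2 * i + 1]);
      // leaving edge: original unless the outgoing edge is being cut at an
      // ON vertex (next is OUT)
      NS.push_back(cls[i] == 0 && cls[j] == 1 ? srcid : P.esrc[i]);
    }
    if ((cls[i] == -1 && cls[j] == 1) || (cls[i] == 1 && cls[j] == -1)) {
      double t = d[i] / (d[i] - d[j]);
      NV.push_back(P.V[2 * i] + t * (P.V[2 * j] - P.V[2 * i]));
      NV.push_back(P.V[2 * i + 1] + t * (P.V[2 * j + 1] - P.V[2 * i + 1]));
      NS.push_back(cls[i] == -1 ? srcid : P.esrc[i]);
    }
  }
  P.V.swap(NV);
  P.esrc.swap(NS);
  if (P.V.size() < 6) P.empty = true;
  return true;
}

double area2(const Poly2& P) {
  size_t nv = P.V.size() / 2;
  double a = 0;
  for (size_t i = 0; i < nv; ++i) {
    size_t j = (i + 1) % nv;
    a += P.V[2 * i] * P.V[2 * j + 1] - P.V[2 * j] * P.V[2 * i + 1];
  }
  return a / 2.0;
}

CellRes build_cell2(const double* p, const double* pts, const int* nbrs,
                    int nn, const double* clip_lo, const double* clip_hi,
                    const double* data_lo, const double* data_hi, double eps,
                    double tol_data, Poly2* keep_poly,
                    std::vector<int>* facet_nbrs) {
  CellRes res;
  std::vector<std::pair<double, int>> ord(nn);
  for (int i = 0; i < nn; ++i) {
    const double* q = pts + 2 * (size_t)nbrs[i];
    double d2 = (q[0] - p[0]) * (q[0] - p[0]) + (q[1] - p[1]) * (q[1] - p[1]);
    ord[i] = {d2, nbrs[i]};
  }
  std::sort(ord.begin(), ord.end(), [&](const std::pair<double, int>& a,
                                        const std::pair<double, int>& b) {
    if (a.first != b.first) return a.first < b.first;
    const double* qa = pts + 2 * (size_t)a.second;
    const double* qb = pts + 2 * (size_t)b.second;
    for (int k = 0; k < 2; ++k)
      if (qa[k] != qb[k]) return qa[k] < qb[k];
    return a.second < b.second;
  });
  Poly2 P;
  P.init_box(clip_lo, clip_hi);
  double maxR2 = 0;
  auto upd_maxR2 = [&]() {
    maxR2 = 0;
    for (size_t i = 0; i < P.V.size() / 2; ++i) {
      double d2 = (P.V[2 * i] - p[0]) * (P.V[2 * i] - p[0]) +
                  (P.V[2 * i + 1] - p[1]) * (P.V[2 * i + 1] - p[1]);
      if (d2 > maxR2) maxR2 = d2;
    }
  };
  upd_maxR2();
  std::vector<int> srcmap;
  for (int i = 0; i < nn; ++i) {
    double d2 = ord[i].first;
    if (d2 == 0) {
      res.failed = true;
      return res;
    }
    if (d2 > 4.0 * maxR2) break;
    const double* q = pts + 2 * (size_t)ord[i].second;
    double nvec[2] = {q[0] - p[0], q[1] - p[1]};
    double len = std::sqrt(d2);
    nvec[0] /= len;
    nvec[1] /= len;
    double c = nvec[0] * 0.5 * (p[0] + q[0]) + nvec[1] * 0.5 * (p[1] + q[1]);
    int srcid = (int)srcmap.size();
    srcmap.push_back(ord[i].second);
    if (clip2(P, nvec, c, srcid, eps)) {
      if (P.empty) {
        res.failed = true;
        return res;
      }
      upd_maxR2();
    }
  }
  res.size = area2(P);
  std::vector<char> has(srcmap.size(), 0);
  for (size_t e = 0; e < P.esrc.size(); ++e) {
    if (P.esrc[e] < 0)
      res.touches_clip = true;
    else if (!has[P.esrc[e]]) {
      has[P.esrc[e]] = 1;
      ++res.nfacets;
      if (facet_nbrs) facet_nbrs->push_back(srcmap[P.esrc[e]]);
    }
  }
  for (size_t i = 0; i < P.V.size() / 2 && !res.outside_data; ++i)
    for (int k = 0; k < 2; ++k)
      if (P.V[2 * i + k] < data_lo[k] - tol_data ||
          P.V[2 * i + k] > data_hi[k] + tol_data) {
        res.outside_data = true;
        break;
      }
  if (keep_poly) *keep_poly = P;
  return res;
}

double box_diag(const Rcpp::NumericVector& lo, const Rcpp::NumericVector& hi) {
  double s = 0;
  for (int k = 0; k < lo.size(); ++k) s += (hi[k] - lo[k]) * (hi[k] - lo[k]);
  return std::sqrt(s);
}

Rcpp::List poly3_to_R(const Poly3& P) {
  // compact to referenced vertices
  size_t nv = P.V.size() / 3;
  std::vector<int> remap(nv, -1);
  int nn = 0;
  for (auto& f : P.F)
    for (int v : f)
      if (remap[v] < 0) remap[v] = nn++;
  Rcpp::NumericMatrix V(nn, 3);
  for (size_t i = 0; i < nv; ++i)
    if (remap[i] >= 0)
      for (int k = 0; k < 3; ++k) V(remap[i], k) = P.V[3 * i + k];
  Rcpp::List faces(P.F.size());
  Rcpp::IntegerVector fsrc(P.F.size());
  for (size_t f = 0; f < P.F.size(); ++f) {
    Rcpp::IntegerVector loop(P.F[f].size());
    for (size_t i = 0; i < P.F[f].size(); ++i) loop[i] = remap[P.F[f][i]] + 1;
    faces[f] = loop;
    fsrc[f] = P.src[f];
  }
  return Rcpp::List::create(Rcpp::Named("vertices") = V,
                            Rcpp::Named("faces") = faces,
                            Rcpp::Named("face_src") = fsrc);
}

Rcpp::List poly2_to_R(const Poly2& P) {
  size_t nv = P.V.size() / 2;
  Rcpp::NumericMatrix V((int)nv, 2);
  for (size_t i = 0; i < nv; ++i) {
    V((int)i, 0) = P.V[2 * i];
    V((int)i, 1) = P.V[2 * i + 1];
  }
  Rcpp::IntegerVector esrc((int)nv);
  for (size_t i = 0; i < nv; ++i) esrc[(int)i] = P.esrc[i];
  return Rcpp::List::create(Rcpp::Named("vertices") = V,
                            Rcpp::Named("edge_src") = esrc);
}

}  // namespace

// [[Rcpp::export(name = ".vc_cells")]]
Rcpp::List vc_cells(Rcpp::NumericMatrix coords, Rcpp::IntegerVector ring_start,
                    Rcpp::IntegerVector ring_idx, Rcpp::NumericVector clip_lo,
                    Rcpp::NumericVector clip_hi, Rcpp::NumericVector data_lo,
                    Rcpp::NumericVector data_hi, bool want_poly,
                    bool want_neighbors) {
  int n = coords.nrow();
  int dim = coords.ncol();
  double diag = box_diag(clip_lo, clip_hi);
  double eps = 1e-10 * diag;
  double tol_data = 1e-9 * diag;
  std::vector<double> pts((size_t)n * dim);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < dim; ++k) pts[(size_t)i * dim + k] = coords(i, k);
  Rcpp::NumericVector sizes(n);
  Rcpp::LogicalVector touches(n), outside(n);
  Rcpp::IntegerVector nfac(n);
  Rcpp::List polys = want_poly ? Rcpp::List(n) : Rcpp::List(0);
  Rcpp::List nbl = want_neighbors ? Rcpp::List(n) : Rcpp::List(0);
  std::vector<int> ring;
  for (int i = 0; i < n; ++i) {
    int a = ring_start[i] - 1, b = ring_start[i + 1] - 1;
    ring.resize(b - a);
    for (int j = a; j < b; ++j) ring[j - a] = ring_idx[j] - 1;
    std::vector<int> fnbr;
    CellRes r;
    if (dim == 3) {
      Poly3 keep;
      r = build_cell3(&pts[(size_t)i * 3], pts.data(), ring.data(),
                      (int)ring.size(), &clip_lo[0], &clip_hi[0], &data_lo[0],
                      &data_hi[0], eps, tol_data, want_poly ? &keep : nullptr,
                      want_neighbors ? &fnbr : nullptr);
      if (want_poly && !r.failed) polys[i] = poly3_to_R(keep);
    } else {
      Poly2 keep;
      r = build_cell2(&pts[(size_t)i * 2], pts.data(), ring.data(),
                      (int)ring.size(), &clip_lo[0], &clip_hi[0], &data_lo[0],
                      &data_hi[0], eps, tol_data, want_poly ? &keep : nullptr,
                      want_neighbors ? &fnbr : nullptr);
      if (want_poly && !r.failed) polys[i] = poly2_to_R(keep);
    }
    if (r.failed)
      Rcpp::stop("Voronoi cell construction failed for point %d "
                 "(empty intersection or coincident generator)",
                 i + 1);
    sizes[i] = r.size;
    touches[i] = r.touches_clip;
    outside[i] = r.outside_data;
    nfac[i] = r.nfacets;
    if (want_neighbors) {
      std::sort(fnbr.begin(), fnbr.end());
      Rcpp::IntegerVector fv(fnbr.size());
      for (size_t j = 0; j < fnbr.size(); ++j) fv[j] = fnbr[j] + 1;
      nbl[i] = fv;
    }
    if ((i & 0x3fff) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("sizes") = sizes, Rcpp::Named("touches_clip") = touches,
      Rcpp::Named("outside_data") = outside, Rcpp::Named("n_facets") = nfac,
      Rcpp::Named("polytopes") = polys, Rcpp::Named("facet_neighbors") = nbl);
}

// [[Rcpp::export(name = ".vc_cell_single")]]
Rcpp::List vc_cell_single(Rcpp::NumericVector p, Rcpp::NumericMatrix nbr,
                          Rcpp::NumericVector clip_lo,
                          Rcpp::NumericVector clip_hi,
                          Rcpp::NumericVector data_lo,
                          Rcpp::NumericVector data_hi) {
  int dim = p.size();
  int nn = nbr.nrow();
  double diag = box_diag(clip_lo, clip_hi);
  double eps = 1e-10 * diag;
  double tol_data = 1e-9 * diag;
  // pts layout: generator's neighbours only; indices 0..nn-1
  std::vector<double> pts((size_t)nn * dim);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < dim; ++k) pts[(size_t)i * dim + k] = nbr(i, k);
  std::vector<int> idx(nn);
  for (int i = 0; i < nn; ++i) idx[i] = i;
  std::vector<int> fnbr;
  CellRes r;
  Rcpp::List poly;
  if (dim == 3) {
    Poly3 keep;
    r = build_cell3(&p[0], pts.data(), idx.data(), nn, &clip_lo[0],
                    &clip_hi[0], &data_lo[0], &data_hi[0], eps, tol_data,
                    &keep, &fnbr);
    if (!r.failed) poly = poly3_to_R(keep);
  } else {
    Poly2 keep;
    r = build_cell2(&p[0], pts.data(), idx.data(), nn, &clip_lo[0],
                    &clip_hi[0], &data_lo[0], &data_hi[0], eps, tol_data,
                    &keep, &fnbr);
    if (!r.failed) poly = poly2_to_R(keep);
  }
  if (r.failed)
    Rcpp::stop("Voronoi cell construction failed "
               "(empty intersection or coincident generator)");
  std::sort(fnbr.begin(), fnbr.end());
  Rcpp::IntegerVector fv(fnbr.size());
  for (size_t j = 0; j < fnbr.size(); ++j) fv[j] = fnbr[j] + 1;
  return Rcpp::List::create(
      Rcpp::Named("size") = r.size, Rcpp::Named("touches_clip") = r.touches_clip,
      Rcpp::Named("outside_data") = r.outside_data,
      Rcpp::Named("n_facets") = r.nfacets, Rcpp::Named("facet_neighbors") = fv,
      Rcpp::Named("polytope") = poly);
}
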
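#ifndef VOROCLUST_PREDICATES_H
#define VOROCLUST_PREDICATES_H

#include <cmath>
#include <cstdlib>

// Filtered geometric predicates: evaluate in double with a relative error
// bound on the determinant's permanent; fall back to long double when the
// result is within the uncertainty band; report 0 (degenerate) when even the
// long double result is inconclusive.  Near-degenerate configurations that
// slip through are handled upstream by a deterministic joggle-and-retry.

namespace vc {

template <typename T>
inline T det3(T a0, T a1, T a2, T b0, T b1, T b2, T c0, T c1, T c2) {
  return a0 * (b1 * c2 - b2 * c1) - a1 * (b0 * c2 - b2 * c0) +
         a2 * (b0 * c1 - b1 * c0);
}

template <typename T>
inline T perm3(T a0, T a1, T a2, T b0, T b1, T b2, T c0, T c1, T c2) {
  using std::fabs;
  return fabs(a0) * (fabs(b1 * c2) + fabs(b2 * c1)) +
         fabs(a1) * (fabs(b0 * c2) + fabs(b2 * c0)) +
         fabs(a2) * (fabs(b0 * c1) + fabs(b1 * c0));
}

// orient3d(a,b,c,d) = sign of det[a-d; b-d; c-d].
// > 0 when d sees triangle (a,b,c) clockwise (right-handed convention).
inline int orient3d(const double* a, const double* b, const double* c,
                    const double* d) {
  double ad0 = a[0] - d[0], ad1 = a[1] - d[1], ad2 = a[2] - d[2];
  double bd0 = b[0] - d[0], bd1 = b[1] - d[1], bd2 = b[2] - d[2];
  double cd0 = c[0] - d[0], cd1 = c[1] - d[1], cd2 = c[2] - d[2];
  double det = det3(ad0, ad1, ad2, bd0, bd1, bd2, cd0, cd1, cd2);
  double perm = perm3(ad0, ad1, ad2, bd0, bd1, bd2, cd0, cd1, cd2);
  if (std::fabs(det) > 1e-11 * perm) return det > 0 ? 1 : -1;
  long double A0 = (long double)a[0] - d[0], A1 = (long double)a[1] - d[1],
              A2 = (long double)a[2] - d[2];
  long double B0 = (long double)b[0] - d[0], B1 = (long double)b[1] - d[1],
              B2 = (long double)b[2] - d[2];
  long double C0 = (long double)c[0] - d[0], C1 = (long double)c[1] - d[1],
              C2 = (long double)c[2] - d[2];
  long double detl = det3(A0, A1, A2, B0, B1, B2, C0, C1, C2);
  long double perml = perm3(A0, A1, A2, B0, B1, B2, C0, C1, C2);
  if (fabsl(detl) > 1e-17L * perml) return detl > 0 ? 1 : -1;
  return 0;
}

template <typename T>
inline T det4_lift(T a0, T a1, T a2, T al, T b0, T b1, T b2, T bl, T c0, T c1,
                   T c2, T cl, T d0, T d1, T d2, T dl) {
  // det of rows (a0 a1 a2 al; b...; c...; d...)
  T ab = a0 * b1 - a1 * b0, ac = a0 * c1 - a1 * c0, ad = a0 * d1 - a1 * d0;
  T bc = b0 * c1 - b1 * c0, bd = b0 * d1 - b1 * d0, cd = c0 * d1 - c1 * d0;
  T abc = a2 * bc - b2 * ac + c2 * ab;
  T abd = a2 * bd - b2 * ad + d2 * ab;
  T acd = a2 * cd - c2 * ad + d2 * ac;
  T bcd = b2 * cd - c2 * bd + d2 * bc;
  return dl * abc - cl * abd + bl * acd - al * bcd;
}

template <typename T>
inline T perm4_lift(T a0, T a1, T a2, T al, T b0, T b1, T b2, T bl, T c0, T c1,
                    T c2, T cl, T d0, T d1, T d2, T dl) {
  using std::fabs;
  T ab = fabs(a0 * b1) + fabs(a1 * b0), ac = fabs(a0 * c1) + fabs(a1 * c0),
    ad = fabs(a0 * d1) + fabs(a1 * d0);
  T bc = fabs(b0 * c1) + fabs(b1 * c0), bd = fabs(b0 * d1) + fabs(b1 * d0),
    cd = fabs(c0 * d1) + fabs(c1 * d0);
  T abc = fabs(a2) * bc + fabs(b2) * ac + fabs(c2) * ab;
  T abd = fabs(a2) * bd + fabs(b2) * ad + fabs(d2) * ab;
  T acd = fabs(a2) * cd + fabs(c2) * ad + fabs(d2) * ac;
  T bcd = fabs(b2) * cd + fabs(c2) * bd + fabs(d2) * bc;
  return fabs(dl) * abc + fabs(cl) * abd + fabs(bl) * acd + fabs(al) * bcd;
}

// insphere(a,b,c,d,e): for a POSITIVELY oriented tetrahedron (a,b,c,d)
// (orient3d(a,b,c,d) > 0), returns > 0 iff e lies strictly inside the
// circumsphere, < 0 outside, 0 on/indeterminate.
inline int insphere(const double* a, const double* b, const double* c,
                    const double* d, const double* e) {
  double ae0 = a[0] - e[0], ae1 = a[1] - e[1], ae2 = a[2] - e[2];
  double be0 = b[0] - e[0], be1 = b[1] - e[1], be2 = b[2] - e[2];
  double ce0 = c[0] - e[0], ce1 = c[1] - e[1], ce2 = c[2] - e[2];
  double de0 = d[0] - e[0], de1 = d[1] - e[1], de2 = d[2] - e[2];
  double al = ae0 * ae0 + ae1 * ae1 + ae2 * ae2;
  double bl = be0 * be0 + be1 * be1 + be2 * be2;
  double cl = ce0 * ce0 + ce1 * ce1 + ce2 * ce2;
  double dl = de0 * de0 + de1 * de1 + de2 * de2;
  double det = det4_lift(ae0, ae1, ae2, al, be0, be1, be2, bl, ce0, ce1, ce2,
                         cl, de0, de1, de2, dl);
  double perm = perm4_lift(ae0, ae1, ae2, al, be0, be1, be2, bl, ce0, ce1, ce2,
                           cl, de0, de1, de2, dl);
  if (std::fabs(det) > 1e-10 * perm) return det > 0 ? 1 : -1;
  long double A0 = (long double)a[0] - e[0], A1 = (long double)a[1] - e[1],
              A2 = (long double)a[2] - e[2];
  long double B0 = (long double)b[0] - e[0], B1 = (long double)b[1] - e[1],
              B2 = (long double)b[2] - e[2];
  long double C0 = (long double)c[0] - e[0], C1 = (long double)c[1] - e[1],
              C2 = (long double)c[2] - e[2];
  long double D0 = (long double)d[0] - e[0], D1 = (long double)d[1] - e[1],
              D2 = (long double)d[2] - e[2];
  long double AL = A0 * A0 + A1 * A1 + A2 * A2;
  long double BL = B0 * B0 + B1 * B1 + B2 * B2;
  long double CL = C0 * C0 + C1 * C1 + C2 * C2;
  long double DL = D0 * D0 + D1 * D1 + D2 * D2;
  long double detl = det4_lift(A0, A1, A2, AL, B0, B1, B2, BL, C0, C1, C2, CL,
                               D0, D1, D2, DL);
  long double perml = perm4_lift(A0, A1, A2, AL, B0, B1, B2, BL, C0, C1, C2,
                                 CL, D0, D1, D2, DL);
  if (fabsl(detl) > 1e-16L * perml) return detl > 0 ? 1 : -1;
  return 0;
}

// orient2d(a,b,c): > 0 iff (a,b,c) counterclockwise.
inline int orient2d(const double* a, const double* b, const double* c) {
  double d1 = (a[0] - c[0]) * (b[1] - c[1]);
  double d2 = (a[1] - c[1]) * (b[0] - c[0]);
  double det = d1 - d2;
  double perm = std::fabs(d1) + std::fabs(d2);
  if (std::fabs(det) > 1e-12 * perm) return det > 0 ? 1 : -1;
  long double D1 = ((long double)a[0] - c[0]) * ((long double)b[1] - c[1]);
  long double D2 = ((long double)a[1] - c[1]) * ((long double)b[0] - c[0]);
  long double detl = D1 - D2;
  long double perml = fabsl(D1) + fabsl(D2);
  if (fabsl(detl) > 1e-18L * perml) return detl > 0 ? 1 : -1;
  return 0;
}

// incircle(a,b,c,e) for CCW triangle (a,b,c): > 0 iff e strictly inside the
// circumcircle.
inline int incircle2d(const double* a, const double* b, const double* c,
                      const double* e) {
  {
    double A0 = a[0] - e[0], A1 = a[1] - e[1];
    double B0 = b[0] - e[0], B1 = b[1] - e[1];
    double C0 = c[0] - e[0], C1 = c[1] - e[1];
    double AL = A0 * A0 + A1 * A1;
    double BL = B0 * B0 + B1 * B1;
    double CL = C0 * C0 + C1 * C1;
    double det = det3(A0, A1, AL, B0, B1, BL, C0, C1, CL);
    double perm = perm3(A0, A1, AL, B0, B1, BL, C0, C1, CL);
    if (std::fabs(det) > 1e-11 * perm) return det > 0 ? 1 : -1;
  }
  long double A0 = (long double)a[0] - e[0], A1 = (long double)a[1] - e[1];
  long double B0 = (long double)b[0] - e[0], B1 = (long double)b[1] - e[1];
  long double C0 = (long double)c[0] - e[0], C1 = (long double)c[1] - e[1];
  long double AL = A0 * A0 + A1 * A1;
  long double BL = B0 * B0 + B1 * B1;
  long double CL = C0 * C0 + C1 * C1;
  long double detl = det3(A0, A1, AL, B0, B1, BL, C0, C1, CL);
  long double perml = perm3(A0, A1, AL, B0, B1, BL, C0, C1, CL);
  if (fabsl(detl) > 1e-17L * perml) return detl > 0 ? 1 : -1;
  return 0;
}

}  // namespace vc

#endif
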
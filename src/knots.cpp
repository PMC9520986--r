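// Geometry and integer-arithmetic kernels for knot classification:
//  - KMT chain simplification (topology-preserving bead elision)
//  - generic planar projection -> crossing diagram (arcs, over/under, sign)
//  - Alexander determinant |Delta(-1)| in exact integer arithmetic
//    (int64 Bareiss; beyond int64, a certified modular + log-determinant
//    procedure, see alexander_decision below)
//  - 2D segment-intersection "knotting" test
//
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- vectors --
struct V3 { double x, y, z; };
static inline V3 vsub(const V3&a, const V3&b){ return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 vcross(const V3&a, const V3&b){
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double vdot(const V3&a, const V3&b){ return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline double vnorm2(const V3&a){ return vdot(a,a); }

// deterministic direction generator (splitmix64 -> uniform unit vector)
struct DirGen {
  uint64_t s;
  explicit DirGen(uint64_t seed) : s(seed ^ 0x9e3779b97f4a7c15ULL) {}
  double unif(){
    s += 0x9e3779b97f4a7c15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    return (double)(z >> 11) * (1.0/9007199254740992.0);
  }
  V3 unit(){
    // marsaglia rejection on the sphere
    for(;;){
      double a = 2.0*unif()-1.0, b = 2.0*unif()-1.0;
      double s2 = a*a + b*b;
      if (s2 > 0.0 && s2 < 1.0){
        double f = 2.0*std::sqrt(1.0 - s2);
        return {a*f, b*f, 1.0 - 2.0*s2};
      }
    }
  }
};

static double ring_diameter(const std::vector<V3>& P){
  // cheap bound: diagonal of the bounding box
  double lo[3] = {P[0].x,P[0].y,P[0].z}, hi[3] = {P[0].x,P[0].y,P[0].z};
  for (const auto& p : P){
    lo[0]=std::min(lo[0],p.x); hi[0]=std::max(hi[0],p.x);
    lo[1]=std::min(lo[1],p.y); hi[1]=std::max(hi[1],p.y);
    lo[2]=std::min(lo[2],p.z); hi[2]=std::max(hi[2],p.z);
  }
  double dx=hi[0]-lo[0], dy=hi[1]-lo[1], dz=hi[2]-lo[2];
  return std::sqrt(dx*dx+dy*dy+dz*dz);
}

// ------------------------------------------------------- KMT simplification --
// Does the (possibly endpoint-excluded) segment P..Q pierce triangle A,B,C?
// Conservative: borderline contacts count as piercing (block removal).
static bool seg_hits_tri(const V3&A, const V3&B, const V3&C,
                         const V3&P, const V3&Q,
                         const V3* excl, double eps){
  V3 n = vcross(vsub(B,A), vsub(C,A));
  double n2 = vnorm2(n);
  V3 dir = vsub(Q,P);
  double denom = vdot(n, dir);
  double dP = vdot(n, vsub(A,P));
  double nn = std::sqrt(n2);
  if (std::fabs(denom) < 1e-14 * nn * std::sqrt(vnorm2(dir)) + 1e-300){
    // segment parallel to the triangle plane
    if (std::fabs(dP) > eps * nn) return false;      // clearly off-plane
    // coplanar: 2D overlap test in the plane spanned by (e1, e2)
    V3 e1 = vsub(B,A);
    double e1n = std::sqrt(vnorm2(e1));
    if (e1n < 1e-300) return true;                   // degenerate, conservative
    e1 = {e1.x/e1n, e1.y/e1n, e1.z/e1n};
    V3 nv = {n.x/nn, n.y/nn, n.z/nn};
    V3 e2 = vcross(nv, e1);
    auto to2 = [&](const V3& p, double& u, double& v){
      V3 r = vsub(p, A); u = vdot(r, e1); v = vdot(r, e2);
    };
    double ax,ay,bx,by,cx,cy,px2,py2,qx2,qy2,ex=1e300,ey=1e300;
    to2(A,ax,ay); to2(B,bx,by); to2(C,cx,cy); to2(P,px2,py2); to2(Q,qx2,qy2);
    bool have_excl = excl != nullptr;
    if (have_excl) to2(*excl, ex, ey);
    auto near_excl = [&](double x, double y){
      return have_excl && (x-ex)*(x-ex)+(y-ey)*(y-ey) < eps*eps;
    };
    auto inside = [&](double x, double y){
      double o1 = (bx-ax)*(y-ay) - (by-ay)*(x-ax);
      double o2 = (cx-bx)*(y-by) - (cy-by)*(x-bx);
      double o3 = (ax-cx)*(y-cy) - (ay-cy)*(x-cx);
      double tol = eps * (std::fabs(bx-ax)+std::fabs(cx-bx)+std::fabs(ax-cx)+
                          std::fabs(by-ay)+std::fabs(cy-by)+std::fabs(ay-cy));
      return (o1 >= -tol && o2 >= -tol && o3 >= -tol) ||
             (o1 <= tol && o2 <= tol && o3 <= tol);
    };
    // segment endpoint strictly inside the triangle?
    if (inside(px2,py2) && !near_excl(px2,py2)) return true;
    if (inside(qx2,qy2) && !near_excl(qx2,qy2)) return true;
    // segment properly crossing a triangle edge (away from the excluded
    // contact)?
    auto cross_edge = [&](double x1,double y1,double x2,double y2){
      double rx = qx2-px2, ry = qy2-py2, sx = x2-x1, sy = y2-y1;
      double den = rx*sy - ry*sx;
      if (std::fabs(den) < 1e-300) return false;
      double t = ((x1-px2)*sy - (y1-py2)*sx)/den;
      double u = ((x1-px2)*ry - (y1-py2)*rx)/den;
      if (t < -1e-12 || t > 1+1e-12 || u < -1e-12 || u > 1+1e-12) return false;
      double xx = px2 + t*rx, yy = py2 + t*ry;
      return !near_excl(xx, yy);
    };
    if (cross_edge(ax,ay,bx,by) || cross_edge(bx,by,cx,cy) ||
        cross_edge(cx,cy,ax,ay)) return true;
    return false;
  }
  double s = dP / denom;
  if (s < -1e-12 || s > 1.0 + 1e-12) return false;
  V3 X = {P.x + s*dir.x, P.y + s*dir.y, P.z + s*dir.z};
  if (excl){
    V3 dX = vsub(X, *excl);
    if (vnorm2(dX) < eps*eps) return false;          // contact only at shared vertex
  }
  // inclusive barycentric test
  V3 v0 = vsub(B,A), v1 = vsub(C,A), v2 = vsub(X,A);
  double d00 = vdot(v0,v0), d01 = vdot(v0,v1), d11 = vdot(v1,v1);
  double d20 = vdot(v2,v0), d21 = vdot(v2,v1);
  double den = d00*d11 - d01*d01;
  if (den <= 0.0) return true;                       // degenerate: be conservative
  double u = (d11*d20 - d01*d21)/den;
  double v = (d00*d21 - d01*d20)/den;
  double tol = 1e-10;
  return (u >= -tol) && (v >= -tol) && (u + v <= 1.0 + tol);
}

// iterative KMT to a fixed point (or the 3-bead floor); returns kept indices
static std::vector<int> kmt_core(const std::vector<V3>& P, double eps){
  int N = (int)P.size();
  std::vector<int> nxt(N), prv(N);
  std::vector<char> alive(N, 1);
  for (int i = 0; i < N; ++i){ nxt[i] = (i+1)%N; prv[i] = (i+N-1)%N; }
  int count = N;
  bool changed = true;
  while (changed && count > 3){
    changed = false;
    int i = 0;
    while (!alive[i]) i = (i+1)%N;
    int steps = count;
    for (int k = 0; k < steps && count > 3; ++k){
      int a = prv[i], b = nxt[i];
      const V3 &A = P[a], &Bv = P[i], &C = P[b];
      V3 n = vcross(vsub(Bv,A), vsub(C,A));
      bool removable;
      if (vnorm2(n) < 1e-24){        // collinear/degenerate triangle
        removable = true;
      } else {
        removable = true;
        // bounding box of the triangle for quick rejection
        double lox = std::min(std::min(A.x,Bv.x),C.x) - eps, hix = std::max(std::max(A.x,Bv.x),C.x) + eps;
        double loy = std::min(std::min(A.y,Bv.y),C.y) - eps, hiy = std::max(std::max(A.y,Bv.y),C.y) + eps;
        double loz = std::min(std::min(A.z,Bv.z),C.z) - eps, hiz = std::max(std::max(A.z,Bv.z),C.z) + eps;
        // walk all segments except the two triangle edges (a,i), (i,b);
        // segments sharing vertex a or b are tested with that contact excluded
        for (int u = b; removable; ){
          int v = nxt[u];
          const V3 &Pu = P[u], &Qv = P[v];
          bool rej = (std::max(Pu.x,Qv.x) < lox) || (std::min(Pu.x,Qv.x) > hix) ||
                     (std::max(Pu.y,Qv.y) < loy) || (std::min(Pu.y,Qv.y) > hiy) ||
                     (std::max(Pu.z,Qv.z) < loz) || (std::min(Pu.z,Qv.z) > hiz);
          if (!rej){
            const V3* excl = (u == b) ? &C : (v == a ? &A : nullptr);
            if (seg_hits_tri(A, Bv, C, Pu, Qv, excl, eps)) removable = false;
          }
          if (v == a) break;
          u = v;
        }
      }
      int advance = nxt[i];
      if (removable){
        alive[i] = 0;
        nxt[a] = b; prv[b] = a;
        --count;
        changed = true;
      }
      i = advance;
    }
  }
  std::vector<int> keep;
  keep.reserve(count);
  int i0 = 0;
  while (!alive[i0]) ++i0;
  int i = i0;
  do { keep.push_back(i); i = nxt[i]; } while (i != i0);
  return keep;
}

static std::vector<V3> as_points(const NumericMatrix& pos){
  int N = pos.nrow();
  std::vector<V3> P(N);
  bool flat = pos.ncol() == 2;
  for (int i = 0; i < N; ++i)
    P[i] = {pos(i,0), pos(i,1), flat ? 0.0 : pos(i,2)};
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_kmt(NumericMatrix pos, double eps_rel){
  std::vector<V3> P = as_points(pos);
  double eps = eps_rel * ring_diameter(P);
  std::vector<int> keep = kmt_core(P, eps);
  NumericMatrix out((int)keep.size(), 3);
  for (size_t r = 0; r < keep.size(); ++r){
    out(r,0) = P[keep[r]].x; out(r,1) = P[keep[r]].y; out(r,2) = P[keep[r]].z;
  }
  return out;
}

// ------------------------------------------------- projection -> diagram --
struct Crossing { int seg_a, seg_b; double ta, tb; int over_is_a; int sign; };

struct DiagramResult {
  bool ok;
  std::string reason;
  // per crossing: over_arc, under_in, under_out, sign (0-based arcs)
  std::vector<int> over_arc, under_in, under_out, sign;
};

static bool extract_crossings(const std::vector<V3>& P, const V3& w,
                              double eps, std::vector<Crossing>& out,
                              std::string& reason){
  int M = (int)P.size();
  // orthonormal frame (u, v, w)
  V3 e = (std::fabs(w.x) < 0.9) ? V3{1,0,0} : V3{0,1,0};
  V3 u = vcross(w, e);
  double un = std::sqrt(vnorm2(u));
  u = {u.x/un, u.y/un, u.z/un};
  V3 v = vcross(w, u);
  std::vector<double> px(M), py(M), ph(M);
  for (int i = 0; i < M; ++i){
    px[i] = vdot(P[i], u); py[i] = vdot(P[i], v); ph[i] = vdot(P[i], w);
  }
  out.clear();
  for (int i = 0; i < M; ++i){
    int i2 = (i+1)%M;
    double rx = px[i2]-px[i], ry = py[i2]-py[i];
    for (int j = i+2; j < M; ++j){
      if (i == 0 && j == M-1) continue;              // adjacent via closure
      int j2 = (j+1)%M;
      double sx = px[j2]-px[j], sy = py[j2]-py[j];
      double denom = rx*sy - ry*sx;
      double qpx = px[j]-px[i], qpy = py[j]-py[i];
      if (std::fabs(denom) < 1e-13 * std::sqrt((rx*rx+ry*ry)*(sx*sx+sy*sy)) + 1e-300){
        // near-parallel projected segments: degenerate only if they can overlap
        double lo1x = std::min(px[i],px[i2]), hi1x = std::max(px[i],px[i2]);
        double lo2x = std::min(px[j],px[j2]), hi2x = std::max(px[j],px[j2]);
        double lo1y = std::min(py[i],py[i2]), hi1y = std::max(py[i],py[i2]);
        double lo2y = std::min(py[j],py[j2]), hi2y = std::max(py[j],py[j2]);
        if (hi1x < lo2x - eps || hi2x < lo1x - eps ||
            hi1y < lo2y - eps || hi2y < lo1y - eps) continue;
        // overlapping near-parallel: check actual proximity via cross distance
        double dist = std::fabs(qpx*ry - qpy*rx) / (std::sqrt(rx*rx+ry*ry) + 1e-300);
        if (dist > eps) continue;
        reason = "near-parallel projected segments";
        return false;
      }
      double t = (qpx*sy - qpy*sx)/denom;
      double s = (qpx*ry - qpy*rx)/denom;
      double li = std::sqrt(rx*rx+ry*ry), lj = std::sqrt(sx*sx+sy*sy);
      double tol_i = eps/(li + 1e-300), tol_j = eps/(lj + 1e-300);
      if (t < -tol_i || t > 1+tol_i || s < -tol_j || s > 1+tol_j) continue;
      if (t < tol_i || t > 1-tol_i || s < tol_j || s > 1-tol_j){
        reason = "crossing too close to a vertex";
        return false;
      }
      double h1 = ph[i] + t*(ph[i2]-ph[i]);
      double h2 = ph[j] + s*(ph[j2]-ph[j]);
      if (std::fabs(h1 - h2) < eps){
        reason = "over/under depths not separated";
        return false;
      }
      Crossing c;
      c.seg_a = i; c.seg_b = j; c.ta = t; c.tb = s;
      c.over_is_a = (h1 > h2) ? 1 : 0;
      // crossing sign from (tangent_over x tangent_under) . w
      double cr = c.over_is_a ? (rx*sy - ry*sx) : (sx*ry - sy*rx);
      c.sign = (cr > 0) ? 1 : -1;
      out.push_back(c);
    }
  }
  return true;
}

static bool build_diagram_core(const std::vector<V3>& P, const V3& w,
                               double eps, DiagramResult& D){
  std::vector<Crossing> cr;
  D.ok = false;
  if (!extract_crossings(P, w, eps, cr, D.reason)) return false;
  int n = (int)cr.size();
  D.over_arc.assign(n,0); D.under_in.assign(n,0);
  D.under_out.assign(n,0); D.sign.assign(n,0);
  if (n == 0){ D.ok = true; return true; }
  // events along the curve: (segment, parameter, crossing id, role under?)
  struct Ev { int seg; double t; int id; int under; };
  std::vector<Ev> ev;
  ev.reserve(2*n);
  for (int c = 0; c < n; ++c){
    ev.push_back({cr[c].seg_a, cr[c].ta, c, cr[c].over_is_a ? 0 : 1});
    ev.push_back({cr[c].seg_b, cr[c].tb, c, cr[c].over_is_a ? 1 : 0});
  }
  std::sort(ev.begin(), ev.end(), [](const Ev&a, const Ev&b){
    return a.seg < b.seg || (a.seg == b.seg && a.t < b.t);
  });
  for (size_t k = 1; k < ev.size(); ++k){
    if (ev[k].seg == ev[k-1].seg && (ev[k].t - ev[k-1].t) < 1e-10){
      D.reason = "coincident crossing points";
      return false;
    }
  }
  int seen = 0;
  for (const Ev& e : ev){
    if (e.under){
      D.under_in[e.id] = seen % n;
      D.under_out[e.id] = (seen + 1) % n;
      ++seen;
    } else {
      D.over_arc[e.id] = seen % n;
    }
  }
  for (int c = 0; c < n; ++c) D.sign[c] = cr[c].sign;
  D.ok = true;
  return true;
}

// [[Rcpp::export]]
List cpp_diagram(NumericMatrix pos, NumericVector dir, double eps_rel){
  std::vector<V3> P = as_points(pos);
  double eps = eps_rel * ring_diameter(P);
  V3 w = {dir[0], dir[1], dir[2]};
  double wn = std::sqrt(vnorm2(w));
  w = {w.x/wn, w.y/wn, w.z/wn};
  DiagramResult D;
  if (!build_diagram_core(P, w, eps, D))
    return List::create(_["ok"] = false, _["reason"] = D.reason);
  int n = (int)D.over_arc.size();
  IntegerMatrix cm(n, 4);
  for (int c = 0; c < n; ++c){
    cm(c,0) = D.over_arc[c] + 1; cm(c,1) = D.under_in[c] + 1;
    cm(c,2) = D.under_out[c] + 1; cm(c,3) = D.sign[c];
  }
  return List::create(_["ok"] = true, _["crossings"] = cm, _["n_arcs"] = n);
}

// ------------------------------------------------ Alexander determinant --
// Bareiss fraction-free elimination over int64 with __int128 overflow guard.
// Returns true on success (det exact); false if any entry would overflow.
static bool bareiss_int64(std::vector<int64_t>& M, int n, int64_t& det){
  if (n <= 0){ det = 1; return true; }
  const __int128 LIM = (__int128)INT64_MAX;
  int64_t prev = 1;
  int sgn = 1;
  for (int k = 0; k < n-1; ++k){
    if (M[(size_t)k*n+k] == 0){
      int p = -1;
      for (int r = k+1; r < n; ++r) if (M[(size_t)r*n+k] != 0){ p = r; break; }
      if (p < 0){ det = 0; return true; }
      for (int c = k; c < n; ++c) std::swap(M[(size_t)k*n+c], M[(size_t)p*n+c]);
      sgn = -sgn;
    }
    for (int i = k+1; i < n; ++i){
      for (int j = k+1; j < n; ++j){
        __int128 t = (__int128)M[(size_t)i*n+j]*M[(size_t)k*n+k]
                   - (__int128)M[(size_t)i*n+k]*M[(size_t)k*n+j];
        t /= prev;                                  // exact division (Bareiss)
        if (t > LIM || t < -LIM) return false;
        M[(size_t)i*n+j] = (int64_t)t;
      }
      M[(size_t)i*n+k] = 0;
    }
    prev = M[(size_t)k*n+k];
  }
  det = sgn * M[(size_t)(n-1)*n+(n-1)];
  return true;
}

// determinant residue mod prime p (p < 2^25 so products stay well inside int64)
static int64_t moddet(const std::vector<int64_t>& M0, int n, int64_t p){
  if (n <= 0) return 1 % p;
  std::vector<int64_t> M(M0);
  for (auto& x : M){ x %= p; if (x < 0) x += p; }
  auto powmod = [&](int64_t b, int64_t e){
    int64_t r = 1; b %= p;
    while (e){ if (e & 1) r = (r*b) % p; b = (b*b) % p; e >>= 1; }
    return r;
  };
  int64_t det = 1;
  for (int k = 0; k < n; ++k){
    int piv = -1;
    for (int r = k; r < n; ++r) if (M[(size_t)r*n+k] != 0){ piv = r; break; }
    if (piv < 0) return 0;
    if (piv != k){
      for (int c = k; c < n; ++c) std::swap(M[(size_t)k*n+c], M[(size_t)piv*n+c]);
      det = p - det;
    }
    int64_t pk = M[(size_t)k*n+k];
    det = (det * pk) % p;
    int64_t inv = powmod(pk, p-2);
    for (int i = k+1; i < n; ++i){
      int64_t f = (M[(size_t)i*n+k] * inv) % p;
      if (f == 0) continue;
      for (int j = k; j < n; ++j){
        int64_t t = M[(size_t)i*n+j] - f * M[(size_t)k*n+j] % p;
        t %= p; if (t < 0) t += p;
        M[(size_t)i*n+j] = t;
      }
    }
  }
  return det;
}

// log |det| via LAPACK LU (through Armadillo); exact arithmetic not needed,
// only the magnitude scale
static double logabsdet_f(const std::vector<int64_t>& M0, int n){
  if (n <= 0) return 0.0;
  arma::mat A(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) A(i,j) = (double)M0[(size_t)i*n+j];
  double val; double sgn;
  arma::log_det(val, sgn, A);
  if (!std::isfinite(val)) return -1e308;  // numerically singular
  return val;
}

struct DetCall { double det; bool trivial; bool exact; };

// Decision procedure for |Delta(-1)|:
//  1. exact int64 Bareiss when feasible;
//  2. otherwise LAPACK log-determinant for the magnitude, plus determinant
//     residues modulo 25-bit primes: |det| == 1 iff log|det| ~ 0 and both
//     residues are +-1 (joint failure probability < 2^-48 and additionally
//     requires a log-determinant error > 0.5, which does not occur for
//     integer matrices of this size); exact value reconstructed by CRT
//     whenever it fits a double (< 2^53), NA otherwise.
static DetCall alexander_decision(std::vector<int64_t>& M, int n){
  DetCall r;
  if (n <= 0){ r.det = 1; r.trivial = true; r.exact = true; return r; }
  if (n <= 120){
    std::vector<int64_t> Mc(M);
    int64_t d;
    if (bareiss_int64(Mc, n, d)){
      double ad = std::fabs((double)d);
      int64_t a = d < 0 ? -d : d;
      r.trivial = (a == 1);
      r.det = (a <= (int64_t(1) << 53)) ? ad : NA_REAL;
      r.exact = true;
      return r;
    }
  }
  const int64_t P1 = 33554393, P2 = 33554383, P3 = 33554371;  // 25-bit primes
  double ld = logabsdet_f(M, n);
  int64_t r1 = moddet(M, n, P1), r2 = moddet(M, n, P2);
  bool pm1 = (r1 == 1 || r1 == P1-1) && (r2 == 1 || r2 == P2-1);
  r.exact = false;
  if (ld < 0.55 && pm1){ r.trivial = true; r.det = 1.0; return r; }
  r.trivial = false;
  if (ld < 36.0){
    // |det| < e^36 < 2^52: reconstruct exactly from three residues
    int64_t r3 = moddet(M, n, P3);
    __int128 Mprod = (__int128)P1*P2*P3;
    // CRT by successive substitution
    auto inv = [](int64_t a, int64_t p){
      int64_t r = 1, b = a % p, e = p-2;
      while (e){ if (e & 1) r = (r*b) % p; b = (b*b) % p; e >>= 1; }
      return r;
    };
    __int128 x = r1 % P1;
    {
      int64_t t = ((r2 - (int64_t)(x % P2)) % P2 + P2) % P2;
      t = (t * inv(P1 % P2, P2)) % P2;
      x += (__int128)t * P1;
    }
    {
      __int128 m12 = (__int128)P1*P2;
      int64_t xm = (int64_t)(x % P3);
      int64_t t = ((r3 - xm) % P3 + P3) % P3;
      t = (t * inv((int64_t)(m12 % P3), P3)) % P3;
      x += (__int128)t * m12;
    }
    if (x > Mprod/2) x -= Mprod;           // centered residue
    __int128 ax = x < 0 ? -x : x;
    r.det = (ax <= ((__int128)1 << 53)) ? (double)ax : NA_REAL;
    if (ax == 1) r.trivial = true;         // (cannot happen given ld >= 0.55)
  } else {
    r.det = NA_REAL;
  }
  return r;
}

static void alexander_matrix(const std::vector<int>& over,
                             const std::vector<int>& uin,
                             const std::vector<int>& uout,
                             const std::vector<int>& sgn,
                             std::vector<int64_t>& M, int& nred){
  int n = (int)over.size();
  nred = n - 1;
  if (nred <= 0) return;
  M.assign((size_t)nred*nred, 0);
  // Fox-calculus rows of the Wirtinger presentation evaluated at t = -1.
  // Positive relation x_out = x_over x_in x_over^-1 gives row
  // (1-t, t, -1) on (over, in, out); the negative relation
  // x_out = x_over^-1 x_in x_over gives (1 - 1/t, 1/t, -1). At t = -1
  // both reduce to (2, -1, -1) — the determinant is blind to mirror
  // images, so the handedness sign does not enter the matrix.
  // Last row and last column deleted; coincident arcs accumulate.
  (void)sgn;
  auto add = [&](int row, int col, int64_t v){
    if (row < nred && col < nred) M[(size_t)row*nred+col] += v;
  };
  for (int c = 0; c < n; ++c){
    add(c, over[c], 2); add(c, uin[c], -1); add(c, uout[c], -1);
  }
}

// [[Rcpp::export]]
List cpp_alexander(IntegerMatrix crossings, int n_arcs){
  int n = crossings.nrow();
  if (n_arcs != n && n > 0)
    stop("inconsistent diagram: number of arcs must equal number of crossings");
  std::vector<int> over(n), uin(n), uout(n), sgn(n);
  for (int c = 0; c < n; ++c){
    over[c] = crossings(c,0) - 1; uin[c] = crossings(c,1) - 1;
    uout[c] = crossings(c,2) - 1; sgn[c] = crossings(c,3);
    if (over[c] < 0 || over[c] >= std::max(n,1) ||
        uin[c] < 0 || uin[c] >= std::max(n,1) ||
        uout[c] < 0 || uout[c] >= std::max(n,1) ||
        (sgn[c] != 1 && sgn[c] != -1))
      stop("inconsistent diagram: arc indices out of range or invalid sign");
  }
  std::vector<int64_t> M;
  int nred;
  alexander_matrix(over, uin, uout, sgn, M, nred);
  DetCall d = alexander_decision(M, nred);
  return List::create(_["det"] = d.det, _["trivial"] = d.trivial,
                      _["exact"] = d.exact);
}

// -------------------------------------------------------- classification --
static List classify_one(std::vector<V3> P, bool simplify, double eps_rel,
                         int max_tries, uint64_t dir_seed){
  double diam = ring_diameter(P);
  double eps = eps_rel * diam;
  int n_before = (int)P.size();
  if (simplify){
    std::vector<int> keep = kmt_core(P, eps);
    std::vector<V3> Q; Q.reserve(keep.size());
    for (int i : keep) Q.push_back(P[i]);
    P.swap(Q);
    eps = eps_rel * ring_diameter(P);
  }
  DirGen g(dir_seed);
  DiagramResult D;
  bool got = false;
  for (int t = 0; t < max_tries; ++t){
    V3 w = g.unit();
    if (build_diagram_core(P, w, eps, D)){ got = true; break; }
  }
  if (!got)
    stop("no generic projection direction found after %d attempts (%s)",
         max_tries, D.reason.c_str());
  int n = (int)D.over_arc.size();
  std::vector<int64_t> M;
  int nred;
  alexander_matrix(D.over_arc, D.under_in, D.under_out, D.sign, M, nred);
  DetCall d = alexander_decision(M, nred);
  return List::create(_["det"] = d.det, _["trivial"] = d.trivial,
                      _["exact"] = d.exact, _["crossings"] = n,
                      _["n_beads"] = (int)P.size(),
                      _["n_beads_input"] = n_before);
}

// [[Rcpp::export]]
List cpp_classify(NumericMatrix pos, bool simplify, double eps_rel,
                  int max_tries, double dir_seed){
  return classify_one(as_points(pos), simplify, eps_rel, max_tries,
                      (uint64_t)dir_seed);
}

// Batch classification: R is N x (3*nconf), columns grouped per conformation.
// [[Rcpp::export]]
List cpp_classify_stack(NumericMatrix R, int nconf, bool simplify,
                        double eps_rel, int max_tries, double dir_seed){
  int N = R.nrow();
  LogicalVector trivial(nconf);
  NumericVector det(nconf);
  IntegerVector crossings(nconf), beads(nconf);
  for (int i = 0; i < nconf; ++i){
    std::vector<V3> P(N);
    for (int r = 0; r < N; ++r)
      P[r] = {R(r, 3*i), R(r, 3*i+1), R(r, 3*i+2)};
    List one = classify_one(std::move(P), simplify, eps_rel, max_tries,
                            (uint64_t)dir_seed + 0x9E3779B9ULL * (uint64_t)(i+1));
    trivial[i] = as<bool>(one["trivial"]);
    det[i] = as<double>(one["det"]);
    crossings[i] = as<int>(one["crossings"]);
    beads[i] = as<int>(one["n_beads"]);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["trivial"] = trivial, _["det"] = det,
                      _["crossings"] = crossings, _["n_beads"] = beads);
}

// --------------------------------------------------------- 2D intersection --
// any two non-adjacent segments of the closed 2D polygon intersect?
// touching within eps counts as intersecting.
static bool seg2_intersect(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy,
                           double eps){
  double rx = bx-ax, ry = by-ay, sx = dx-cx, sy = dy-cy;
  double o1 = rx*(cy-ay) - ry*(cx-ax);
  double o2 = rx*(dy-ay) - ry*(dx-ax);
  double o3 = sx*(ay-cy) - sy*(ax-cx);
  double o4 = sx*(by-cy) - sy*(bx-cx);
  double lr = std::sqrt(rx*rx+ry*ry), ls = std::sqrt(sx*sx+sy*sy);
  double e1 = eps*lr, e2 = eps*ls;
  if (((o1 > e1 && o2 < -e1) || (o1 < -e1 && o2 > e1)) &&
      ((o3 > e2 && o4 < -e2) || (o3 < -e2 && o4 > e2))) return true;
  // near-collinear / touching cases: point-on-segment within eps
  auto on_seg = [eps](double px, double py, double qx, double qy,
                      double xx, double yy){
    double vx = qx-px, vy = qy-py;
    double L2 = vx*vx + vy*vy;
    if (L2 < 1e-300) return (xx-px)*(xx-px)+(yy-py)*(yy-py) <= eps*eps;
    double t = ((xx-px)*vx + (yy-py)*vy)/L2;
    t = std::max(0.0, std::min(1.0, t));
    double ddx = xx-(px+t*vx), ddy = yy-(py+t*vy);
    return ddx*ddx + ddy*ddy <= eps*eps;
  };
  if (std::fabs(o1) <= e1 && on_seg(ax,ay,bx,by,cx,cy)) return true;
  if (std::fabs(o2) <= e1 && on_seg(ax,ay,bx,by,dx,dy)) return true;
  if (std::fabs(o3) <= e2 && on_seg(cx,cy,dx,dy,ax,ay)) return true;
  if (std::fabs(o4) <= e2 && on_seg(cx,cy,dx,dy,bx,by)) return true;
  return false;
}

static bool any_intersection_core(const std::vector<double>& x,
                                  const std::vector<double>& y,
                                  double eps, int& si, int& sj){
  int N = (int)x.size();
  for (int i = 0; i < N; ++i){
    int i2 = (i+1)%N;
    for (int j = i+2; j < N; ++j){
      if (i == 0 && j == N-1) continue;
      int j2 = (j+1)%N;
      if (seg2_intersect(x[i],y[i],x[i2],y[i2],x[j],y[j],x[j2],y[j2],eps)){
        si = i+1; sj = j+1;
        return true;
      }
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_any_intersection2d(NumericMatrix pos, double eps_rel){
  int N = pos.nrow();
  std::vector<double> x(N), y(N);
  double lox = pos(0,0), hix = lox, loy = pos(0,1), hiy = loy;
  for (int i = 0; i < N; ++i){
    x[i] = pos(i,0); y[i] = pos(i,1);
    lox = std::min(lox,x[i]); hix = std::max(hix,x[i]);
    loy = std::min(loy,y[i]); hiy = std::max(hiy,y[i]);
  }
  double diam = std::sqrt((hix-lox)*(hix-lox) + (hiy-loy)*(hiy-loy));
  int si = NA_INTEGER, sj = NA_INTEGER;
  bool hit = any_intersection_core(x, y, eps_rel*diam, si, sj);
  return List::create(_["intersects"] = hit, _["seg_i"] = si, _["seg_j"] = sj);
}

// Batch: R is N x (2*nconf); returns logical "knotted" per conformation.
// [[Rcpp::export]]
LogicalVector cpp_intersect_stack2d(NumericMatrix R, int nconf, double eps_rel){
  int N = R.nrow();
  LogicalVector out(nconf);
  std::vector<double> x(N), y(N);
  for (int i = 0; i < nconf; ++i){
    double lox = R(0,2*i), hix = lox, loy = R(0,2*i+1), hiy = loy;
    for (int r = 0; r < N; ++r){
      x[r] = R(r,2*i); y[r] = R(r,2*i+1);
      lox = std::min(lox,x[r]); hix = std::max(hix,x[r]);
      loy = std::min(loy,y[r]); hiy = std::max(hiy,y[r]);
    }
    double diam = std::sqrt((hix-lox)*(hix-lox) + (hiy-loy)*(hiy-loy));
    int si, sj;
    out[i] = any_intersection_core(x, y, eps_rel*diam, si, sj);
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
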
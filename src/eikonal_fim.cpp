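// Anisotropic Eikonal solver on tetrahedral meshes: fast-iterative
// (active-list, label-correcting) scheme. Converges to the viscosity
// solution of |grad(phi)|_{D^-1} = 1 with per-tet symmetric tensor D
// (squared conduction speeds along the local fiber frame).
//
// The local update at a vertex x of a tet minimizes, over the opposite
// face conv{y1,y2,y3},
//     t(y) + sqrt((x-y)^T M (x-y)),   M = D^{-1},
// solved exactly on the face interior (KKT quadratic), the three edges,
// and the three vertices.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Sym3 {
  double a, b, c, d, e, f; // [[a,b,c],[b,d,e],[c,e,f]]
};

static inline void mulM(const Sym3 &M, const double v[3], double out[3]) {
  out[0] = M.a * v[0] + M.b * v[1] + M.c * v[2];
  out[1] = M.b * v[0] + M.d * v[1] + M.e * v[2];
  out[2] = M.c * v[0] + M.e * v[1] + M.f * v[2];
}

static inline double quadM(const Sym3 &M, const double v[3]) {
  double mv[3];
  mulM(M, v, mv);
  return v[0] * mv[0] + v[1] * mv[1] + v[2] * mv[2];
}

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// 1-D minimization along an edge: min_{s in [0,1]} (1-s) t1 + s t2 +
// sqrt(q(s)), e(s) = e1 + s (e2 - e1), q = e^T M e.
static double edgeUpdate(const Sym3 &M, const double e1[3], const double e2[3],
                         double t1, double t2) {
  double d[3] = {e2[0] - e1[0], e2[1] - e1[1], e2[2] - e1[2]};
  double A = quadM(M, d);              // s^2 coeff
  double Me1[3];
  mulM(M, e1, Me1);
  double B = dot3(d, Me1);             // s coeff (x2)
  double C = quadM(M, e1);
  double a = t2 - t1;
  double best = INF;
  // endpoints
  double v0 = t1 + std::sqrt(C);
  double q1 = A + 2.0 * B + C;
  double v1 = t2 + std::sqrt(q1 > 0 ? q1 : 0.0);
  best = v0 < v1 ? v0 : v1;
  // interior stationary point: a + (A s + B)/sqrt(q) = 0
  // => a^2 q = (A s + B)^2 with sign(A s + B) = -sign(a)
  double aa = a * a;
  double qa = A * (A - aa);
  double qb = 2.0 * B * (A - aa);
  double qc = B * B - aa * C;
  if (std::fabs(qa) > 1e-300) {
    double disc = qb * qb - 4.0 * qa * qc;
    if (disc >= 0) {
      double sd = std::sqrt(disc);
      for (int k = 0; k < 2; ++k) {
        double s = (-qb + (k ? sd : -sd)) / (2.0 * qa);
        if (s > 0.0 && s < 1.0) {
          double ee[3] = {e1[0] + s * d[0], e1[1] + s * d[1], e1[2] + s * d[2]};
          double q = quadM(M, ee);
          if (q > 0) {
            double val = (1.0 - s) * t1 + s * t2 + std::sqrt(q);
            if (val < best) best = val;
          }
        }
      }
    }
  }
  return best;
}

// Face (2-D) stationary point, solved via the reduced quadratic in
// S = sqrt(q): u = u0 - B a S with B = (G^T M G)^{-1}; returns INF if the
// stationary point is infeasible.
static double faceUpdate(const Sym3 &M, const double x[3], const double y1[3],
                         const double y2[3], const double y3[3], double t1,
                         double t2, double t3) {
  double d1[3] = {y2[0] - y1[0], y2[1] - y1[1], y2[2] - y1[2]};
  double d2[3] = {y3[0] - y1[0], y3[1] - y1[1], y3[2] - y1[2]};
  double e0[3] = {x[0] - y1[0], x[1] - y1[1], x[2] - y1[2]};
  double Md1[3], Md2[3], Me0[3];
  mulM(M, d1, Md1);
  mulM(M, d2, Md2);
  mulM(M, e0, Me0);
  double g11 = dot3(d1, Md1), g12 = dot3(d1, Md2), g22 = dot3(d2, Md2);
  double h1 = dot3(d1, Me0), h2 = dot3(d2, Me0);
  double det = g11 * g22 - g12 * g12;
  if (std::fabs(det) < 1e-300) return INF;
  double a1 = t2 - t1, a2 = t3 - t1;
  // u0 = Ginv * h ; Ba = Ginv * a
  double u01 = (g22 * h1 - g12 * h2) / det;
  double u02 = (g11 * h2 - g12 * h1) / det;
  double Ba1 = (g22 * a1 - g12 * a2) / det;
  double Ba2 = (g11 * a2 - g12 * a1) / det;
  // e(S) = r0 + r1 S
  double r0[3], r1[3];
  for (int i = 0; i < 3; ++i) {
    r0[i] = e0[i] - (u01 * d1[i] + u02 * d2[i]);
    r1[i] = Ba1 * d1[i] + Ba2 * d2[i];
  }
  double A = quadM(M, r1) - 1.0;
  double Mr1[3];
  mulM(M, r1, Mr1);
  double Bq = dot3(r0, Mr1);
  double Cq = quadM(M, r0);
  double best = INF;
  double roots[2];
  int nr = 0;
  if (std::fabs(A) < 1e-14) {
    if (std::fabs(Bq) > 1e-300) {
      roots[nr++] = -Cq / (2.0 * Bq);
    }
  } else {
    double disc = Bq * Bq - A * Cq;
    if (disc >= 0) {
      double sd = std::sqrt(disc);
      roots[nr++] = (-Bq + sd) / A;
      roots[nr++] = (-Bq - sd) / A;
    }
  }
  for (int k = 0; k < nr; ++k) {
    double S = roots[k];
    if (!(S > 0.0)) continue;
    double u1 = u01 - Ba1 * S, u2 = u02 - Ba2 * S;
    if (u1 <= 0.0 || u2 <= 0.0 || u1 + u2 >= 1.0) continue;
    double val = t1 + a1 * u1 + a2 * u2 + S;
    if (val < best) best = val;
  }
  return best;
}

// Full local update for vertex x against face (y1,y2,y3).
static double localUpdate(const Sym3 &M, const double x[3], const double y1[3],
                          const double y2[3], const double y3[3], double t1,
                          double t2, double t3) {
  double best = INF;
  double e1[3] = {x[0] - y1[0], x[1] - y1[1], x[2] - y1[2]};
  double e2[3] = {x[0] - y2[0], x[1] - y2[1], x[2] - y2[2]};
  double e3[3] = {x[0] - y3[0], x[1] - y3[1], x[2] - y3[2]};
  if (t1 < INF && t2 < INF) {
    double v = edgeUpdate(M, e1, e2, t1, t2);
    if (v < best) best = v;
  }
  if (t1 < INF && t3 < INF) {
    double v = edgeUpdate(M, e1, e3, t1, t3);
    if (v < best) best = v;
  }
  if (t2 < INF && t3 < INF) {
    double v = edgeUpdate(M, e2, e3, t2, t3);
    if (v < best) best = v;
  }
  if (t1 < INF && t2 < INF && t3 < INF) {
    double v = faceUpdate(M, x, y1, y2, y3, t1, t2, t3);
    if (v < best) best = v;
  }
  // single-vertex fallbacks (also covers cases with only one finite time)
  if (t1 < INF) {
    double v = t1 + std::sqrt(quadM(M, e1));
    if (v < best) best = v;
  }
  if (t2 < INF) {
    double v = t2 + std::sqrt(quadM(M, e2));
    if (v < best) best = v;
  }
  if (t3 < INF) {
    double v = t3 + std::sqrt(quadM(M, e3));
    if (v < best) best = v;
  }
  return best;
}

// [[Rcpp::export(name = ".fim_local")]]
double fim_local(NumericVector x, NumericVector y1, NumericVector y2,
                 NumericVector y3, NumericVector Mp, double t1, double t2,
                 double t3) {
  Sym3 M;
  M.a = Mp[0];
  M.b = Mp[1];
  M.c = Mp[2];
  M.d = Mp[3];
  M.e = Mp[4];
  M.f = Mp[5];
  double xx[3] = {x[0], x[1], x[2]};
  double a1[3] = {y1[0], y1[1], y1[2]};
  double a2[3] = {y2[0], y2[1], y2[2]};
  double a3[3] = {y3[0], y3[1], y3[2]};
  return localUpdate(M, xx, a1, a2, a3, t1, t2, t3);
}

// [[Rcpp::export(name = ".fim_solve")]]
NumericVector fim_solve(NumericMatrix coords, IntegerMatrix tets,
                        NumericMatrix tensorInv, IntegerVector sourceIdx,
                        NumericVector sourceTime, double tol,
                        NumericVector initTimes) {
  int nv = coords.nrow();
  int nt = tets.nrow();
  std::vector<double> X(3 * nv);
  for (int i = 0; i < nv; ++i) {
    X[3 * i] = coords(i, 0);
    X[3 * i + 1] = coords(i, 1);
    X[3 * i + 2] = coords(i, 2);
  }
  std::vector<Sym3> M(nt);
  for (int t = 0; t < nt; ++t) {
    M[t].a = tensorInv(t, 0);
    M[t].b = tensorInv(t, 1);
    M[t].c = tensorInv(t, 2);
    M[t].d = tensorInv(t, 3);
    M[t].e = tensorInv(t, 4);
    M[t].f = tensorInv(t, 5);
  }
  // vertex -> incident tets (CSR)
  std::vector<int> cnt(nv, 0);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 4; ++k) cnt[tets(t, k)]++;
  std::vector<int> off(nv + 1, 0);
  for (int i = 0; i < nv; ++i) off[i + 1] = off[i] + cnt[i];
  std::vector<int> adj(off[nv]);
  std::vector<int> pos(off.begin(), off.end() - 1);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 4; ++k) adj[pos[tets(t, k)]++] = t;

  std::vector<double> phi(nv, INF);
  if (initTimes.size() == nv) {
    for (int i = 0; i < nv; ++i) {
      double v = initTimes[i];
      phi[i] = R_finite(v) ? v : INF;
    }
  }
  std::vector<char> active(nv, 0);
  std::deque<int> list;
  for (int s = 0; s < sourceIdx.size(); ++s) {
    int i = sourceIdx[s];
    if (sourceTime[s] < phi[i]) phi[i] = sourceTime[s];
  }
  // activate neighbours of every finite vertex
  for (int i = 0; i < nv; ++i) {
    if (phi[i] < INF) {
      for (int p = off[i]; p < off[i + 1]; ++p) {
        int t = adj[p];
        for (int k = 0; k < 4; ++k) {
          int j = tets(t, k);
          if (!active[j]) {
            active[j] = 1;
            list.push_back(j);
          }
        }
      }
    }
  }

  int vids[4];
  long iter = 0, maxIter = 200L * (long)nv + 100000L;
  while (!list.empty() && iter < maxIter) {
    ++iter;
    int i = list.front();
    list.pop_front();
    double old = phi[i];
    double best = old;
    for (int p = off[i]; p < off[i + 1]; ++p) {
      int t = adj[p];
      int m = 0;
      for (int k = 0; k < 4; ++k) {
        int j = tets(t, k);
        if (j != i) vids[m++] = j;
      }
      if (m != 3) continue; // degenerate tet listing
      double v = localUpdate(M[t], &X[3 * i], &X[3 * vids[0]],
                             &X[3 * vids[1]], &X[3 * vids[2]], phi[vids[0]],
                             phi[vids[1]], phi[vids[2]]);
      if (v < best) best = v;
    }
    if (best < old - tol) {
      phi[i] = best;
      // keep active, and (re)activate neighbours
      list.push_back(i);
      for (int p = off[i]; p < off[i + 1]; ++p) {
        int t = adj[p];
        for (int k = 0; k < 4; ++k) {
          int j = tets(t, k);
          if (j != i && !active[j]) {
            active[j] = 1;
            list.push_back(j);
          }
        }
      }
    } else {
      if (best < old) phi[i] = best;
      active[i] = 0;
    }
  }

  NumericVector out(nv);
  for (int i = 0; i < nv; ++i) out[i] = phi[i] < INF ? phi[i] : R_PosInf;
  return out;
}
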
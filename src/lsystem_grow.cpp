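// Rule-based Y-branching core of the Purkinje L-system (stages 2 and 3).
// Steps are projected onto the endocardial surface (tangent plane of the
// nearest surface vertex, clamped to a capture distance), growing tips
// terminate early near foreign fibres (avoidance radius) or fuse into
// loops (capture radius, stage 2 only). Uses R's RNG for reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};

static inline V3 sub(const V3 &a, const V3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline V3 add(const V3 &a, const V3 &b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
static inline V3 scale(const V3 &a, double s) {
  return {a.x * s, a.y * s, a.z * s};
}
static inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(const V3 &a) {
  double n = norm(a);
  return n > 1e-12 ? scale(a, 1.0 / n) : V3{0, 0, 1};
}

// Rodrigues rotation about unit axis
static inline V3 rotate(const V3 &v, const V3 &k, double ang) {
  double c = std::cos(ang), s = std::sin(ang);
  V3 kv = cross(k, v);
  double kd = dot(k, v);
  return {v.x * c + kv.x * s + k.x * kd * (1 - c),
          v.y * c + kv.y * s + k.y * kd * (1 - c),
          v.z * c + kv.z * s + k.z * kd * (1 - c)};
}

struct Grid {
  double lox, loy, loz, cell;
  int dx, dy, dz;
  std::unordered_map<long, std::vector<int> > buckets;
  long key(const V3 &p) const {
    int i = (int)std::floor((p.x - lox) / cell);
    int j = (int)std::floor((p.y - loy) / cell);
    int k = (int)std::floor((p.z - loz) / cell);
    if (i < 0) i = 0;
    if (j < 0) j = 0;
    if (k < 0) k = 0;
    if (i >= dx) i = dx - 1;
    if (j >= dy) j = dy - 1;
    if (k >= dz) k = dz - 1;
    return (long)i + (long)dx * ((long)j + (long)dy * (long)k);
  }
  void insert(const V3 &p, int id) { buckets[key(p)].push_back(id); }
  template <class F>
  void forNear(const V3 &p, int ring, F f) const {
    int ci = (int)std::floor((p.x - lox) / cell);
    int cj = (int)std::floor((p.y - loy) / cell);
    int ck = (int)std::floor((p.z - loz) / cell);
    for (int i = ci - ring; i <= ci + ring; ++i) {
      if (i < 0 || i >= dx) continue;
      for (int j = cj - ring; j <= cj + ring; ++j) {
        if (j < 0 || j >= dy) continue;
        for (int k = ck - ring; k <= ck + ring; ++k) {
          if (k < 0 || k >= dz) continue;
          long key = (long)i + (long)dx * ((long)j + (long)dy * (long)k);
          auto it = buckets.find(key);
          if (it != buckets.end())
            for (int id : it->second) f(id);
        }
      }
    }
  }
};

static double truncNorm(double mean, double sd, bool positive) {
  if (sd <= 0) return mean;
  double k = 3.0;
  if (positive && mean - k * sd <= 0) k = 0.95 * mean / sd;
  double lo = mean - k * sd, hi = mean + k * sd;
  for (int it = 0; it < 1000; ++it) {
    double d = R::rnorm(mean, sd);
    if (d >= lo && d <= hi) return d;
  }
  return mean;
}

} // namespace

// [[Rcpp::export(name = ".grow_branches")]]
List grow_branches(NumericMatrix nodePos, IntegerVector nodeBranch,
                   IntegerVector nodeFusable, NumericMatrix tipMat,
                   NumericMatrix projPts, NumericMatrix projNrm, double cap,
                   double lenMean, double lenSd, double angMean,
                   double angSd, int segments, int maxBranches,
                   double avoidR, double loopR, bool spawnTips,
                   int branchCounter0) {
  int n0 = nodePos.nrow();
  int np = projPts.nrow();

  // bounding box over everything
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int r = 0; r < np; ++r)
    for (int c = 0; c < 3; ++c) {
      if (projPts(r, c) < lo[c]) lo[c] = projPts(r, c);
      if (projPts(r, c) > hi[c]) hi[c] = projPts(r, c);
    }
  double cell = 4.0;
  Grid pgrid, ngrid;
  for (Grid *g : {&pgrid, &ngrid}) {
    g->lox = lo[0] - 3 * cell;
    g->loy = lo[1] - 3 * cell;
    g->loz = lo[2] - 3 * cell;
    g->cell = cell;
    g->dx = (int)std::ceil((hi[0] - lo[0] + 6 * cell) / cell) + 1;
    g->dy = (int)std::ceil((hi[1] - lo[1] + 6 * cell) / cell) + 1;
    g->dz = (int)std::ceil((hi[2] - lo[2] + 6 * cell) / cell) + 1;
  }
  for (int r = 0; r < np; ++r)
    pgrid.insert({projPts(r, 0), projPts(r, 1), projPts(r, 2)}, r);

  std::vector<V3> pos(n0);
  std::vector<int> branch(nodeBranch.begin(), nodeBranch.end());
  std::vector<char> fusable(n0, 1);
  for (int r = 0; r < n0 && r < nodeFusable.size(); ++r)
    fusable[r] = (char)nodeFusable[r];
  for (int r = 0; r < n0; ++r) {
    pos[r] = {nodePos(r, 0), nodePos(r, 1), nodePos(r, 2)};
    ngrid.insert(pos[r], r);
  }
  std::vector<int> nearVert(n0, -1);
  std::vector<int> stageOf(n0, 0);
  std::vector<std::pair<int, int> > edges;
  std::vector<double> statLen, statAng;

  auto nearestProj = [&](const V3 &p, int &vid) {
    double best = 1e300;
    vid = -1;
    for (int ring = 1; ring <= 8; ++ring) {
      pgrid.forNear(p, ring, [&](int id) {
        V3 q = {projPts(id, 0), projPts(id, 1), projPts(id, 2)};
        V3 d = sub(q, p);
        double d2 = dot(d, d);
        if (d2 < best) {
          best = d2;
          vid = id;
        }
      });
      if (vid >= 0 && std::sqrt(best) <= ring * cell) break;
    }
    return std::sqrt(best);
  };
  auto project = [&](const V3 &p, int &vid) {
    nearestProj(p, vid);
    if (vid < 0) return p;
    V3 xv = {projPts(vid, 0), projPts(vid, 1), projPts(vid, 2)};
    V3 nv = {projNrm(vid, 0), projNrm(vid, 1), projNrm(vid, 2)};
    V3 rel = sub(p, xv);
    V3 pp = sub(p, scale(nv, dot(rel, nv)));
    V3 d = sub(pp, xv);
    double dl = norm(d);
    if (dl > cap) pp = add(xv, scale(d, cap / dl));
    return pp;
  };

  // tips: columns nodeId (1-based), dir xyz, parentBranch, sibling
  struct Tip {
    int id, parent, sibling;
    V3 dir;
  };
  std::vector<Tip> tips;
  for (int r = 0; r < tipMat.nrow(); ++r)
    tips.push_back({(int)tipMat(r, 0) - 1,
                    (int)tipMat(r, 4), (int)tipMat(r, 5),
                    {tipMat(r, 1), tipMat(r, 2), tipMat(r, 3)}});

  int nBranches = 0;
  int branchCounter = branchCounter0;
  while (!tips.empty() && nBranches < maxBranches) {
    int pick = (int)std::floor(unif_rand() * tips.size());
    if (pick >= (int)tips.size()) pick = tips.size() - 1;
    Tip tip = tips[pick];
    tips[pick] = tips.back();
    tips.pop_back();
    // branch angle: untruncated Gaussian; a negative draw simply swaps
    // the handedness of the Y-split
    double angDeg = R::rnorm(angMean, angSd);
    double ang = angDeg * M_PI / 180.0;
    int sib[2] = {-1, -1};
    for (int side = 0; side < 2 && nBranches < maxBranches; ++side) {
      double sgn = side == 0 ? 1.0 : -1.0;
      ++nBranches;
      int branchId = ++branchCounter;
      double len = truncNorm(lenMean, lenSd, true);
      statLen.push_back(len);
      statAng.push_back(angDeg);
      double step = len / segments;
      int pv = tip.id < n0 ? -1 : nearVert[tip.id];
      // tangent normal at the tip
      V3 nrm = {0, 0, 1};
      {
        int vq;
        V3 tp = pos[tip.id];
        nearestProj(tp, vq);
        if (vq >= 0)
          nrm = {projNrm(vq, 0), projNrm(vq, 1), projNrm(vq, 2)};
        (void)pv;
      }
      V3 dir = rotate(tip.dir, nrm, sgn * ang / 2.0);
      dir = unit(sub(dir, scale(nrm, dot(dir, nrm))));
      V3 p = pos[tip.id];
      int prev = tip.id;
      int parentBranch = tip.id < (int)branch.size() ? branch[tip.id] : 0;
      bool alive = true;
      for (int sg = 0; sg < segments; ++sg) {
        V3 pn = add(p, scale(dir, step));
        int vid;
        pn = project(pn, vid);
        V3 dn = sub(pn, p);
        double nd = norm(dn);
        if (nd < 1e-9) break;
        dir = scale(dn, 1.0 / nd);
        double rq = std::max(avoidR, loopR);
        if (rq > 0) {
          int jmin = -1;
          double dmin2 = 1e300;
          ngrid.forNear(pn, 1, [&](int id) {
            int bId = branch[id];
            if (bId == branchId || bId == parentBranch || bId == sib[0] ||
                bId == sib[1] || id == tip.id)
              return;
            V3 d = sub(pos[id], pn);
            double d2 = dot(d, d);
            if (d2 < dmin2) {
              dmin2 = d2;
              jmin = id;
            }
          });
          if (jmin >= 0) {
            double dmin = std::sqrt(dmin2);
            bool canFuse = jmin >= (int)fusable.size() || fusable[jmin];
            if (loopR > 0 && dmin <= loopR && canFuse) {
              edges.push_back({prev, jmin});
              alive = false;
              break;
            }
            if (avoidR > 0 && dmin <= avoidR) {
              alive = false;
              break;
            }
          }
        }
        int id = pos.size();
        pos.push_back(pn);
        branch.push_back(branchId);
        nearVert.resize(pos.size(), -1);
        nearVert[id] = vid;
        stageOf.resize(pos.size(), 0);
        ngrid.insert(pn, id);
        edges.push_back({prev, id});
        prev = id;
        p = pn;
      }
      sib[side] = branchId;
      if (alive && prev != tip.id && spawnTips)
        tips.push_back({prev, parentBranch, branchId, dir});
    }
  }

  int nNew = pos.size() - n0;
  NumericMatrix outPos(nNew, 3);
  IntegerVector outBranch(nNew), outNear(nNew);
  for (int r = 0; r < nNew; ++r) {
    outPos(r, 0) = pos[n0 + r].x;
    outPos(r, 1) = pos[n0 + r].y;
    outPos(r, 2) = pos[n0 + r].z;
    outBranch[r] = branch[n0 + r];
    outNear[r] = nearVert[n0 + r] + 1; // back to 1-based proj index
  }
  IntegerMatrix outEdges(edges.size(), 2);
  for (size_t r = 0; r < edges.size(); ++r) {
    outEdges(r, 0) = edges[r].first + 1;
    outEdges(r, 1) = edges[r].second + 1;
  }
  return List::create(_["pos"] = outPos, _["branch"] = outBranch,
                      _["nearVert"] = outNear, _["edges"] = outEdges,
                      _["len"] = statLen, _["ang"] = statAng,
                      _["branchCounter"] = branchCounter);
}
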
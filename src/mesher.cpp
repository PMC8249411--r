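// Implicit-surface triangularization pipeline:
//   marching tetrahedra (Kuhn 6-tet cube subdivision) -> incremental
//   isotropic remeshing (split / collapse / flip / tangential smoothing)
//   -> Newton projection of vertices onto the zero set along the gradient.
// All steps are deterministic (index-ordered loops, no RNG).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <functional>
#include <array>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Implicit surface evaluation (quartic discocyte or quadric ellipsoid),
// optionally pre-composed with an inverse affine map: F_eff(x) = F(Minv x).
// Gradient by chain rule: grad_x = Minv^T gradF(Minv x).
// ---------------------------------------------------------------------------
struct Surface {
  int kind;            // 0 = quartic (P,Q,R), 1 = ellipsoid (a,b,c)
  double p0, p1, p2;
  bool hasM;
  double Minv[9];      // row-major

  void toLocal(const double* x, double* q) const {
    if (!hasM) { q[0]=x[0]; q[1]=x[1]; q[2]=x[2]; return; }
    q[0] = Minv[0]*x[0] + Minv[1]*x[1] + Minv[2]*x[2];
    q[1] = Minv[3]*x[0] + Minv[4]*x[1] + Minv[5]*x[2];
    q[2] = Minv[6]*x[0] + Minv[7]*x[1] + Minv[8]*x[2];
  }
  double value(const double* x) const {
    double q[3]; toLocal(x, q);
    if (kind == 0) {
      double s = q[0]*q[0] + q[1]*q[1] + q[2]*q[2];
      return s*s + p0*(q[0]*q[0] + q[1]*q[1]) + p1*q[2]*q[2] + p2;
    }
    return q[0]*q[0]/(p0*p0) + q[1]*q[1]/(p1*p1) + q[2]*q[2]/(p2*p2) - 1.0;
  }
  void grad(const double* x, double* g) const {
    double q[3]; toLocal(x, q);
    double gq[3];
    if (kind == 0) {
      double s = q[0]*q[0] + q[1]*q[1] + q[2]*q[2];
      gq[0] = 4.0*s*q[0] + 2.0*p0*q[0];
      gq[1] = 4.0*s*q[1] + 2.0*p0*q[1];
      gq[2] = 4.0*s*q[2] + 2.0*p1*q[2];
    } else {
      gq[0] = 2.0*q[0]/(p0*p0);
      gq[1] = 2.0*q[1]/(p1*p1);
      gq[2] = 2.0*q[2]/(p2*p2);
    }
    if (!hasM) { g[0]=gq[0]; g[1]=gq[1]; g[2]=gq[2]; return; }
    // Minv^T * gq
    g[0] = Minv[0]*gq[0] + Minv[3]*gq[1] + Minv[6]*gq[2];
    g[1] = Minv[1]*gq[0] + Minv[4]*gq[1] + Minv[7]*gq[2];
    g[2] = Minv[2]*gq[0] + Minv[5]*gq[1] + Minv[8]*gq[2];
  }
};

static Surface surfaceFromList(List spec) {
  Surface s;
  s.kind = as<int>(spec["kind"]);
  NumericVector pp = spec["params"];
  s.p0 = pp[0]; s.p1 = pp[1]; s.p2 = pp[2];
  NumericMatrix Mi = spec["minv"];
  s.hasM = false;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      s.Minv[3*i + j] = Mi(i, j);
      if (Mi(i, j) != (i == j ? 1.0 : 0.0)) s.hasM = true;
    }
  return s;
}

// Newton step along the gradient; returns true if converged to |F| < tol.
static bool projectPoint(const Surface& s, double* x, double tol, int maxit) {
  for (int it = 0; it < maxit; ++it) {
    double f = s.value(x);
    if (std::fabs(f) < tol) return true;
    double g[3]; s.grad(x, g);
    double g2 = g[0]*g[0] + g[1]*g[1] + g[2]*g[2];
    if (g2 < 1e-300) return false;
    double t = f / g2;
    x[0] -= t*g[0]; x[1] -= t*g[1]; x[2] -= t*g[2];
  }
  return std::fabs(s.value(x)) < tol;
}

// [[Rcpp::export]]
NumericMatrix cpp_project(List spec, NumericMatrix V, double tol, int maxit) {
  Surface s = surfaceFromList(spec);
  NumericMatrix out = clone(V);
  int n = out.nrow();
  for (int i = 0; i < n; ++i) {
    double x[3] = { out(i,0), out(i,1), out(i,2) };
    projectPoint(s, x, tol, maxit);
    out(i,0) = x[0]; out(i,1) = x[1]; out(i,2) = x[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Kuhn subdivision (6 tets per cube, all sharing
// the main diagonal). Face diagonals of adjacent cubes coincide, so the
// extracted mesh is watertight. Zero-crossing vertices are welded by the
// (grid-node, grid-node) edge key.
// ---------------------------------------------------------------------------
typedef std::array<double,3> Vec3;
typedef std::array<int,3>    Tri;

static inline uint64_t ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (uint64_t)a << 32 | (uint32_t)b;
}

// [[Rcpp::export]]
List cpp_marching_tets(List spec,
                       NumericVector lo, NumericVector hi,
                       IntegerVector ncell) {
  Surface s = surfaceFromList(spec);
  const int nx = ncell[0], ny = ncell[1], nz = ncell[2];
  const int px = nx + 1, py = ny + 1, pz = nz + 1;
  const double dx = (hi[0]-lo[0])/nx, dy = (hi[1]-lo[1])/ny, dz = (hi[2]-lo[2])/nz;

  std::vector<double> val((size_t)px*py*pz);
  // nudge exact zeros so no triangle vertex coincides with a grid node
  const double nud = 1e-12;
  for (int k = 0; k < pz; ++k)
    for (int j = 0; j < py; ++j)
      for (int i = 0; i < px; ++i) {
        double x[3] = { lo[0]+i*dx, lo[1]+j*dy, lo[2]+k*dz };
        double f = s.value(x);
        if (std::fabs(f) < nud) f = nud;
        val[((size_t)k*py + j)*px + i] = f;
      }
  auto nid = [&](int i, int j, int k) -> int {
    return (int)(((size_t)k*py + j)*px + i);
  };
  auto npos = [&](int id, double* x) {
    int i = id % px, j = (id/px) % py, k = id/(px*py);
    x[0] = lo[0]+i*dx; x[1] = lo[1]+j*dy; x[2] = lo[2]+k*dz;
  };

  // Kuhn tets: paths (0,0,0) -> (1,1,1), one per axis permutation
  static const int tet[6][4][3] = {
    {{0,0,0},{1,0,0},{1,1,0},{1,1,1}},
    {{0,0,0},{1,0,0},{1,0,1},{1,1,1}},
    {{0,0,0},{0,1,0},{1,1,0},{1,1,1}},
    {{0,0,0},{0,1,0},{0,1,1},{1,1,1}},
    {{0,0,0},{0,0,1},{1,0,1},{1,1,1}},
    {{0,0,0},{0,0,1},{0,1,1},{1,1,1}}
  };

  std::unordered_map<uint64_t,int> evtx;
  std::vector<Vec3> V;
  std::vector<Tri>  F;
  V.reserve(1 << 16); F.reserve(1 << 17);

  auto edgeVertex = [&](int na, int nb) -> int {
    uint64_t key = ekey(na, nb);
    auto it = evtx.find(key);
    if (it != evtx.end()) return it->second;
    double a[3], b[3]; npos(na, a); npos(nb, b);
    double va = val[na], vb = val[nb];
    double t = va / (va - vb);
    Vec3 p = { a[0] + t*(b[0]-a[0]), a[1] + t*(b[1]-a[1]), a[2] + t*(b[2]-a[2]) };
    int id = (int)V.size();
    V.push_back(p);
    evtx.emplace(key, id);
    return id;
  };
  auto emitTri = [&](int va, int vb, int vc, const double* outPt) {
    if (va == vb || vb == vc || va == vc) return;
    const Vec3 &A = V[va], &B = V[vb], &C = V[vc];
    double u[3] = { B[0]-A[0], B[1]-A[1], B[2]-A[2] };
    double w[3] = { C[0]-A[0], C[1]-A[1], C[2]-A[2] };
    double n[3] = { u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0] };
    double cx = (A[0]+B[0]+C[0])/3.0, cy = (A[1]+B[1]+C[1])/3.0, cz = (A[2]+B[2]+C[2])/3.0;
    double d[3] = { outPt[0]-cx, outPt[1]-cy, outPt[2]-cz };
    Tri t;
    if (n[0]*d[0] + n[1]*d[1] + n[2]*d[2] >= 0.0) t = { va, vb, vc };
    else t = { va, vc, vb };
    F.push_back(t);
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        for (int tt = 0; tt < 6; ++tt) {
          int n4[4]; double v4[4];
          for (int c = 0; c < 4; ++c) {
            n4[c] = nid(i + tet[tt][c][0], j + tet[tt][c][1], k + tet[tt][c][2]);
            v4[c] = val[n4[c]];
          }
          int neg[4], pos[4], nn = 0, np = 0;
          for (int c = 0; c < 4; ++c) {
            if (v4[c] < 0) neg[nn++] = c; else pos[np++] = c;
          }
          if (nn == 0 || nn == 4) continue;
          // mean position of positive corners: reference outward direction
          double op[3] = {0,0,0};
          for (int c = 0; c < np; ++c) {
            double x[3]; npos(n4[pos[c]], x);
            op[0] += x[0]/np; op[1] += x[1]/np; op[2] += x[2]/np;
          }
          if (nn == 1 || nn == 3) {
            int apex = (nn == 1) ? neg[0] : pos[0];
            int oth[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != apex) oth[m++] = c;
            int a = edgeVertex(n4[apex], n4[oth[0]]);
            int b = edgeVertex(n4[apex], n4[oth[1]]);
            int c2 = edgeVertex(n4[apex], n4[oth[2]]);
            emitTri(a, b, c2, op);
          } else {
            // 2-2: quad e(n0,p0) e(n0,p1) e(n1,p1) e(n1,p0)
            int q0 = edgeVertex(n4[neg[0]], n4[pos[0]]);
            int q1 = edgeVertex(n4[neg[0]], n4[pos[1]]);
            int q2 = edgeVertex(n4[neg[1]], n4[pos[1]]);
            int q3 = edgeVertex(n4[neg[1]], n4[pos[0]]);
            emitTri(q0, q1, q2, op);
            emitTri(q0, q2, q3, op);
          }
        }

  // keep only the largest connected component (vertex-connectivity union-find)
  int nV = (int)V.size(), nF = (int)F.size();
  std::vector<int> uf(nV);
  for (int i = 0; i < nV; ++i) uf[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (uf[a] != a) { uf[a] = uf[uf[a]]; a = uf[a]; }
    return a;
  };
  for (const Tri& t : F) {
    int a = find(t[0]), b = find(t[1]), c = find(t[2]);
    uf[b] = a; uf[find(c)] = find(a);
  }
  std::unordered_map<int, double> compArea;
  std::vector<double> farea(nF);
  for (int f = 0; f < nF; ++f) {
    const Vec3 &A = V[F[f][0]], &B = V[F[f][1]], &C = V[F[f][2]];
    double u[3] = { B[0]-A[0], B[1]-A[1], B[2]-A[2] };
    double w[3] = { C[0]-A[0], C[1]-A[1], C[2]-A[2] };
    double n0 = u[1]*w[2]-u[2]*w[1], n1 = u[2]*w[0]-u[0]*w[2], n2 = u[0]*w[1]-u[1]*w[0];
    farea[f] = 0.5*std::sqrt(n0*n0 + n1*n1 + n2*n2);
    compArea[find(F[f][0])] += farea[f];
  }
  int best = -1; double bestA = -1.0;
  for (auto& kv : compArea) if (kv.second > bestA) { bestA = kv.second; best = kv.first; }
  std::vector<int> vmap(nV, -1);
  std::vector<Vec3> V2; std::vector<Tri> F2;
  for (int f = 0; f < nF; ++f) {
    if (find(F[f][0]) != best) continue;
    Tri t;
    for (int c = 0; c < 3; ++c) {
      int v = F[f][c];
      if (vmap[v] < 0) { vmap[v] = (int)V2.size(); V2.push_back(V[v]); }
      t[c] = vmap[v];
    }
    F2.push_back(t);
  }

  NumericMatrix Vout((int)V2.size(), 3);
  IntegerMatrix Fout((int)F2.size(), 3);
  for (int i = 0; i < (int)V2.size(); ++i)
    for (int c = 0; c < 3; ++c) Vout(i, c) = V2[i][c];
  for (int i = 0; i < (int)F2.size(); ++i)
    for (int c = 0; c < 3; ++c) Fout(i, c) = F2[i][c];   // 0-based
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---------------------------------------------------------------------------
// Incremental isotropic remeshing toward a uniform target edge length.
// ---------------------------------------------------------------------------
struct Mesh {
  std::vector<Vec3> V;
  std::vector<Tri>  F;
  std::vector<char> vAlive, fAlive;

  // adjacency (rebuilt on demand)
  std::unordered_map<uint64_t, std::array<int,2>> e2f; // edge -> 2 faces
  std::vector<std::vector<int>> vF;                    // vertex -> faces

  void buildAdjacency() {
    e2f.clear();
    e2f.reserve(F.size() * 2);
    vF.assign(V.size(), {});
    for (int f = 0; f < (int)F.size(); ++f) {
      if (!fAlive[f]) continue;
      for (int c = 0; c < 3; ++c) {
        int a = F[f][c], b = F[f][(c+1)%3];
        auto it = e2f.find(ekey(a, b));
        if (it == e2f.end()) e2f[ekey(a, b)] = { f, -1 };
        else it->second[1] = f;
        vF[F[f][c]].push_back(f);
      }
    }
  }
  double elen2(int a, int b) const {
    double dx = V[a][0]-V[b][0], dy = V[a][1]-V[b][1], dz = V[a][2]-V[b][2];
    return dx*dx + dy*dy + dz*dz;
  }
  std::vector<int> ring(int v) const {           // vertex one-ring (unordered)
    std::vector<int> r;
    for (int f : vF[v]) {
      if (!fAlive[f]) continue;
      for (int c = 0; c < 3; ++c)
        if (F[f][c] != v) {
          bool seen = false;
          for (int x : r) if (x == F[f][c]) { seen = true; break; }
          if (!seen) r.push_back(F[f][c]);
        }
    }
    return r;
  }
  int valence(int v) const { return (int)ring(v).size(); }

  void compact() {
    std::vector<int> vmap(V.size(), -1);
    std::vector<Vec3> V2; V2.reserve(V.size());
    for (int i = 0; i < (int)V.size(); ++i)
      if (vAlive[i]) { vmap[i] = (int)V2.size(); V2.push_back(V[i]); }
    std::vector<Tri> F2; F2.reserve(F.size());
    for (int f = 0; f < (int)F.size(); ++f) {
      if (!fAlive[f]) continue;
      F2.push_back({ vmap[F[f][0]], vmap[F[f][1]], vmap[F[f][2]] });
    }
    V.swap(V2); F.swap(F2);
    vAlive.assign(V.size(), 1);
    fAlive.assign(F.size(), 1);
  }
};

static void splitLongEdges(Mesh& M, double Lmax, const Surface& s,
                           double tol, int maxit) {
  const double L2 = Lmax * Lmax;
  for (int pass = 0; pass < 12; ++pass) {
    M.buildAdjacency();
    std::vector<std::array<int,2>> longE;
    for (auto& kv : M.e2f) {
      int a = (int)(kv.first >> 32), b = (int)(kv.first & 0xffffffffu);
      if (M.elen2(a, b) > L2) longE.push_back({ a, b });
    }
    if (longE.empty()) return;
    std::vector<char> fTouched(M.F.size(), 0);
    bool did = false;
    for (auto& e : longE) {
      auto it = M.e2f.find(ekey(e[0], e[1]));
      if (it == M.e2f.end()) continue;
      int f1 = it->second[0], f2 = it->second[1];
      if (f1 < 0 || f2 < 0) continue;
      if (fTouched[f1] || fTouched[f2]) continue;
      if (!M.fAlive[f1] || !M.fAlive[f2]) continue;
      int a = e[0], b = e[1];
      Vec3 mid = { (M.V[a][0]+M.V[b][0])/2, (M.V[a][1]+M.V[b][1])/2,
                   (M.V[a][2]+M.V[b][2])/2 };
      double x[3] = { mid[0], mid[1], mid[2] };
      projectPoint(s, x, tol, maxit);
      mid = { x[0], x[1], x[2] };
      int vm = (int)M.V.size();
      M.V.push_back(mid); M.vAlive.push_back(1);
      for (int f : { f1, f2 }) {
        int va = M.F[f][0], vb = M.F[f][1], vc = M.F[f][2];
        // rotate so edge (a,b) is (va,vb)
        for (int r = 0; r < 3 && !((va==a&&vb==b)||(va==b&&vb==a)); ++r) {
          int t = va; va = vb; vb = vc; vc = t;
        }
        M.fAlive[f] = 0;
        fTouched[f] = 1;
        M.F.push_back({ va, vm, vc }); M.fAlive.push_back(1); fTouched.push_back(1);
        M.F.push_back({ vm, vb, vc }); M.fAlive.push_back(1); fTouched.push_back(1);
      }
      did = true;
    }
    if (!did) return;
  }
}

static void collapseShortEdges(Mesh& M, double Lmin, double Lmax,
                               const Surface& s, double tol, int maxit) {
  const double Lmin2 = Lmin*Lmin, Lmax2 = Lmax*Lmax;
  for (int pass = 0; pass < 6; ++pass) {
    M.buildAdjacency();
    std::vector<std::array<int,2>> shortE;
    for (auto& kv : M.e2f) {
      int a = (int)(kv.first >> 32), b = (int)(kv.first & 0xffffffffu);
      if (M.elen2(a, b) < Lmin2) shortE.push_back({ a, b });
    }
    if (shortE.empty()) return;
    std::vector<char> vTouched(M.V.size(), 0);
    bool did = false;
    for (auto& e : shortE) {
      int a = e[0], b = e[1];
      if (vTouched[a] || vTouched[b]) continue;
      if (!M.vAlive[a] || !M.vAlive[b]) continue;
      auto it = M.e2f.find(ekey(a, b));
      if (it == M.e2f.end() || it->second[1] < 0) continue;
      if (M.elen2(a, b) >= Lmin2) continue;
      // link condition: rings must intersect in exactly the 2 shared vertices
      std::vector<int> ra = M.ring(a), rb = M.ring(b);
      int common = 0;
      for (int x : ra) for (int y : rb) if (x == y) ++common;
      if (common != 2) continue;
      Vec3 mid = { (M.V[a][0]+M.V[b][0])/2, (M.V[a][1]+M.V[b][1])/2,
                   (M.V[a][2]+M.V[b][2])/2 };
      double x[3] = { mid[0], mid[1], mid[2] };
      projectPoint(s, x, tol, maxit);
      mid = { x[0], x[1], x[2] };
      // do not create overly long edges
      bool bad = false;
      for (int w : ra) {
        if (w == b) continue;
        double dx = mid[0]-M.V[w][0], dy = mid[1]-M.V[w][1], dz = mid[2]-M.V[w][2];
        if (dx*dx+dy*dy+dz*dz > Lmax2) { bad = true; break; }
      }
      if (!bad) for (int w : rb) {
        if (w == a) continue;
        double dx = mid[0]-M.V[w][0], dy = mid[1]-M.V[w][1], dz = mid[2]-M.V[w][2];
        if (dx*dx+dy*dy+dz*dz > Lmax2) { bad = true; break; }
      }
      if (bad) continue;
      // collapse a -> b
      int f1 = it->second[0], f2 = it->second[1];
      M.fAlive[f1] = 0; M.fAlive[f2] = 0;
      for (int f : M.vF[a]) {
        if (!M.fAlive[f]) continue;
        for (int c = 0; c < 3; ++c) if (M.F[f][c] == a) M.F[f][c] = b;
      }
      M.V[b] = mid;
      M.vAlive[a] = 0;
      vTouched[a] = 1; vTouched[b] = 1;
      for (int w : ra) vTouched[w] = 1;
      for (int w : rb) vTouched[w] = 1;
      did = true;
    }
    M.compact();
    if (!did) return;
  }
}

static void flipEdges(Mesh& M) {
  M.buildAdjacency();
  // cache valences
  std::vector<int> val(M.V.size());
  for (int v = 0; v < (int)M.V.size(); ++v) val[v] = M.valence(v);
  std::vector<char> fTouched(M.F.size(), 0);
  std::vector<std::array<int,2>> edges;
  edges.reserve(M.e2f.size());
  for (auto& kv : M.e2f)
    edges.push_back({ (int)(kv.first >> 32), (int)(kv.first & 0xffffffffu) });
  for (auto& e : edges) {
    auto it = M.e2f.find(ekey(e[0], e[1]));
    if (it == M.e2f.end()) continue;
    int f1 = it->second[0], f2 = it->second[1];
    if (f1 < 0 || f2 < 0 || fTouched[f1] || fTouched[f2]) continue;
    int a = e[0], b = e[1];
    auto opp = [&](int f) {
      for (int c = 0; c < 3; ++c)
        if (M.F[f][c] != a && M.F[f][c] != b) return M.F[f][c];
      return -1;
    };
    int c1 = opp(f1), c2 = opp(f2);
    if (c1 < 0 || c2 < 0 || c1 == c2) continue;
    if (M.e2f.count(ekey(c1, c2))) continue;    // flip would duplicate an edge
    auto dev = [](int v) { return (v - 6) * (v - 6); };
    int before = dev(val[a]) + dev(val[b]) + dev(val[c1]) + dev(val[c2]);
    int after  = dev(val[a]-1) + dev(val[b]-1) + dev(val[c1]+1) + dev(val[c2]+1);
    if (after >= before) continue;
    if (val[a] <= 3 || val[b] <= 3) continue;
    // geometric guard: new triangles must keep a consistent normal
    auto nrm = [&](int u, int v, int w, double* n) {
      double p[3] = { M.V[v][0]-M.V[u][0], M.V[v][1]-M.V[u][1], M.V[v][2]-M.V[u][2] };
      double q[3] = { M.V[w][0]-M.V[u][0], M.V[w][1]-M.V[u][1], M.V[w][2]-M.V[u][2] };
      n[0]=p[1]*q[2]-p[2]*q[1]; n[1]=p[2]*q[0]-p[0]*q[2]; n[2]=p[0]*q[1]-p[1]*q[0];
    };
    double n1[3], n2[3], m1[3], m2[3];
    // orient f1 so it reads (a, b, c1) cyclically
    bool abOrder = false;
    for (int c = 0; c < 3; ++c)
      if (M.F[f1][c] == a && M.F[f1][(c+1)%3] == b) abOrder = true;
    int A = abOrder ? a : b, B = abOrder ? b : a;
    nrm(A, B, c1, n1); nrm(B, A, c2, n2);
    nrm(A, c2, c1, m1); nrm(c2, B, c1, m2);
    auto dot = [](double* u, double* v) { return u[0]*v[0]+u[1]*v[1]+u[2]*v[2]; };
    if (dot(m1, n1) <= 0 || dot(m2, n1) <= 0 ||
        dot(m1, n2) <= 0 || dot(m2, n2) <= 0) continue;
    M.F[f1] = { A, c2, c1 };
    M.F[f2] = { c2, B, c1 };
    fTouched[f1] = 1; fTouched[f2] = 1;
    --val[a]; --val[b]; ++val[c1]; ++val[c2];
    M.e2f.erase(ekey(a, b));
    M.e2f[ekey(c1, c2)] = { f1, f2 };
  }
}

static void smoothAndProject(Mesh& M, double lambda, const Surface& s,
                             double tol, int maxit) {
  M.buildAdjacency();
  std::vector<Vec3> newV = M.V;
  for (int v = 0; v < (int)M.V.size(); ++v) {
    std::vector<int> r = M.ring(v);
    if (r.size() < 3) continue;
    double g[3] = {0,0,0};
    for (int w : r) { g[0] += M.V[w][0]; g[1] += M.V[w][1]; g[2] += M.V[w][2]; }
    g[0] /= r.size(); g[1] /= r.size(); g[2] /= r.size();
    double d[3] = { g[0]-M.V[v][0], g[1]-M.V[v][1], g[2]-M.V[v][2] };
    double x0[3] = { M.V[v][0], M.V[v][1], M.V[v][2] };
    double nrm[3]; s.grad(x0, nrm);
    double nn = std::sqrt(nrm[0]*nrm[0]+nrm[1]*nrm[1]+nrm[2]*nrm[2]);
    if (nn > 1e-300) {
      nrm[0] /= nn; nrm[1] /= nn; nrm[2] /= nn;
      double dn = d[0]*nrm[0]+d[1]*nrm[1]+d[2]*nrm[2];
      d[0] -= dn*nrm[0]; d[1] -= dn*nrm[1]; d[2] -= dn*nrm[2];
    }
    double x[3] = { x0[0] + lambda*d[0], x0[1] + lambda*d[1], x0[2] + lambda*d[2] };
    projectPoint(s, x, tol, maxit);
    newV[v] = { x[0], x[1], x[2] };
  }
  M.V.swap(newV);
}

// [[Rcpp::export]]
List cpp_remesh(List spec, NumericMatrix Vin, IntegerMatrix Fin,
                double targetLen, int iters, double tol) {
  Surface s = surfaceFromList(spec);
  Mesh M;
  M.V.resize(Vin.nrow());
  for (int i = 0; i < Vin.nrow(); ++i)
    M.V[i] = { Vin(i,0), Vin(i,1), Vin(i,2) };
  M.F.resize(Fin.nrow());
  for (int i = 0; i < Fin.nrow(); ++i)
    M.F[i] = { Fin(i,0), Fin(i,1), Fin(i,2) };   // 0-based
  M.vAlive.assign(M.V.size(), 1);
  M.fAlive.assign(M.F.size(), 1);
  const int projIt = 30;
  for (int it = 0; it < iters; ++it) {
    splitLongEdges(M, 4.0/3.0 * targetLen, s, tol, projIt);
    collapseShortEdges(M, 0.8 * targetLen, 4.0/3.0 * targetLen, s, tol, projIt);
    flipEdges(M);
    M.compact();
    smoothAndProject(M, 0.5, s, tol, projIt);
  }
  M.compact();
  NumericMatrix Vout((int)M.V.size(), 3);
  IntegerMatrix Fout((int)M.F.size(), 3);
  for (int i = 0; i < (int)M.V.size(); ++i)
    for (int c = 0; c < 3; ++c) Vout(i, c) = M.V[i][c];
  for (int i = 0; i < (int)M.F.size(); ++i)
    for (int c = 0; c < 3; ++c) Fout(i, c) = M.F[i][c];
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
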
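// Incremental (Bowyer-Watson) 3D Delaunay tetrahedralisation.
//
// Degenerate inputs (cospherical/cocircular sets such as voxel lattices or
// cube corners) are handled by a deterministic, index-keyed jitter of the
// working coordinates -- a cheap stand-in for symbolic perturbation. Tet
// volumes and circumradii are reported from the ORIGINAL coordinates, so the
// jitter only selects among valid triangulations of degenerate point sets.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline double orient3d(const double* a, const double* b, const double* c, const double* d) {
  double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy)
       - ady * (bdx * cdz - bdz * cdx)
       + adz * (bdx * cdy - bdy * cdx);
}

inline double insphereDet(const double* a, const double* b, const double* c,
                          const double* d, const double* e) {
  double ax = a[0] - e[0], ay = a[1] - e[1], az = a[2] - e[2];
  double bx = b[0] - e[0], by = b[1] - e[1], bz = b[2] - e[2];
  double cx = c[0] - e[0], cy = c[1] - e[1], cz = c[2] - e[2];
  double dx = d[0] - e[0], dy = d[1] - e[1], dz = d[2] - e[2];
  double a2 = ax * ax + ay * ay + az * az;
  double b2 = bx * bx + by * by + bz * bz;
  double c2 = cx * cx + cy * cy + cz * cz;
  double d2 = dx * dx + dy * dy + dz * dz;
  // det of 4x4 [ [ax ay az a2] ... ] via expansion on last column
  auto det3 = [](double m00, double m01, double m02,
                 double m10, double m11, double m12,
                 double m20, double m21, double m22) {
    return m00 * (m11 * m22 - m12 * m21)
         - m01 * (m10 * m22 - m12 * m20)
         + m02 * (m10 * m21 - m11 * m20);
  };
  return -a2 * det3(bx, by, bz, cx, cy, cz, dx, dy, dz)
       + b2 * det3(ax, ay, az, cx, cy, cz, dx, dy, dz)
       - c2 * det3(ax, ay, az, bx, by, bz, dx, dy, dz)
       + d2 * det3(ax, ay, az, bx, by, bz, cx, cy, cz);
}

struct Tet {
  int v[4];
  int nbr[4];   // neighbour tet opposite vertex v[i], -1 if none
  bool alive;
  int stamp;    // cavity-membership stamp
};

struct Delaunay3D {
  std::vector<double> P;   // jittered working coords, (n + 4) x 3
  int n;                   // number of real points
  std::vector<Tet> tets;
  double sphSign = 1.0;
  int curStamp = 0;
  int lastTet = 0;

  const double* pt(int i) const { return &P[3 * (size_t)i]; }

  void calibrate() {
    double A[3] = {0, 0, 0}, B[3] = {1, 0, 0}, C[3] = {0, 1, 0}, D[3] = {0, 0, 1};
    double E[3] = {0.25, 0.25, 0.25};
    if (orient3d(A, B, C, D) < 0) std::swap(A[0], B[0]), std::swap(A[1], B[1]), std::swap(A[2], B[2]);
    sphSign = insphereDet(A, B, C, D, E) > 0 ? 1.0 : -1.0;
  }

  bool inSphere(const Tet& t, const double* p) const {
    return sphSign * insphereDet(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]), p) > 0;
  }

  int makeTet(int a, int b, int c, int d) {
    if (orient3d(pt(a), pt(b), pt(c), pt(d)) < 0) std::swap(a, b);
    Tet t;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.nbr[0] = t.nbr[1] = t.nbr[2] = t.nbr[3] = -1;
    t.alive = true; t.stamp = 0;
    tets.push_back(t);
    return (int)tets.size() - 1;
  }

  // is p strictly outside face i of tet t?
  bool outsideFace(const Tet& t, int i, const double* p) const {
    int a = t.v[(i + 1) & 3], b = t.v[(i + 2) & 3], c = t.v[(i + 3) & 3];
    double op = orient3d(pt(a), pt(b), pt(c), p);
    double oi = orient3d(pt(a), pt(b), pt(c), pt(t.v[i]));
    return op * oi < 0;
  }

  int locate(const double* p) {
    int cur = lastTet;
    if (cur < 0 || !tets[cur].alive)
      for (int i = (int)tets.size() - 1; i >= 0; --i) if (tets[i].alive) { cur = i; break; }
    for (int steps = 0; steps < (int)tets.size() + 64; ++steps) {
      const Tet& t = tets[cur];
      bool moved = false;
      for (int i = 0; i < 4; ++i) {
        if (outsideFace(t, i, p)) {
          int nb = t.nbr[i];
          if (nb < 0) break;
          cur = nb;
          moved = true;
          break;
        }
      }
      if (!moved) return cur;
    }
    // walk failed (numerical cycling): exhaustive fallback
    for (int i = 0; i < (int)tets.size(); ++i) {
      if (!tets[i].alive) continue;
      bool out = false;
      for (int f = 0; f < 4; ++f) if (outsideFace(tets[i], f, p)) { out = true; break; }
      if (!out) return i;
    }
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive && inSphere(tets[i], p)) return i;
    stop("Delaunay point location failed");
    return -1;
  }

  void insert(int ip) {
    const double* p = pt(ip);
    int seed = locate(p);
    ++curStamp;
    std::vector<int> cavity;
    std::vector<int> stack;
    tets[seed].stamp = curStamp;
    cavity.push_back(seed);
    stack.push_back(seed);
    while (!stack.empty()) {
      int ci = stack.back(); stack.pop_back();
      for (int f = 0; f < 4; ++f) {
        int nb = tets[ci].nbr[f];
        if (nb < 0 || tets[nb].stamp == curStamp) continue;
        if (inSphere(tets[nb], p)) {
          tets[nb].stamp = curStamp;
          cavity.push_back(nb);
          stack.push_back(nb);
        }
      }
    }
    // boundary faces of the cavity -> new tets
    struct BFace { int a, b, c, outside, outFace; };
    std::vector<BFace> faces;
    for (int ci : cavity) {
      for (int f = 0; f < 4; ++f) {
        int nb = tets[ci].nbr[f];
        if (nb >= 0 && tets[nb].stamp == curStamp) continue;
        BFace bf;
        bf.a = tets[ci].v[(f + 1) & 3];
        bf.b = tets[ci].v[(f + 2) & 3];
        bf.c = tets[ci].v[(f + 3) & 3];
        bf.outside = nb;
        bf.outFace = -1;
        if (nb >= 0)
          for (int g = 0; g < 4; ++g) if (tets[nb].nbr[g] == ci) bf.outFace = g;
        faces.push_back(bf);
      }
    }
    for (int ci : cavity) tets[ci].alive = false;
    // create new tets and stitch adjacency
    std::map<std::pair<int, int>, std::pair<int, int>> edgeMap; // edge -> (tet, face)
    int firstNew = -1;
    for (const BFace& bf : faces) {
      int nt = makeTet(bf.a, bf.b, bf.c, ip);
      if (firstNew < 0) firstNew = nt;
      Tet& t = tets[nt];
      // face opposite ip is (a,b,c): find which slot holds ip
      int slotP = -1;
      for (int i = 0; i < 4; ++i) if (t.v[i] == ip) slotP = i;
      t.nbr[slotP] = bf.outside;
      if (bf.outside >= 0 && bf.outFace >= 0) tets[bf.outside].nbr[bf.outFace] = nt;
      // the other three faces each contain ip and an edge of (a,b,c)
      for (int i = 0; i < 4; ++i) {
        if (i == slotP) continue;
        int e[2]; int k = 0;
        for (int j = 0; j < 4; ++j)
          if (j != i && t.v[j] != ip) e[k++] = t.v[j];
        if (e[0] > e[1]) std::swap(e[0], e[1]);
        auto key = std::make_pair(e[0], e[1]);
        auto it = edgeMap.find(key);
        if (it == edgeMap.end()) {
          edgeMap[key] = std::make_pair(nt, i);
        } else {
          t.nbr[i] = it->second.first;
          tets[it->second.first].nbr[it->second.second] = nt;
          edgeMap.erase(it);
        }
      }
    }
    lastTet = firstNew;
  }
};

inline double hashJitter(uint32_t key) {
  // deterministic in [-0.5, 0.5)
  uint32_t h = key * 2654435761u;
  h ^= h >> 16; h *= 2246822519u; h ^= h >> 13;
  return (double)h / 4294967296.0 - 0.5;
}

} // namespace

// [[Rcpp::export]]
List cpp_delaunay3d(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  Delaunay3D D;
  D.n = n;
  D.calibrate();
  // bounding box and jitter scale
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = hi[d] = pts(0, d); }
  for (int i = 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (pts(i, d) < lo[d]) lo[d] = pts(i, d);
      if (pts(i, d) > hi[d]) hi[d] = pts(i, d);
    }
  double diag = 0;
  for (int d = 0; d < 3; ++d) diag += (hi[d] - lo[d]) * (hi[d] - lo[d]);
  diag = std::sqrt(diag);
  if (diag <= 0) stop("all points coincide");
  double jit = 1e-8 * diag;
  D.P.resize(3 * (size_t)(n + 4));
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      D.P[3 * (size_t)i + d] = pts(i, d) + jit * hashJitter((uint32_t)(3 * i + d + 1));
  // super-tetrahedron, well outside the data
  double c0[3] = {(lo[0] + hi[0]) / 2, (lo[1] + hi[1]) / 2, (lo[2] + hi[2]) / 2};
  double R = 150.0 * diag;
  double sv[4][3] = {
    { c0[0] + R,  c0[1],          c0[2] - R / 2 },
    { c0[0] - R / 2, c0[1] + R * 0.8660254, c0[2] - R / 2 },
    { c0[0] - R / 2, c0[1] - R * 0.8660254, c0[2] - R / 2 },
    { c0[0],      c0[1],          c0[2] + R }
  };
  for (int i = 0; i < 4; ++i)
    for (int d = 0; d < 3; ++d) D.P[3 * (size_t)(n + i) + d] = sv[i][d];
  D.tets.reserve(12 * (size_t)n);
  D.makeTet(n, n + 1, n + 2, n + 3);
  // deterministic shuffled insertion order
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t s = 88172645463325252ull;
  for (int i = n - 1; i > 0; --i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    int j = (int)(s % (uint64_t)(i + 1));
    std::swap(order[i], order[j]);
  }
  for (int i = 0; i < n; ++i) {
    D.insert(order[i]);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  // collect real tets; stats from original coordinates
  std::vector<int> keep;
  for (int i = 0; i < (int)D.tets.size(); ++i) {
    const Tet& t = D.tets[i];
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    keep.push_back(i);
  }
  int m = (int)keep.size();
  IntegerMatrix TV(m, 4);
  NumericVector vol(m), crad(m);
  for (int r = 0; r < m; ++r) {
    const Tet& t = D.tets[keep[r]];
    double v[4][3];
    for (int i = 0; i < 4; ++i) {
      TV(r, i) = t.v[i] + 1;
      for (int d = 0; d < 3; ++d) v[i][d] = pts(t.v[i], d);
    }
    double o = orient3d(v[0], v[1], v[2], v[3]);
    vol[r] = std::fabs(o) / 6.0;
    // circumcentre: solve 2 (vi - v0) . c = |vi - v0|^2, i = 1..3
    double Mx[3][3], rhs[3];
    for (int i = 0; i < 3; ++i) {
      double s2 = 0;
      for (int d = 0; d < 3; ++d) {
        Mx[i][d] = v[i + 1][d] - v[0][d];
        s2 += Mx[i][d] * Mx[i][d];
      }
      rhs[i] = s2 / 2.0;
    }
    double det = Mx[0][0] * (Mx[1][1] * Mx[2][2] - Mx[1][2] * Mx[2][1])
               - Mx[0][1] * (Mx[1][0] * Mx[2][2] - Mx[1][2] * Mx[2][0])
               + Mx[0][2] * (Mx[1][0] * Mx[2][1] - Mx[1][1] * Mx[2][0]);
    if (std::fabs(det) < 1e-300) {
      crad[r] = R_PosInf;
    } else {
      auto solveCol = [&](int col) {
        double A[3][3];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) A[i][j] = (j == col) ? rhs[i] : Mx[i][j];
        return (A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
              - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
              + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0])) / det;
      };
      double cx = solveCol(0), cy = solveCol(1), cz = solveCol(2);
      crad[r] = std::sqrt(cx * cx + cy * cy + cz * cz);
    }
  }
  return List::create(_["tets"] = TV, _["volume"] = vol, _["circumradius"] = crad);
}
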
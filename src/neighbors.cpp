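// Spatial search primitives used across the pipeline: a static 3D kd-tree
// (kNN queries), grid-hash fixed-radius connected components (Euclidean
// clustering), and voxel-grid centroid downsampling.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct KDTree3 {
  // points stored row-major as x,y,z triplets
  std::vector<double> pts;
  std::vector<int> perm;           // permutation of point indices
  struct Node { int left, right, begin, end, dim; double split; };
  std::vector<Node> nodes;
  int root = -1;
  static const int LEAF = 16;

  void build(const NumericMatrix& m) {
    int n = m.nrow();
    pts.resize(3 * (size_t)n);
    perm.resize(n);
    for (int i = 0; i < n; ++i) {
      pts[3 * (size_t)i] = m(i, 0);
      pts[3 * (size_t)i + 1] = m(i, 1);
      pts[3 * (size_t)i + 2] = m(i, 2);
      perm[i] = i;
    }
    nodes.reserve(2 * n / LEAF + 8);
    root = buildRange(0, n);
  }

  int buildRange(int b, int e) {
    Node nd; nd.begin = b; nd.end = e; nd.left = nd.right = -1; nd.dim = 0; nd.split = 0;
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (e - b <= LEAF) return id;
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int i = b; i < e; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = pts[3 * (size_t)perm[i] + d];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    int dim = 0; double ext = hi[0] - lo[0];
    for (int d = 1; d < 3; ++d) if (hi[d] - lo[d] > ext) { ext = hi[d] - lo[d]; dim = d; }
    int mid = (b + e) / 2;
    std::nth_element(perm.begin() + b, perm.begin() + mid, perm.begin() + e,
                     [&](int a, int c) { return pts[3 * (size_t)a + dim] < pts[3 * (size_t)c + dim]; });
    double split = pts[3 * (size_t)perm[mid] + dim];
    int l = buildRange(b, mid);
    int r = buildRange(mid, e);
    nodes[id].dim = dim; nodes[id].split = split; nodes[id].left = l; nodes[id].right = r;
    return id;
  }

  // bounded max-heap of (dist2, idx)
  struct Cand { double d2; int idx; };
  struct CandCmp { bool operator()(const Cand& a, const Cand& b) const { return a.d2 < b.d2; } };

  void knn(const double* q, int k, int skip,
           std::vector<Cand>& heap) const {
    heap.clear();
    search(root, q, k, skip, heap);
    std::sort_heap(heap.begin(), heap.end(), CandCmp());
  }

  void search(int id, const double* q, int k, int skip, std::vector<Cand>& heap) const {
    const Node& nd = nodes[id];
    if (nd.left < 0) {
      for (int i = nd.begin; i < nd.end; ++i) {
        int p = perm[i];
        if (p == skip) continue;
        double dx = pts[3 * (size_t)p] - q[0];
        double dy = pts[3 * (size_t)p + 1] - q[1];
        double dz = pts[3 * (size_t)p + 2] - q[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if ((int)heap.size() < k) {
          heap.push_back({d2, p});
          std::push_heap(heap.begin(), heap.end(), CandCmp());
        } else if (d2 < heap.front().d2) {
          std::pop_heap(heap.begin(), heap.end(), CandCmp());
          heap.back() = {d2, p};
          std::push_heap(heap.begin(), heap.end(), CandCmp());
        }
      }
      return;
    }
    double diff = q[nd.dim] - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search(near, q, k, skip, heap);
    if ((int)heap.size() < k || diff * diff < heap.front().d2)
      search(far, q, k, skip, heap);
  }
};

inline int64_t cellKey(int ix, int iy, int iz) {
  // 21 bits per axis, offset to keep non-negative
  return (((int64_t)(ix + 1048576)) << 42) |
         (((int64_t)(iy + 1048576)) << 21) |
         ((int64_t)(iz + 1048576));
}

} // namespace

// [[Rcpp::export]]
List cpp_knn(NumericMatrix data, NumericMatrix query, int k, bool self = false) {
  // self = TRUE means query rows are the same points as data rows (row i of
  // query is data point i) and the point itself must be excluded.
  int n = data.nrow(), m = query.nrow();
  if (k < 1) stop("k must be >= 1");
  if (k > (self ? n - 1 : n)) stop("k larger than number of available neighbours");
  KDTree3 tree;
  tree.build(data);
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<KDTree3::Cand> heap;
  heap.reserve(k + 1);
  double q[3];
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    tree.knn(q, k, self ? i : -1, heap);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = heap[j].idx + 1;
      dist(i, j) = std::sqrt(heap[j].d2);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// [[Rcpp::export]]
NumericVector cpp_mean_knn_dist(NumericMatrix data, int k) {
  // mean distance from each point to its k nearest neighbours (self excluded)
  int n = data.nrow();
  if (k < 1 || k > n - 1) stop("need 1 <= k <= n - 1");
  KDTree3 tree;
  tree.build(data);
  NumericVector out(n);
  std::vector<KDTree3::Cand> heap;
  heap.reserve(k + 1);
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = data(i, 0); q[1] = data(i, 1); q[2] = data(i, 2);
    tree.knn(q, k, i, heap);
    double s = 0;
    for (int j = 0; j < k; ++j) s += std::sqrt(heap[j].d2);
    out[i] = s / k;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_radius_components(NumericMatrix pts, double r) {
  // connected components of the graph linking points within distance r,
  // via a uniform grid of cell size r (each point checks its 27 cells).
  // labels are assigned in order of first discovery (deterministic).
  int n = pts.nrow();
  IntegerVector lab(n, 0);
  if (n == 0) return lab;
  double r2 = r * r;
  double mn[3];
  for (int d = 0; d < 3; ++d) {
    mn[d] = pts(0, d);
    for (int i = 1; i < n; ++i) if (pts(i, d) < mn[d]) mn[d] = pts(i, d);
  }
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(2 * (size_t)n);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor((pts(i, 0) - mn[0]) / r);
    cy[i] = (int)std::floor((pts(i, 1) - mn[1]) / r);
    cz[i] = (int)std::floor((pts(i, 2) - mn[2]) / r);
    grid[cellKey(cx[i], cy[i], cz[i])].push_back(i);
  }
  int comp = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (lab[s]) continue;
    ++comp;
    lab[s] = comp;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            auto it = grid.find(cellKey(cx[i] + dx, cy[i] + dy, cz[i] + dz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (lab[j]) continue;
              double ddx = pts(i, 0) - pts(j, 0);
              double ddy = pts(i, 1) - pts(j, 1);
              double ddz = pts(i, 2) - pts(j, 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) {
                lab[j] = comp;
                stack.push_back(j);
              }
            }
          }
    }
  }
  return lab;
}

// [[Rcpp::export]]
List cpp_voxel_centroids(NumericMatrix pts, double voxel) {
  // centroid per occupied voxel; centroids ordered by voxel key so the
  // output is independent of input point order up to that ordering.
  int n = pts.nrow();
  if (voxel <= 0) stop("voxel size must be > 0");
  double mn[3] = {0, 0, 0};
  if (n > 0)
    for (int d = 0; d < 3; ++d) {
      mn[d] = pts(0, d);
      for (int i = 1; i < n; ++i) if (pts(i, d) < mn[d]) mn[d] = pts(i, d);
    }
  struct Acc { double x = 0, y = 0, z = 0; int cnt = 0; };
  std::unordered_map<int64_t, Acc> acc;
  acc.reserve(2 * (size_t)n);
  std::vector<int64_t> keyOf(n);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor((pts(i, 0) - mn[0]) / voxel);
    int iy = (int)std::floor((pts(i, 1) - mn[1]) / voxel);
    int iz = (int)std::floor((pts(i, 2) - mn[2]) / voxel);
    int64_t k = cellKey(ix, iy, iz);
    keyOf[i] = k;
    Acc& a = acc[k];
    a.x += pts(i, 0); a.y += pts(i, 1); a.z += pts(i, 2); a.cnt++;
  }
  std::vector<int64_t> keys;
  keys.reserve(acc.size());
  for (auto& kv : acc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  std::unordered_map<int64_t, int> rowOf;
  rowOf.reserve(keys.size());
  int m = (int)keys.size();
  NumericMatrix cent(m, 3);
  IntegerVector cnt(m);
  for (int i = 0; i < m; ++i) {
    const Acc& a = acc[keys[i]];
    cent(i, 0) = a.x / a.cnt; cent(i, 1) = a.y / a.cnt; cent(i, 2) = a.z / a.cnt;
    cnt[i] = a.cnt;
    rowOf[keys[i]] = i + 1;
  }
  IntegerVector vox(n);
  for (int i = 0; i < n; ++i) vox[i] = rowOf[keyOf[i]];
  return List::create(_["centroids"] = cent, _["count"] = cnt, _["voxel_of"] = vox);
}
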
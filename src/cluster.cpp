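#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// DBSCAN on 3D points with a uniform-grid (cell size = eps) neighbour index.
// Labels: 0 = noise, 1..k = clusters.  Border points join the first core
// point's cluster that reaches them (standard DBSCAN semantics).
// ---------------------------------------------------------------------------

static inline int64_t cell_key(int cx, int cy, int cz) {
  return ((int64_t)(cx + 1048576) << 42) | ((int64_t)(cy + 1048576) << 21) |
         (int64_t)(cz + 1048576);
}

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_pts) {
  const int n = pts.nrow();
  const double eps2 = eps * eps;
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(n);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(pts(i, 0) / eps);
    cy[i] = (int)std::floor(pts(i, 1) / eps);
    cz[i] = (int)std::floor(pts(i, 2) / eps);
    grid[cell_key(cx[i], cy[i], cz[i])].push_back(i);
  }
  auto neighbours = [&](int i, std::vector<int>& out) {
    out.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double ddx = pts(i, 0) - pts(j, 0);
            double ddy = pts(i, 1) - pts(j, 1);
            double ddz = pts(i, 2) - pts(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= eps2) out.push_back(j);
          }
        }
  };
  std::vector<int> label(n, -1); // -1 unvisited, 0 noise, >0 cluster
  std::vector<int> nb, nb2;
  int ncl = 0;
  for (int i = 0; i < n; ++i) {
    if (label[i] != -1) continue;
    neighbours(i, nb);
    if ((int)nb.size() < min_pts) {
      label[i] = 0;
      continue;
    }
    ++ncl;
    label[i] = ncl;
    std::queue<int> q;
    for (int j : nb)
      if (j != i) q.push(j);
    while (!q.empty()) {
      int j = q.front();
      q.pop();
      if (label[j] == 0) label[j] = ncl; // border point
      if (label[j] != -1) continue;
      label[j] = ncl;
      neighbours(j, nb2);
      if ((int)nb2.size() >= min_pts)
        for (int k : nb2) {
          if (label[k] == -1 || label[k] == 0) q.push(k);
        }
    }
  }
  return IntegerVector(label.begin(), label.end());
}

// ---------------------------------------------------------------------------
// kd-tree nearest neighbour (1-NN) for ICP correspondence search.
// ---------------------------------------------------------------------------

struct KDNode {
  int idx, left, right, axis;
};

struct KDTree {
  const double* pts; // n x 3, column-major with leading dim n
  int n;
  std::vector<KDNode> nodes;
  std::vector<int> order;
  double coord(int i, int k) const { return pts[(size_t)k * n + i]; }
  int build(int begin, int end, int depth) {
    if (begin >= end) return -1;
    int axis = depth % 3;
    int mid = (begin + end) / 2;
    std::nth_element(order.begin() + begin, order.begin() + mid,
                     order.begin() + end, [&](int a, int b) {
                       return coord(a, axis) < coord(b, axis);
                     });
    KDNode nd;
    nd.idx = order[mid];
    nd.axis = axis;
    int id = (int)nodes.size();
    nodes.push_back(nd);
    int l = build(begin, mid, depth + 1);
    int r = build(mid + 1, end, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
  void query(int node, const double* q, int& best, double& best2) const {
    if (node < 0) return;
    const KDNode& nd = nodes[node];
    double dx = q[0] - coord(nd.idx, 0);
    double dy = q[1] - coord(nd.idx, 1);
    double dz = q[2] - coord(nd.idx, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best2) {
      best2 = d2;
      best = nd.idx;
    }
    double diff = q[nd.axis] - coord(nd.idx, nd.axis);
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    query(near, q, best, best2);
    if (diff * diff < best2) query(far, q, best, best2);
  }
};

// [[Rcpp::export]]
List cpp_nn1(NumericMatrix query, NumericMatrix ref) {
  KDTree T;
  T.pts = ref.begin();
  T.n = ref.nrow();
  T.order.resize(T.n);
  for (int i = 0; i < T.n; ++i) T.order[i] = i;
  T.nodes.reserve(T.n);
  int root = T.build(0, T.n, 0);
  int m = query.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  for (int i = 0; i < m; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    int best = -1;
    double best2 = 1e300;
    T.query(root, q, best, best2);
    idx[i] = best + 1;
    dist[i] = std::sqrt(best2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
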
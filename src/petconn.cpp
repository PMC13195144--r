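// Spatial kernels: exact k-nearest neighbours (k-d tree) and the
// spatially-aware iterative point-cloud compressor (mutual-nearest-pair
// centroid merging in a joint position/intensity feature space).
#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct KdTree {
  const std::vector<double>& pts; // n x d, row-major
  int n, d;
  std::vector<int> idx;    // permutation of point indices
  std::vector<int> left_, right_, point_;
  std::vector<int> axis_;
  int root;

  KdTree(const std::vector<double>& p, int n_, int d_) : pts(p), n(n_), d(d_) {
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    left_.reserve(n); right_.reserve(n); point_.reserve(n); axis_.reserve(n);
    root = build(0, n, 0);
  }

  int build(int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int ax = depth % d;
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) {
                       double va = pts[(size_t)a * d + ax];
                       double vb = pts[(size_t)b * d + ax];
                       if (va != vb) return va < vb;
                       return a < b;
                     });
    int node = (int)point_.size();
    point_.push_back(idx[mid]);
    axis_.push_back(ax);
    left_.push_back(-1);
    right_.push_back(-1);
    int l = build(lo, mid, depth + 1);
    int r = build(mid + 1, hi, depth + 1);
    left_[node] = l;
    right_[node] = r;
    return node;
  }

  // candidate: (dist2, index); keep k smallest lexicographically
  struct Cand {
    double d2;
    int id;
    bool operator<(const Cand& o) const { // max-heap: worst on top
      if (d2 != o.d2) return d2 < o.d2;
      return id < o.id;
    }
  };

  void search(int node, const double* q, int k, int skip,
              std::priority_queue<Cand>& heap) const {
    if (node < 0) return;
    int p = point_[node];
    if (p != skip) {
      double d2 = 0.0;
      for (int a = 0; a < d; ++a) {
        double diff = q[a] - pts[(size_t)p * d + a];
        d2 += diff * diff;
      }
      Cand c{d2, p};
      if ((int)heap.size() < k) heap.push(c);
      else if (c < heap.top()) { heap.pop(); heap.push(c); }
    }
    int ax = axis_[node];
    double diff = q[ax] - pts[(size_t)point_[node] * d + ax];
    int near = diff <= 0 ? left_[node] : right_[node];
    int far = diff <= 0 ? right_[node] : left_[node];
    search(near, q, k, skip, heap);
    if ((int)heap.size() < k || diff * diff <= heap.top().d2) {
      search(far, q, k, skip, heap);
    }
  }

  // k nearest (excluding `skip` if >= 0), sorted by (dist, index)
  std::vector<int> query(const double* q, int k, int skip) const {
    std::priority_queue<Cand> heap;
    search(root, q, k, skip, heap);
    std::vector<Cand> out;
    out.reserve(heap.size());
    while (!heap.empty()) { out.push_back(heap.top()); heap.pop(); }
    std::sort(out.begin(), out.end(), [](const Cand& a, const Cand& b) {
      if (a.d2 != b.d2) return a.d2 < b.d2;
      return a.id < b.id;
    });
    std::vector<int> ids(out.size());
    for (size_t i = 0; i < out.size(); ++i) ids[i] = out[i].id;
    return ids;
  }
};

std::vector<double> to_rowmajor(const NumericMatrix& X) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> out((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) out[(size_t)i * d + j] = X(i, j);
  return out;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix X, int k) {
  int n = X.nrow();
  if (k < 1) stop("k must be >= 1");
  if (k >= n) stop("k must be smaller than the number of points");
  std::vector<double> pts = to_rowmajor(X);
  KdTree tree(pts, n, X.ncol());
  IntegerMatrix out(n, k);
  int d = X.ncol();
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb = tree.query(&pts[(size_t)i * d], k, i);
    for (int j = 0; j < k; ++j) out(i, j) = nb[j] + 1; // 1-based
  }
  return out;
}

namespace {

struct Edge {
  double d2;
  int i, j;       // node indices, i < j
  int vi, vj;     // versions at push time
};
struct EdgeCmp { // min-heap by (d2, i, j)
  bool operator()(const Edge& a, const Edge& b) const {
    if (a.d2 != b.d2) return a.d2 > b.d2;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

} // namespace

// Iteratively merge the currently closest candidate pair (in feature
// space) into a weight-summed, weighted-centroid point until `target`
// points remain. Candidate edges come from a static k-d tree over the
// ORIGINAL points mapped through union-find to surviving centroids, with
// a brute-force refill if the candidate heap runs dry. Deterministic:
// ties broken by lowest node index.
// [[Rcpp::export]]
List cpp_compress(NumericMatrix feat, NumericVector suv, NumericMatrix pos,
                  int target, int k_cand = 8) {
  const int n = feat.nrow();
  const int d = feat.ncol();
  if (target < 1) stop("target must be >= 1");
  std::vector<double> orig = to_rowmajor(feat);
  KdTree tree(orig, n, d);

  std::vector<double> F = orig;                 // current features
  std::vector<double> S(suv.begin(), suv.end());
  std::vector<double> P((size_t)n * 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) P[(size_t)i * 3 + a] = pos(i, a);
  std::vector<double> W(n, 1.0);
  std::vector<char> alive(n, 1);
  std::vector<int> version(n, 0);
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  auto dist2 = [&](int a, int b) {
    double s = 0.0;
    for (int ax = 0; ax < d; ++ax) {
      double diff = F[(size_t)a * d + ax] - F[(size_t)b * d + ax];
      s += diff * diff;
    }
    return s;
  };

  std::priority_queue<Edge, std::vector<Edge>, EdgeCmp> heap;
  auto push_edge = [&](int a, int b) {
    if (a == b) return;
    int i = std::min(a, b), j = std::max(a, b);
    heap.push(Edge{dist2(i, j), i, j, version[i], version[j]});
  };

  // initial candidates: k_cand nearest neighbours of each original point
  int k0 = std::min(k_cand, n - 1);
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb = tree.query(&orig[(size_t)i * d], k0, i);
    for (int j : nb) if (i < j) push_edge(i, j);
    for (int j : nb) if (j < i) push_edge(j, i); // keep both directions covered
  }

  int alive_count = n;
  std::vector<double> q(d);
  while (alive_count > target) {
    if (heap.empty()) {
      // refill: nearest alive neighbour of each alive node (brute force)
      std::vector<int> ids;
      ids.reserve(alive_count);
      for (int i = 0; i < n; ++i) if (alive[i]) ids.push_back(i);
      for (size_t a = 0; a < ids.size(); ++a) {
        double best = R_PosInf; int bj = -1;
        for (size_t b = 0; b < ids.size(); ++b) {
          if (a == b) continue;
          double d2 = dist2(ids[a], ids[b]);
          if (d2 < best || (d2 == best && ids[b] < bj)) { best = d2; bj = ids[b]; }
        }
        if (bj >= 0) push_edge(ids[a], bj);
      }
      if (heap.empty()) break;
    }
    Edge e = heap.top(); heap.pop();
    if (!alive[e.i] || !alive[e.j]) continue;
    if (version[e.i] != e.vi || version[e.j] != e.vj) continue;
    // merge j into i (i < j): weighted centroid
    double wi = W[e.i], wj = W[e.j], wn = wi + wj;
    for (int ax = 0; ax < d; ++ax) {
      F[(size_t)e.i * d + ax] =
        (wi * F[(size_t)e.i * d + ax] + wj * F[(size_t)e.j * d + ax]) / wn;
    }
    for (int ax = 0; ax < 3; ++ax) {
      P[(size_t)e.i * 3 + ax] =
        (wi * P[(size_t)e.i * 3 + ax] + wj * P[(size_t)e.j * 3 + ax]) / wn;
    }
    S[e.i] = (wi * S[e.i] + wj * S[e.j]) / wn;
    W[e.i] = wn;
    alive[e.j] = 0;
    parent[e.j] = e.i;
    version[e.i] += 1;
    --alive_count;
    // new candidates for the merged centroid
    for (int ax = 0; ax < d; ++ax) q[ax] = F[(size_t)e.i * d + ax];
    std::vector<int> nb = tree.query(q.data(), std::min(2 * k0, n - 1), -1);
    int added = 0;
    for (int ob : nb) {
      int r = find(ob);
      if (r != e.i && alive[r]) { push_edge(e.i, r); if (++added >= k0) break; }
    }
  }

  std::vector<int> keep;
  keep.reserve(alive_count);
  for (int i = 0; i < n; ++i) if (alive[i]) keep.push_back(i);
  int m = (int)keep.size();
  NumericVector values(m), weights(m);
  NumericMatrix positions(m, 3);
  for (int a = 0; a < m; ++a) {
    values[a] = S[keep[a]];
    weights[a] = W[keep[a]];
    for (int ax = 0; ax < 3; ++ax) positions(a, ax) = P[(size_t)keep[a] * 3 + ax];
  }
  return List::create(_["values"] = values, _["weights"] = weights,
                      _["positions"] = positions);
}
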
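// k-d tree over points in feature space, for k-nearest-neighbour queries on
// the enumerated control-candidate index. Median-split build, best-first
// pruned depth-first query with a bounded max-heap.
#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int point;   // row index of the splitting point
  int axis;
  int left, right;  // node indices, -1 if leaf side empty
};

struct Tree {
  std::vector<Node> nodes;
  NumericMatrix pts;
  int root;
};

int build(Tree& t, std::vector<int>& idx, int lo, int hi, int depth) {
  if (lo >= hi) return -1;
  int d = t.pts.ncol();
  int axis = depth % d;
  int mid = (lo + hi) / 2;
  const NumericMatrix& P = t.pts;
  std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                   [&](int a, int b) { return P(a, axis) < P(b, axis); });
  Node node;
  node.point = idx[mid];
  node.axis = axis;
  int self = (int)t.nodes.size();
  t.nodes.push_back(node);
  int l = build(t, idx, lo, mid, depth + 1);
  int r = build(t, idx, mid + 1, hi, depth + 1);
  t.nodes[self].left = l;
  t.nodes[self].right = r;
  return self;
}

typedef std::pair<double, int> HeapItem;  // (squared distance, point index)

void query(const Tree& t, int node, const NumericVector& q, int k,
           std::priority_queue<HeapItem>& heap) {
  if (node < 0) return;
  const Node& nd = t.nodes[node];
  double d2 = 0.0;
  for (int j = 0; j < t.pts.ncol(); ++j) {
    double diff = t.pts(nd.point, j) - q[j];
    d2 += diff * diff;
  }
  if ((int)heap.size() < k) {
    heap.push(HeapItem(d2, nd.point));
  } else if (d2 < heap.top().first) {
    heap.pop();
    heap.push(HeapItem(d2, nd.point));
  }
  double diff_axis = q[nd.axis] - t.pts(nd.point, nd.axis);
  int near = diff_axis <= 0 ? nd.left : nd.right;
  int far = diff_axis <= 0 ? nd.right : nd.left;
  query(t, near, q, k, heap);
  if ((int)heap.size() < k || diff_axis * diff_axis < heap.top().first) {
    query(t, far, q, k, heap);
  }
}

}  // namespace

// [[Rcpp::export]]
SEXP kdtree_build(NumericMatrix pts) {
  Tree* t = new Tree();
  t->pts = pts;
  std::vector<int> idx(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) idx[i] = i;
  t->nodes.reserve(pts.nrow());
  t->root = build(*t, idx, 0, pts.nrow(), 0);
  XPtr<Tree> ptr(t, true);
  return ptr;
}

// [[Rcpp::export]]
List kdtree_query(SEXP tree, NumericMatrix queries, int k) {
  XPtr<Tree> t(tree);
  int n = t->pts.nrow();
  int kk = std::min(k, n);
  int m = queries.nrow();
  IntegerMatrix idx(m, kk);
  NumericMatrix dist(m, kk);
  for (int i = 0; i < m; ++i) {
    NumericVector q = queries(i, _);
    std::priority_queue<HeapItem> heap;
    query(*t, t->root, q, kk, heap);
    int pos = (int)heap.size() - 1;
    while (!heap.empty()) {
      idx(i, pos) = heap.top().second + 1;  // 1-based for R
      dist(i, pos) = std::sqrt(heap.top().first);
      heap.pop();
      --pos;
    }
  }
  return List::create(Named("idx") = idx, Named("dist") = dist);
}
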
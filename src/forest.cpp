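// Weighted regression random forest (CART, variance reduction criterion).
//
// Implemented in-package because no tree-ensemble learner is available in
// the target environment. Semantics follow the common RF regressor:
// bootstrap bagging, per-split mtry feature subsampling, weighted-SSE
// splits, min_split / min_leaf (sample counts) and max_depth controls.
// Sample weights enter the split criterion and leaf values; bootstrap
// resampling is uniform (weights multiply the bootstrap counts).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;     // -1 for a leaf
  double threshold;
  int left, right; // node indices, -1 for a leaf
  double value;    // weighted mean of y in node
};

struct Problem {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, max_depth, min_split, min_leaf;
};

static void build_node(const Problem& pb,
                       std::vector<int>& idx, int lo, int hi,
                       const std::vector<double>& w,
                       int depth, std::vector<Node>& nodes, int me,
                       std::mt19937& rng,
                       std::vector<int>& feat_pool) {
  const int n = hi - lo;
  double sw = 0.0, swy = 0.0;
  for (int t = lo; t < hi; ++t) {
    sw += w[idx[t]];
    swy += w[idx[t]] * pb.y[idx[t]];
  }
  const double node_value = (sw > 0.0) ? swy / sw : 0.0;
  nodes[me].feature = -1;
  nodes[me].threshold = 0.0;
  nodes[me].left = nodes[me].right = -1;
  nodes[me].value = node_value;
  if (n < pb.min_split || n < 2 * pb.min_leaf ||
      (pb.max_depth > 0 && depth >= pb.max_depth))
    return;

  // constant-y check
  bool const_y = true;
  for (int t = lo + 1; t < hi; ++t)
    if (pb.y[idx[t]] != pb.y[idx[lo]]) { const_y = false; break; }
  if (const_y) return;

  const int p = pb.X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  for (int j = 0; j < p; ++j) feat_pool[j] = j;
  int best_f = -1, best_pos = -1;
  double best_thr = 0.0, best_score = R_PosInf;

  std::vector<int> ord(n);
  std::vector<int> best_ord;

  for (int m = 0; m < pb.mtry && m < p; ++m) {
    std::uniform_int_distribution<int> pick(m, p - 1);
    std::swap(feat_pool[m], feat_pool[pick(rng)]);
    const int f = feat_pool[m];
    for (int t = 0; t < n; ++t) ord[t] = idx[lo + t];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return pb.X(a, f) < pb.X(b, f);
    });
    double lw = 0.0, lwy = 0.0, lwy2 = 0.0;
    double tw = 0.0, twy = 0.0, twy2 = 0.0;
    for (int t = 0; t < n; ++t) {
      const double wi = w[ord[t]], yi = pb.y[ord[t]];
      tw += wi; twy += wi * yi; twy2 += wi * yi * yi;
    }
    for (int t = 0; t < n - 1; ++t) {
      const double wi = w[ord[t]], yi = pb.y[ord[t]];
      lw += wi; lwy += wi * yi; lwy2 += wi * yi * yi;
      if (pb.X(ord[t], f) == pb.X(ord[t + 1], f)) continue;
      const int nl = t + 1, nr = n - nl;
      if (nl < pb.min_leaf || nr < pb.min_leaf) continue;
      const double rw = tw - lw, rwy = twy - lwy, rwy2 = twy2 - lwy2;
      if (lw <= 0.0 || rw <= 0.0) continue;
      const double sse = (lwy2 - lwy * lwy / lw) + (rwy2 - rwy * rwy / rw);
      if (sse < best_score - 1e-12) {
        best_score = sse;
        best_f = f;
        best_thr = 0.5 * (pb.X(ord[t], f) + pb.X(ord[t + 1], f));
        best_pos = nl;
        best_ord = ord;
      }
    }
  }
  if (best_f < 0) return;
  const double parent_sse_proxy = best_score; (void)parent_sse_proxy;

  for (int t = 0; t < n; ++t) idx[lo + t] = best_ord[t];
  const int mid = lo + best_pos;

  const int li = (int)nodes.size(); nodes.push_back(Node());
  const int ri = (int)nodes.size(); nodes.push_back(Node());
  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  nodes[me].left = li;
  nodes[me].right = ri;
  build_node(pb, idx, lo, mid, w, depth + 1, nodes, li, rng, feat_pool);
  build_node(pb, idx, mid, hi, w, depth + 1, nodes, ri, rng, feat_pool);
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                int n_trees, int mtry, int max_depth,
                int min_split, int min_leaf, int seed, bool bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::mt19937 rng((unsigned)seed);
  List trees(n_trees);
  std::vector<int> feat_pool(p);
  Problem pb{X, y, mtry, max_depth, min_split, min_leaf};
  for (int b = 0; b < n_trees; ++b) {
    std::vector<double> wb(n, 0.0);
    std::vector<int> idx;
    if (bootstrap) {
      std::uniform_int_distribution<int> pick(0, n - 1);
      std::vector<int> cnt(n, 0);
      for (int t = 0; t < n; ++t) cnt[pick(rng)]++;
      for (int i = 0; i < n; ++i)
        if (cnt[i] > 0) { wb[i] = w[i] * cnt[i]; idx.push_back(i); }
    } else {
      for (int i = 0; i < n; ++i) { wb[i] = w[i]; idx.push_back(i); }
    }
    std::vector<Node> nodes;
    nodes.push_back(Node());
    build_node(pb, idx, 0, (int)idx.size(), wb, 0, nodes, 0, rng, feat_pool);
    NumericMatrix tm((int)nodes.size(), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feature;
      tm(k, 1) = nodes[k].threshold;
      tm(k, 2) = nodes[k].left;
      tm(k, 3) = nodes[k].right;
      tm(k, 4) = nodes[k].value;
    }
    trees[b] = tm;
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix tm = trees[b];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while ((int)tm(k, 0) >= 0) {
        const int f = (int)tm(k, 0);
        k = (X(i, f) <= tm(k, 1)) ? (int)tm(k, 2) : (int)tm(k, 3);
      }
      out[i] += tm(k, 4);
    }
  }
  return out / (double)B;
}
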
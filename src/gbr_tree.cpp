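// Gradient-boosted regression trees for squared-error loss: each boosting
// round fits an exact greedy CART tree (variance-reduction splits, depth
// and minimum-node-size limited) to the residuals and adds it with
// shrinkage. Trees are stored as complete binary arrays so the fitted
// ensemble serializes as a plain numeric matrix.
//
// Ensemble layout: first row (-1, f0, 0) holds the initial prediction;
// then one row per node of each tree: (feature, threshold, value) with
// feature = -1 marking a leaf (value = leaf prediction) and node index
// within a tree following the complete-binary-tree convention (children of
// node i at 2i+1, 2i+2). Rows per tree = 2^(depth+1) - 1.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

struct Node { int feature; double threshold; double value; };

static void fit_node(const std::vector<double>& xs, int p,
                     const std::vector<double>& resid,
                     std::vector<int>& idx, int lo, int hi, int depth,
                     int max_depth, int min_node, std::vector<Node>& nodes,
                     int node_id) {
  const int n = hi - lo;
  double sum = 0.0;
  for (int t = lo; t < hi; ++t) sum += resid[idx[t]];
  const double mean = sum / n;
  nodes[node_id] = {-1, 0.0, mean};
  if (depth >= max_depth || n < 2 * min_node) return;

  double parent_sse_term = sum * sum / n;
  double best_gain = 1e-12;
  int best_f = -1, best_pos = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  std::vector<int> best_ord;
  for (int f = 0; f < p; ++f) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return xs[(size_t)a * p + f] < xs[(size_t)b * p + f];
    });
    double lsum = 0.0;
    for (int t = 0; t < n - 1; ++t) {
      lsum += resid[ord[t]];
      int nl = t + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double xl = xs[(size_t)ord[t] * p + f];
      double xr = xs[(size_t)ord[t + 1] * p + f];
      if (xr <= xl) continue;  // cannot separate ties
      double rsum = sum - lsum;
      double gain = lsum * lsum / nl + rsum * rsum / nr - parent_sse_term;
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_pos = t;
        best_thr = 0.5 * (xl + xr);
        best_ord = ord;
      }
    }
  }
  if (best_f < 0) return;  // leaf: no admissible split

  nodes[node_id] = {best_f, best_thr, mean};
  std::copy(best_ord.begin(), best_ord.end(), idx.begin() + lo);
  int mid = lo + best_pos + 1;
  fit_node(xs, p, resid, idx, lo, mid, depth + 1, max_depth, min_node,
           nodes, 2 * node_id + 1);
  fit_node(xs, p, resid, idx, mid, hi, depth + 1, max_depth, min_node,
           nodes, 2 * node_id + 2);
}

static double tree_predict(const Node* nodes, const double* x) {
  int i = 0;
  while (nodes[i].feature >= 0)
    i = (x[nodes[i].feature] <= nodes[i].threshold) ? 2 * i + 1 : 2 * i + 2;
  return nodes[i].value;
}

// [[Rcpp::export]]
NumericMatrix gbr_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                          double learning_rate, int max_depth, int min_node) {
  const int n = X.nrow(), p = X.ncol();
  const int tree_nodes = (1 << (max_depth + 1)) - 1;
  std::vector<double> xs((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) xs[(size_t)i * p + k] = X(i, k);

  double f0 = std::accumulate(y.begin(), y.end(), 0.0) / n;
  std::vector<double> fhat(n, f0), resid(n);
  NumericMatrix ens(1 + n_trees * tree_nodes, 3);
  ens(0, 0) = -1.0; ens(0, 1) = f0; ens(0, 2) = 0.0;

  std::vector<int> idx(n);
  std::vector<Node> nodes(tree_nodes);
  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - fhat[i];
    std::iota(idx.begin(), idx.end(), 0);
    for (int t = 0; t < tree_nodes; ++t) nodes[t] = {-1, 0.0, 0.0};
    fit_node(xs, p, resid, idx, 0, n, 0, max_depth, min_node, nodes, 0);
    for (int i = 0; i < n; ++i)
      fhat[i] += learning_rate * tree_predict(nodes.data(), &xs[(size_t)i * p]);
    for (int t = 0; t < tree_nodes; ++t) {
      int r = 1 + m * tree_nodes + t;
      ens(r, 0) = nodes[t].feature;
      ens(r, 1) = nodes[t].threshold;
      ens(r, 2) = nodes[t].value;
    }
  }
  ens.attr("tree_nodes") = tree_nodes;
  ens.attr("learning_rate") = learning_rate;
  return ens;
}

// [[Rcpp::export]]
NumericVector gbr_predict_cpp(NumericMatrix ens, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  const int total = ens.nrow() - 1;
  int tree_nodes = ens.hasAttribute("tree_nodes")
    ? as<int>(ens.attr("tree_nodes")) : 0;
  double lr = ens.hasAttribute("learning_rate")
    ? as<double>(ens.attr("learning_rate")) : 1.0;
  if (tree_nodes <= 0)
    stop("ensemble matrix lacks the tree_nodes attribute");
  const int n_trees = total / tree_nodes;
  const double f0 = ens(0, 1);

  std::vector<Node> nodes((size_t)total);
  for (int t = 0; t < total; ++t)
    nodes[t] = {(int)ens(1 + t, 0), ens(1 + t, 1), ens(1 + t, 2)};

  std::vector<double> xrow(p);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < p; ++k) xrow[k] = X(i, k);
    double f = f0;
    for (int m = 0; m < n_trees; ++m)
      f += lr * tree_predict(&nodes[(size_t)m * tree_nodes], xrow.data());
    out[i] = f;
  }
  return out;
}
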
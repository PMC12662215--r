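// Bagged regression trees on a 0/1 outcome (a probability forest):
// each tree is grown on a bootstrap sample with per-split candidate-
// variable subsampling (mtry) and variance-reduction splits; the forest
// prediction is the mean of the trees' leaf means, an estimate of
// P(y = 1). Trees are stored flat: one node matrix per forest with
// per-tree offsets.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Node {
  int var;        // -1 for leaf
  double split;   // x[var] <= split goes left
  int left, right;
  double pred;
};

struct BuildItem {
  int node_id;
  int begin, end; // range in sample index buffer
  int depth;
};

static void grow_tree(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int>& samp, int mtry, int min_node,
                      int max_depth, std::mt19937& rng,
                      std::vector<Node>& nodes) {
  const int p = X.ncol();
  std::vector<int> vars(p);
  for (int j = 0; j < p; ++j) vars[j] = j;
  std::vector<std::pair<double, double> > xy;

  nodes.push_back(Node());
  std::vector<BuildItem> stack;
  stack.push_back(BuildItem{0, 0, (int)samp.size(), 0});

  while (!stack.empty()) {
    BuildItem it = stack.back();
    stack.pop_back();
    int n = it.end - it.begin;
    double sum = 0.0;
    for (int k = it.begin; k < it.end; ++k) sum += y[samp[k]];
    double mean = sum / n;
    Node& nd = nodes[it.node_id];
    nd.var = -1;
    nd.pred = mean;
    nd.left = nd.right = -1;

    bool pure = (sum < 1e-12) || (n - sum < 1e-12);
    if (n < min_node || pure || (max_depth > 0 && it.depth >= max_depth))
      continue;

    // candidate variables for this split
    std::shuffle(vars.begin(), vars.end(), rng);
    int best_var = -1;
    double best_split = 0.0, best_gain = 1e-12;
    double parent_score = sum * sum / n;

    for (int m = 0; m < mtry && m < p; ++m) {
      int j = vars[m];
      xy.clear();
      for (int k = it.begin; k < it.end; ++k)
        xy.push_back(std::make_pair(X(samp[k], j), y[samp[k]]));
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue;
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xy[i].second;
        if (xy[i + 1].first <= xy[i].first) continue;
        int nl = i + 1, nr = n - nl;
        double sr = sum - sl;
        double gain = sl * sl / nl + sr * sr / nr - parent_score;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = j;
          best_split = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (best_var < 0) continue;

    // partition sample range
    int mid = it.begin;
    for (int k = it.begin; k < it.end; ++k) {
      if (X(samp[k], best_var) <= best_split) {
        std::swap(samp[k], samp[mid]);
        ++mid;
      }
    }
    if (mid == it.begin || mid == it.end) continue; // numeric ties

    int li = (int)nodes.size();
    nodes.push_back(Node());
    int ri = (int)nodes.size();
    nodes.push_back(Node());
    nodes[it.node_id].var = best_var;
    nodes[it.node_id].split = best_split;
    nodes[it.node_id].left = li;
    nodes[it.node_id].right = ri;
    stack.push_back(BuildItem{li, it.begin, mid, it.depth + 1});
    stack.push_back(BuildItem{ri, mid, it.end, it.depth + 1});
  }
}

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int n_trees,
                    int mtry, int min_node, int max_depth, int seed) {
  const int n = X.nrow();
  if (n == 0) stop("empty training set");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<double> var_v, split_v, pred_v;
  std::vector<int> left_v, right_v, offset;

  std::vector<int> samp(n);
  std::vector<Node> nodes;
  for (int t = 0; t < n_trees; ++t) {
    for (int k = 0; k < n; ++k) samp[k] = pick(rng);
    nodes.clear();
    grow_tree(X, y, samp, mtry, min_node, max_depth, rng, nodes);
    int off = (int)var_v.size();
    offset.push_back(off);
    for (size_t q = 0; q < nodes.size(); ++q) {
      var_v.push_back(nodes[q].var);
      split_v.push_back(nodes[q].split);
      left_v.push_back(nodes[q].left < 0 ? -1 : nodes[q].left + off);
      right_v.push_back(nodes[q].right < 0 ? -1 : nodes[q].right + off);
      pred_v.push_back(nodes[q].pred);
    }
  }
  return List::create(
    _["var"] = IntegerVector(var_v.begin(), var_v.end()),
    _["split"] = NumericVector(split_v.begin(), split_v.end()),
    _["left"] = IntegerVector(left_v.begin(), left_v.end()),
    _["right"] = IntegerVector(right_v.begin(), right_v.end()),
    _["pred"] = NumericVector(pred_v.begin(), pred_v.end()),
    _["offset"] = IntegerVector(offset.begin(), offset.end()),
    _["n_trees"] = n_trees);
}

static void predict_raw(const int* var, const double* split,
                        const int* left, const int* right,
                        const double* pred, const int* offset, int n_trees,
                        const double* X, int n, double* out) {
  // X is column-major n x p; accumulate tree-major for cache locality
  for (int i = 0; i < n; ++i) out[i] = 0.0;
  for (int t = 0; t < n_trees; ++t) {
    const int root = offset[t];
    for (int i = 0; i < n; ++i) {
      int node = root;
      int v = var[node];
      while (v >= 0) {
        node = (X[(size_t)v * n + i] <= split[node]) ? left[node]
                                                     : right[node];
        v = var[node];
      }
      out[i] += pred[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= n_trees;
}

struct ForestView {
  IntegerVector var, left, right, offset;
  NumericVector split, pred;
  int n_trees;
  explicit ForestView(List f)
    : var(f["var"]), left(f["left"]), right(f["right"]),
      offset(f["offset"]), split(f["split"]), pred(f["pred"]),
      n_trees(f["n_trees"]) {}
};

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List forest, NumericMatrix X) {
  ForestView f(forest);
  NumericVector out(X.nrow());
  predict_raw(f.var.begin(), f.split.begin(), f.left.begin(),
              f.right.begin(), f.pred.begin(), f.offset.begin(), f.n_trees,
              X.begin(), X.nrow(), out.begin());
  return out;
}

// Partial dependence: for each grid value, force column `col` (0-based)
// to it for every row and return the mean prediction.
// [[Rcpp::export]]
NumericVector cpp_partial_dependence(List forest, NumericMatrix X,
                                     int col, NumericVector grid) {
  ForestView f(forest);
  const int n = X.nrow();
  NumericMatrix Xc = clone(X);
  std::vector<double> buf(n);
  NumericVector out(grid.size());
  for (int g = 0; g < grid.size(); ++g) {
    for (int i = 0; i < n; ++i) Xc(i, col) = grid[g];
    predict_raw(f.var.begin(), f.split.begin(), f.left.begin(),
                f.right.begin(), f.pred.begin(), f.offset.begin(),
                f.n_trees, Xc.begin(), n, buf.data());
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += buf[i];
    out[g] = acc / n;
  }
  return out;
}

// Two-variable partial dependence over the Cartesian grid (g1 outer
// varying slowest is column-major style: result index = i1 + g1.size()*i2
// with grid1 varying fastest).
// [[Rcpp::export]]
NumericVector cpp_partial_dependence2(List forest, NumericMatrix X,
                                      int col1, int col2,
                                      NumericVector grid1,
                                      NumericVector grid2) {
  ForestView f(forest);
  const int n = X.nrow();
  NumericMatrix Xc = clone(X);
  std::vector<double> buf(n);
  NumericVector out(grid1.size() * grid2.size());
  int k = 0;
  for (int g2 = 0; g2 < grid2.size(); ++g2) {
    for (int i = 0; i < n; ++i) Xc(i, col2) = grid2[g2];
    for (int g1 = 0; g1 < grid1.size(); ++g1, ++k) {
      for (int i = 0; i < n; ++i) Xc(i, col1) = grid1[g1];
      predict_raw(f.var.begin(), f.split.begin(), f.left.begin(),
                  f.right.begin(), f.pred.begin(), f.offset.begin(),
                  f.n_trees, Xc.begin(), n, buf.data());
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += buf[i];
      out[k] = acc / n;
    }
  }
  return out;
}
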
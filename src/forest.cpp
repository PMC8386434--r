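// Probability forest: an ensemble of CART-style classification trees whose
// terminal nodes store class frequencies; predictions are the frequencies
// averaged over trees (Malley-style probability machine). Splits minimize
// Gini impurity; variable importance is the total impurity decrease
// attributable to splits on a feature (mean decrease in impurity), averaged
// over trees. All randomness (bootstrap, mtry subsampling) comes from R's
// RNG so set.seed() makes fits reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;
  std::vector<double> probs; // class frequencies (leaves only)
};

struct Tree {
  std::vector<Node> nodes;
};

double gini(const std::vector<double> &cnt, double n) {
  if (n <= 0.0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += (c / n) * (c / n);
  return 1.0 - s;
}

int sample_int(int n) { // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int n_class, mtry, min_node;
  std::vector<double> &importance;
  Tree tree;

  Builder(const NumericMatrix &X_, const IntegerVector &y_, int K, int mtry_,
          int min_node_, std::vector<double> &imp)
      : X(X_), y(y_), n_class(K), mtry(mtry_), min_node(min_node_),
        importance(imp) {}

  int build(std::vector<int> &idx, int n_total) {
    int n = (int)idx.size();
    std::vector<double> cnt(n_class, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    double imp_node = gini(cnt, (double)n);

    int node_id = (int)tree.nodes.size();
    tree.nodes.push_back(Node());

    bool is_leaf = (n < std::max(2, min_node)) || imp_node <= 0.0;
    int best_f = -1;
    double best_thr = 0.0, best_gain = 0.0;
    std::vector<int> left_idx, right_idx;

    if (!is_leaf) {
      int p = X.ncol();
      // mtry features without replacement (partial Fisher-Yates on R RNG)
      std::vector<int> feats(p);
      for (int j = 0; j < p; ++j) feats[j] = j;
      int m = std::min(mtry, p);
      for (int j = 0; j < m; ++j)
        std::swap(feats[j], feats[j + sample_int(p - j)]);

      std::vector<std::pair<double, int>> vals(n);
      std::vector<double> cl(n_class), cr(n_class);
      for (int fj = 0; fj < m; ++fj) {
        int f = feats[fj];
        for (int i = 0; i < n; ++i)
          vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue;
        std::fill(cl.begin(), cl.end(), 0.0);
        cr = cnt;
        for (int i = 0; i < n - 1; ++i) {
          cl[vals[i].second] += 1.0;
          cr[vals[i].second] -= 1.0;
          if (vals[i].first == vals[i + 1].first) continue;
          double nl = i + 1.0, nr = n - i - 1.0;
          double gain = imp_node -
                        (nl / n) * gini(cl, nl) - (nr / n) * gini(cr, nr);
          if (gain > best_gain + 1e-15) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
      if (best_f < 0) {
        is_leaf = true;
      } else {
        for (int i : idx) {
          if (X(i, best_f) <= best_thr) left_idx.push_back(i);
          else right_idx.push_back(i);
        }
        if (left_idx.empty() || right_idx.empty()) is_leaf = true;
      }
    }

    if (is_leaf) {
      Node &nd = tree.nodes[node_id];
      nd.feature = -1;
      nd.left = nd.right = -1;
      nd.probs.resize(n_class);
      for (int k = 0; k < n_class; ++k) nd.probs[k] = cnt[k] / (double)n;
      return node_id;
    }

    importance[best_f] += best_gain * (double)n / (double)n_total;
    int li = build(left_idx, n_total);
    int ri = build(right_idx, n_total);
    Node &nd = tree.nodes[node_id];
    nd.feature = best_f;
    nd.threshold = best_thr;
    nd.left = li;
    nd.right = ri;
    return node_id;
  }
};

List serialize_tree(const Tree &t, int n_class) {
  int n = (int)t.nodes.size();
  IntegerMatrix topo(n, 3);
  NumericVector thr(n);
  NumericMatrix probs(n, n_class);
  for (int i = 0; i < n; ++i) {
    const Node &nd = t.nodes[i];
    topo(i, 0) = nd.feature;
    topo(i, 1) = nd.left;
    topo(i, 2) = nd.right;
    thr[i] = nd.feature < 0 ? NA_REAL : nd.threshold;
    if (nd.feature < 0)
      for (int k = 0; k < n_class; ++k) probs(i, k) = nd.probs[k];
  }
  return List::create(_["topo"] = topo, _["threshold"] = thr,
                      _["probs"] = probs);
}

} // namespace

// [[Rcpp::export(name = ".forest_fit_cpp")]]
List forest_fit_cpp(NumericMatrix X, IntegerVector y, int n_class,
                    int n_trees, int mtry, int min_node) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = sample_int(n); // bootstrap
    Builder b(X, y, n_class, mtry, min_node, importance);
    b.build(idx, n);
    trees[t] = serialize_tree(b.tree, n_class);
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / (double)n_trees;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["n_class"] = n_class);
}

// [[Rcpp::export(name = ".forest_predict_cpp")]]
NumericMatrix forest_predict_cpp(List forest, NumericMatrix X) {
  int n_class = as<int>(forest["n_class"]);
  List trees = forest["trees"];
  int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, n_class);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerMatrix topo = tr["topo"];
    NumericVector thr = tr["threshold"];
    NumericMatrix probs = tr["probs"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (topo(node, 0) >= 0)
        node = X(i, topo(node, 0)) <= thr[node] ? topo(node, 1)
                                                : topo(node, 2);
      for (int k = 0; k < n_class; ++k) out(i, k) += probs(node, k);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_class; ++k) out(i, k) /= (double)T;
  return out;
}
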
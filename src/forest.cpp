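// Random forest with exposed decision paths.
//
// Classic CART/Breiman forest (bootstrap, Gini, sqrt(d) candidate features,
// unlimited depth, min leaf 1) with one addition required for decision-path
// proximity: deterministic missing-value handling. Missing values are
// excluded from split-gain computation and routed down a stored
// majority branch, so every record follows exactly one root-to-leaf path and
// "identical decision sequence" is well defined.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuilder {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // 0-based node ids
  std::vector<int> majority;    // 0 = left, 1 = right (missing-value routing)
  std::vector<int> pred;        // majority class at node
  std::vector<std::vector<double>> counts; // per-node class counts

  int new_node(int k) {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    majority.push_back(0);
    pred.push_back(0);
    counts.push_back(std::vector<double>(k, 0.0));
    return (int)feature.size() - 1;
  }
};

inline double gini_from_counts(const std::vector<double>& cnt, double total) {
  if (total <= 0.0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += c * c;
  return 1.0 - s / (total * total);
}

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = -1.0;
};

// best Gini split among candidate features, missing values excluded
SplitResult best_split(const NumericMatrix& X, const IntegerVector& y,
                       const std::vector<int>& idx, int k,
                       const std::vector<int>& cand) {
  SplitResult best;
  const int m = (int)idx.size();
  std::vector<std::pair<double, int>> vals;
  vals.reserve(m);
  for (int f : cand) {
    vals.clear();
    for (int i : idx) {
      double v = X(i, f);
      if (!ISNAN(v)) vals.push_back({v, y[i]});
    }
    const int nv = (int)vals.size();
    if (nv < 2) continue;
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::vector<double> lcnt(k, 0.0), rcnt(k, 0.0);
    for (auto& p : vals) rcnt[p.second] += 1.0;
    double parent = gini_from_counts(rcnt, (double)nv);
    double nl = 0.0, nr = (double)nv;
    for (int t = 0; t < nv - 1; ++t) {
      lcnt[vals[t].second] += 1.0;
      rcnt[vals[t].second] -= 1.0;
      nl += 1.0;
      nr -= 1.0;
      if (vals[t].first == vals[t + 1].first) continue;
      double g = parent -
        (nl / nv) * gini_from_counts(lcnt, nl) -
        (nr / nv) * gini_from_counts(rcnt, nr);
      if (g > best.gain + 1e-12) {
        best.gain = g;
        best.feature = f;
        best.threshold = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  return best;
}

void grow(TreeBuilder& tb, int node, const NumericMatrix& X,
          const IntegerVector& y, std::vector<int>& idx, int k, int mtry,
          int min_node, std::mt19937& rng, std::vector<int>& featpool) {
  std::vector<double>& cnt = tb.counts[node];
  for (int i : idx) cnt[y[i]] += 1.0;
  int best_c = 0;
  for (int c = 1; c < k; ++c) if (cnt[c] > cnt[best_c]) best_c = c;
  tb.pred[node] = best_c;

  bool pure = true;
  for (int c = 0; c < k; ++c) {
    if (c != best_c && cnt[c] > 0.0) { pure = false; break; }
  }
  if (pure || (int)idx.size() < 2 * min_node || (int)idx.size() < 2) return;

  // sample mtry candidate features without replacement (partial Fisher-Yates)
  const int d = (int)featpool.size();
  for (int t = 0; t < mtry; ++t) {
    std::uniform_int_distribution<int> u(t, d - 1);
    std::swap(featpool[t], featpool[u(rng)]);
  }
  std::vector<int> cand(featpool.begin(), featpool.begin() + mtry);
  SplitResult sp = best_split(X, y, idx, k, cand);
  if (sp.feature < 0 || sp.gain <= 1e-12) return;

  std::vector<int> lidx, ridx, midx;
  for (int i : idx) {
    double v = X(i, sp.feature);
    if (ISNAN(v)) midx.push_back(i);
    else if (v <= sp.threshold) lidx.push_back(i);
    else ridx.push_back(i);
  }
  int maj = (ridx.size() > lidx.size()) ? 1 : 0; // ties go left
  for (int i : midx) (maj == 0 ? lidx : ridx).push_back(i);
  if (lidx.empty() || ridx.empty()) return;

  tb.feature[node] = sp.feature;
  tb.threshold[node] = sp.threshold;
  tb.majority[node] = maj;
  int ln = tb.new_node(k);
  int rn = tb.new_node(k);
  tb.left[node] = ln;
  tb.right[node] = rn;
  idx.clear(); idx.shrink_to_fit();
  grow(tb, ln, X, y, lidx, k, mtry, min_node, rng, featpool);
  grow(tb, rn, X, y, ridx, k, mtry, min_node, rng, featpool);
}

int traverse(const IntegerVector& feature, const NumericVector& threshold,
             const IntegerVector& left, const IntegerVector& right,
             const IntegerVector& majority, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    double v = X(row, feature[node]);
    bool go_left;
    if (ISNAN(v)) go_left = (majority[node] == 0);
    else go_left = (v <= threshold[node]);
    node = go_left ? left[node] : right[node];
  }
  return node;
}

} // namespace

// [[Rcpp::export(name = ".cpp_train_forest")]]
List cpp_train_forest(NumericMatrix X, IntegerVector y, int n_classes,
                      int n_trees, int mtry, int min_node, int seed) {
  const int n = X.nrow();
  const int d = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > d) mtry = d;
  std::mt19937 rng((uint32_t)seed);
  List trees(n_trees);
  std::vector<int> featpool(d);
  for (int t = 0; t < n_trees; ++t) {
    TreeBuilder tb;
    tb.new_node(n_classes);
    std::vector<int> idx(n);
    std::uniform_int_distribution<int> u(0, n - 1);
    for (int i = 0; i < n; ++i) idx[i] = u(rng);
    for (int i = 0; i < d; ++i) featpool[i] = i;
    grow(tb, 0, X, y, idx, n_classes, mtry, min_node, rng, featpool);
    int nn = (int)tb.feature.size();
    NumericMatrix cnts(nn, n_classes);
    for (int i = 0; i < nn; ++i)
      for (int c = 0; c < n_classes; ++c) cnts(i, c) = tb.counts[i][c];
    trees[t] = List::create(
      _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
      _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["majority"] = IntegerVector(tb.majority.begin(), tb.majority.end()),
      _["pred"] = IntegerVector(tb.pred.begin(), tb.pred.end()),
      _["counts"] = cnts);
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_leaf_ids")]]
IntegerMatrix cpp_leaf_ids(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  IntegerMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector majority = tr["majority"];
    for (int i = 0; i < n; ++i)
      out(i, t) = traverse(feature, threshold, left, right, majority, X, i);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_vote_matrix")]]
IntegerMatrix cpp_vote_matrix(List trees, IntegerMatrix leaf_ids) {
  const int n = leaf_ids.nrow();
  const int T = trees.size();
  IntegerMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) out(i, t) = pred[leaf_ids(i, t)];
  }
  return out;
}

// proximity of each query row (rows of leaf_q) against each corpus row
// [[Rcpp::export(name = ".cpp_proximity_counts")]]
IntegerMatrix cpp_proximity_counts(IntegerMatrix leaf_q, IntegerMatrix leaf_c) {
  const int nq = leaf_q.nrow();
  const int nc = leaf_c.nrow();
  const int T = leaf_q.ncol();
  IntegerMatrix out(nq, nc);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nc; ++j) {
      int s = 0;
      for (int t = 0; t < T; ++t)
        if (leaf_q(i, t) == leaf_c(j, t)) ++s;
      out(i, j) = s;
    }
  }
  return out;
}
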
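// Depth-limited regression trees on gradient-boosting pseudo-residuals.
// Splits maximise variance reduction (sum-of-squares gain); leaf values are
// the one-step Newton update sum(r) / (sum(p*(1-p)) + lambda). Feature
// subsampling per split and bootstrap row sampling use R's RNG, so results
// are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // 0-based split feature; -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // 0-based node ids; -1 for leaf
  std::vector<double> value;     // Newton leaf value (0 for internal)
};

// minimum gain required to accept a split; guards pure/degenerate nodes
const double MIN_GAIN = 1e-10;

int build_node(const NumericMatrix& X, const NumericVector& r,
               const NumericVector& w, double lambda,
               std::vector<int>& idx, int depth, int max_depth,
               int min_leaf, int mtry, Tree& T) {
  const int n = (int)idx.size();
  const int p = X.ncol();
  int node = (int)T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.value.push_back(0.0);

  bool can_split = depth < max_depth && n >= 2 * min_leaf;
  int best_f = -1;
  double best_thr = 0.0, best_gain = MIN_GAIN;

  if (can_split) {
    std::vector<int> feats;
    if (mtry < p) {
      IntegerVector s = sample(p, mtry, false);  // R RNG, 1-based
      feats.assign(s.begin(), s.end());
      for (int& f : feats) f -= 1;
      std::sort(feats.begin(), feats.end());
    } else {
      feats.resize(p);
      for (int f = 0; f < p; ++f) feats[f] = f;
    }

    double s_all = 0.0;
    for (int i : idx) s_all += r[i];

    std::vector<std::pair<double, int> > vi(n);
    for (int f : feats) {
      for (int j = 0; j < n; ++j) vi[j] = std::make_pair(X(idx[j], f), idx[j]);
      std::stable_sort(vi.begin(), vi.end());
      double sl = 0.0;
      for (int j = 0; j < n - 1; ++j) {
        sl += r[vi[j].second];
        int nl = j + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        if (vi[j].first == vi[j + 1].first) continue;  // not a boundary
        double sr = s_all - sl;
        double gain = sl * sl / nl + sr * sr / nr - s_all * s_all / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vi[j].first + vi[j + 1].first);
        }
      }
    }
  }

  if (best_f < 0) {
    double num = 0.0, den = lambda;
    for (int i : idx) { num += r[i]; den += w[i]; }
    T.value[node] = den > 0.0 ? num / den : 0.0;
    return node;
  }

  std::vector<int> lidx, ridx;
  lidx.reserve(n); ridx.reserve(n);
  for (int i : idx)
    (X(i, best_f) <= best_thr ? lidx : ridx).push_back(i);
  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  int l = build_node(X, r, w, lambda, lidx, depth + 1, max_depth, min_leaf, mtry, T);
  int rt = build_node(X, r, w, lambda, ridx, depth + 1, max_depth, min_leaf, mtry, T);
  T.left[node] = l;
  T.right[node] = rt;
  return node;
}

List tree_to_list(const Tree& T) {
  return List::create(_["feature"] = IntegerVector(T.feature.begin(), T.feature.end()),
                      _["threshold"] = NumericVector(T.threshold.begin(), T.threshold.end()),
                      _["left"] = IntegerVector(T.left.begin(), T.left.end()),
                      _["right"] = IntegerVector(T.right.begin(), T.right.end()),
                      _["value"] = NumericVector(T.value.begin(), T.value.end()));
}

inline double predict_row(const IntegerVector& feature, const NumericVector& threshold,
                          const IntegerVector& left, const IntegerVector& right,
                          const NumericVector& value, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = X(row, feature[node]) <= threshold[node] ? left[node] : right[node];
  return value[node];
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = predict_row(feature, threshold, left, right, value, X, i);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  int n = X.nrow(), m = trees.size();
  NumericVector out(n);
  for (int t = 0; t < m; ++t) {
    List tree = trees[t];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector left = tree["left"], right = tree["right"];
    NumericVector value = tree["value"];
    for (int i = 0; i < n; ++i)
      out[i] += predict_row(feature, threshold, left, right, value, X, i);
  }
  return out / (double)m;
}

// Fit one boosting round: a forest of n_trees regression trees on the
// pseudo-residuals r with Newton weights w = p*(1-p). Returns the fitted
// trees and the forest increment (mean tree output) for the training rows.
// [[Rcpp::export]]
List cpp_fit_round(NumericMatrix X, NumericVector r, NumericVector w,
                   double lambda, int n_trees, int max_depth, int min_leaf,
                   int mtry, bool bootstrap) {
  int n = X.nrow();
  List trees(n_trees);
  NumericVector h(n);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      IntegerVector s = sample(n, n, true);  // R RNG, 1-based
      for (int i = 0; i < n; ++i) idx[i] = s[i] - 1;
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Tree T;
    build_node(X, r, w, lambda, idx, 0, max_depth, min_leaf, mtry, T);
    List tl = tree_to_list(T);
    trees[t] = tl;
    IntegerVector feature = tl["feature"];
    NumericVector threshold = tl["threshold"];
    IntegerVector left = tl["left"], right = tl["right"];
    NumericVector value = tl["value"];
    for (int i = 0; i < n; ++i)
      h[i] += predict_row(feature, threshold, left, right, value, X, i);
  }
  return List::create(_["trees"] = trees, _["h"] = h / (double)n_trees);
}
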
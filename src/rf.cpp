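#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// CART-style regression trees for the random-forest surrogate.
// Splits maximize variance reduction (equivalently the sum of child
// mean-squared deviations), thresholds are midpoints of consecutive
// distinct sorted feature values, and ties break to the lowest feature
// index then the smallest threshold. All randomness comes from R's RNG
// so forests are reproducible via set.seed().

struct Node {
  int feature;      // -1 for a leaf
  double threshold;
  int left, right;  // child node ids, -1 for a leaf
  double value;     // leaf mean (mean of training targets in the node)
  int n;            // training samples in the node
};

struct TreeBuilder {
  const NumericMatrix &X;
  const NumericVector &y;
  int mtry, min_node_size;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix &X_, const NumericVector &y_, int mtry_,
              int min_node_size_)
      : X(X_), y(y_), mtry(mtry_), min_node_size(min_node_size_) {}

  int build(std::vector<int> &idx) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    int n = (int)idx.size();
    double sum = 0.0, sum2 = 0.0;
    for (int k = 0; k < n; ++k) {
      sum += y[idx[k]];
      sum2 += y[idx[k]] * y[idx[k]];
    }
    double mean = sum / n;
    nodes[id].value = mean;
    nodes[id].n = n;
    nodes[id].feature = -1;
    nodes[id].threshold = NA_REAL;
    nodes[id].left = nodes[id].right = -1;
    double node_ss = sum2 - sum * sum / n;
    if (n < min_node_size || node_ss <= 1e-12) return id;

    // sample mtry distinct features, then visit in ascending index order
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
    for (int k = 0; k < mtry; ++k) {
      int r = k + (int)(unif_rand() * (p - k));
      if (r >= p) r = p - 1;
      std::swap(feats[k], feats[r]);
    }
    feats.resize(mtry);
    std::sort(feats.begin(), feats.end());

    int best_feat = -1;
    double best_thr = 0.0, best_score = -1.0;
    std::vector<std::pair<double, int> > vals(n);
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      int f = feats[fi];
      for (int k = 0; k < n; ++k)
        vals[k] = std::make_pair(X(idx[k], f), idx[k]);
      std::sort(vals.begin(), vals.end());
      double cum = 0.0;
      int nl = 0;
      for (int k = 0; k < n - 1; ++k) {
        cum += y[vals[k].second];
        ++nl;
        if (vals[k + 1].first <= vals[k].first) continue; // tie in value
        // score = sum_L^2/n_L + sum_R^2/n_R (maximizing this maximizes
        // the variance reduction of the split)
        double sl = cum, sr = sum - cum;
        double score = sl * sl / nl + sr * sr / (n - nl);
        if (score > best_score + 1e-12) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_feat < 0) return id; // no admissible split on sampled features

    std::vector<int> left_idx, right_idx;
    for (int k = 0; k < n; ++k) {
      if (X(idx[k], best_feat) <= best_thr)
        left_idx.push_back(idx[k]);
      else
        right_idx.push_back(idx[k]);
    }
    int l = build(left_idx);
    int r = build(right_idx);
    nodes[id].feature = best_feat;
    nodes[id].threshold = best_thr;
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
};

static List tree_to_list(const std::vector<Node> &nodes) {
  int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m), nn(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
    nn[i] = nodes[i].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["n"] = nn);
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node_size, bool bootstrap) {
  RNGScope scope;
  int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx;
    idx.reserve(n);
    if (bootstrap) {
      for (int k = 0; k < n; ++k) {
        int r = (int)(unif_rand() * n);
        if (r >= n) r = n - 1;
        idx.push_back(r);
        inbag(r, t) += 1;
      }
      std::sort(idx.begin(), idx.end());
    } else {
      for (int k = 0; k < n; ++k) {
        idx.push_back(k);
        inbag(k, t) = 1;
      }
    }
    TreeBuilder tb(X, y, mtry, min_node_size);
    tb.build(idx);
    trees[t] = tree_to_list(tb.nodes);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// walk every row of X down one tree; adds into (or writes to) out
static void predict_tree_rows(const List &tree, const NumericMatrix &X,
                              double *out, bool accumulate) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    if (accumulate)
      out[i] += value[node];
    else
      out[i] = value[node];
  }
}

// mean over trees, one prediction per row of X
// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tree = trees[t];
    predict_tree_rows(tree, X, REAL(out), true);
  }
  return out / (double)ntree;
}

// per-tree predictions for every row (n x ntree), used for OOB error
// [[Rcpp::export]]
NumericMatrix rf_predict_all_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix out(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    List tree = trees[t];
    predict_tree_rows(tree, X, &out(0, t), false);
  }
  return out;
}
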
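// Greedy regression-tree growing and squared-error gradient boosting.
// Kept in C++ because fitting hundreds of trees per cross-validation fold
// dominates the runtime of grid search and repeated CV. Bagging index
// draws are made in R (R's RNG), so a seed fully determines the ensemble.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Tree {
  // flat node arrays; var = -1 marks a leaf
  std::vector<int> var;
  std::vector<double> split;
  std::vector<int> left, right;
  std::vector<double> value;    // leaf prediction (mean residual)
  std::vector<double> improve;  // SSE reduction achieved by the split
};

// exhaustive best-split search on rows `idx`; returns true if a split with
// positive SSE reduction exists subject to min_obs per child
static bool best_split(const NumericMatrix& X, const std::vector<double>& r,
                       const std::vector<int>& idx, int min_obs,
                       int& bvar, double& bsplit, double& bimp) {
  const int n = (int)idx.size(), p = X.ncol();
  if (n < 2 * min_obs) return false;
  double sum = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) sum += r[idx[i]];
  const double mean = sum / n;
  for (int i = 0; i < n; ++i) {
    const double d = r[idx[i]] - mean;
    ss += d * d;
  }
  bimp = 0.0; bvar = -1; bsplit = 0.0;
  // contiguous per-feature buffers: sorting indexes into these instead of
  // the R matrix keeps the comparator cache-friendly
  std::vector<double> val(n), rv(n);
  std::vector<int> ord(n);
  const double* Xp = X.begin();
  const int nrow = X.nrow();
  for (int j = 0; j < p; ++j) {
    const double* col = Xp + (size_t)j * nrow;
    for (int i = 0; i < n; ++i) val[i] = col[idx[i]];
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return val[a] < val[b]; });
    for (int i = 0; i < n; ++i) rv[i] = r[idx[ord[i]]];
    double lsum = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      lsum += rv[i];
      const double xl = val[ord[i]], xr = val[ord[i + 1]];
      if (xl == xr) continue;               // split only between distinct values
      const int nl = i + 1, nr = n - nl;
      if (nl < min_obs || nr < min_obs) continue;
      const double rsum = sum - lsum;
      // SSE reduction = nl*ml^2 + nr*mr^2 - n*mean^2 (means of residuals)
      const double imp = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (imp > bimp) {
        bimp = imp;
        bvar = j;
        bsplit = (xl + xr) / 2.0;
      }
    }
  }
  return bvar >= 0 && bimp > 0.0;
}

static int grow(const NumericMatrix& X, const std::vector<double>& r,
                const std::vector<int>& idx, int depth, int max_depth,
                int min_obs, Tree& t) {
  const int node = (int)t.var.size();
  double sum = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) sum += r[idx[i]];
  t.var.push_back(-1);
  t.split.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(idx.empty() ? 0.0 : sum / (double)idx.size());
  t.improve.push_back(0.0);
  if (depth >= max_depth) return node;
  int bvar; double bsplit, bimp;
  if (!best_split(X, r, idx, min_obs, bvar, bsplit, bimp)) return node;
  std::vector<int> li, ri;
  for (size_t i = 0; i < idx.size(); ++i) {
    if (X(idx[i], bvar) <= bsplit) li.push_back(idx[i]);
    else ri.push_back(idx[i]);
  }
  t.var[node] = bvar;
  t.split[node] = bsplit;
  t.improve[node] = bimp;
  t.left[node] = grow(X, r, li, depth + 1, max_depth, min_obs, t);
  t.right[node] = grow(X, r, ri, depth + 1, max_depth, min_obs, t);
  return node;
}

static double tree_pred_row(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.var[node] >= 0)
    node = (X(row, t.var[node]) <= t.split[node]) ? t.left[node] : t.right[node];
  return t.value[node];
}

static List tree_to_list(const Tree& t) {
  return List::create(_["var"] = IntegerVector(t.var.begin(), t.var.end()),
                      _["split"] = NumericVector(t.split.begin(), t.split.end()),
                      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
                      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
                      _["value"] = NumericVector(t.value.begin(), t.value.end()),
                      _["improve"] = NumericVector(t.improve.begin(), t.improve.end()));
}

static Tree tree_from_list(const List& l) {
  Tree t;
  IntegerVector var = l["var"], left = l["left"], right = l["right"];
  NumericVector split = l["split"], value = l["value"], improve = l["improve"];
  t.var.assign(var.begin(), var.end());
  t.split.assign(split.begin(), split.end());
  t.left.assign(left.begin(), left.end());
  t.right.assign(right.begin(), right.end());
  t.value.assign(value.begin(), value.end());
  t.improve.assign(improve.begin(), improve.end());
  return t;
}

// [[Rcpp::export]]
List fit_single_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                         int max_depth, int min_obs) {
  std::vector<double> r(y.begin(), y.end());
  std::vector<int> idx(rows.begin(), rows.end());  // 0-based
  Tree t;
  grow(X, r, idx, 0, max_depth, min_obs, t);
  return tree_to_list(t);
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  Tree t = tree_from_list(tree);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tree_pred_row(t, X, i);
  return out;
}

// Full boosting loop: F0 = mean(y); per iteration fit a tree to current
// residuals on the bagged rows, then F += lr * tree(X) on all rows.
// bags: bag_size x n_trees matrix of 1-based row indices drawn in R.
// [[Rcpp::export]]
List boost_fit_cpp(NumericMatrix X, NumericVector y, IntegerMatrix bags,
                   double learning_rate, int max_depth, int min_obs) {
  const int n = X.nrow(), n_trees = bags.ncol();
  const double f0 = mean(y);
  std::vector<double> F(n, f0), r(n);
  NumericVector deviance(n_trees);
  List trees(n_trees);
  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) r[i] = y[i] - F[i];
    std::vector<int> idx(bags.nrow());
    for (int i = 0; i < bags.nrow(); ++i) idx[i] = bags(i, m) - 1;
    Tree t;
    grow(X, r, idx, 0, max_depth, min_obs, t);
    double dev = 0.0;
    for (int i = 0; i < n; ++i) {
      F[i] += learning_rate * tree_pred_row(t, X, i);
      const double d = y[i] - F[i];
      dev += d * d;
    }
    deviance[m] = dev / n;
    trees[m] = tree_to_list(t);
  }
  return List::create(_["init"] = f0, _["trees"] = trees,
                      _["train_deviance"] = deviance);
}

// [[Rcpp::export]]
NumericVector boost_predict_cpp(List trees, double init, double learning_rate,
                                NumericMatrix X) {
  const int n = X.nrow(), m = trees.size();
  NumericVector out(n, init);
  for (int k = 0; k < m; ++k) {
    Tree t = tree_from_list(trees[k]);
    for (int i = 0; i < n; ++i) out[i] += learning_rate * tree_pred_row(t, X, i);
  }
  return out;
}
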
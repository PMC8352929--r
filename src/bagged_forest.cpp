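// Bagged CART regression forest used for per-sample m/z-error modelling.
// Variance-reduction splits, `mtry` candidate predictors per node, minimum
// terminal node size `min_node`. RNG comes from R (set.seed-reproducible).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> var;        // split variable, -1 for leaf
  std::vector<double> split;   // split point (go left if x <= split)
  std::vector<int> left, right;
  std::vector<double> pred;    // leaf prediction (node mean)
};

static int new_node(Tree &t) {
  t.var.push_back(-1); t.split.push_back(0.0);
  t.left.push_back(-1); t.right.push_back(-1); t.pred.push_back(0.0);
  return (int)t.var.size() - 1;
}

// Best split of rows [lo,hi) of idx on variable v; returns SSE gain and
// fills cut. Children must each hold >= min_node rows.
static double best_split_var(const NumericMatrix &X, const NumericVector &y,
                             std::vector<int> &idx, int lo, int hi, int v,
                             int min_node, double &cut) {
  const int n = hi - lo;
  std::vector<std::pair<double,double>> xv(n);
  for (int i = 0; i < n; ++i)
    xv[i] = std::make_pair(X(idx[lo + i], v), y[idx[lo + i]]);
  std::sort(xv.begin(), xv.end());
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += xv[i].second;
  double best = -1.0, acc = 0.0;
  const double base = tot * tot / n;
  cut = NA_REAL;
  for (int i = 0; i < n - 1; ++i) {
    acc += xv[i].second;
    const int nl = i + 1, nr = n - nl;
    if (nl < min_node) continue;
    if (nr < min_node) break;
    if (xv[i].first == xv[i + 1].first) continue;  // no cut between ties
    const double gain = acc * acc / nl +
      (tot - acc) * (tot - acc) / nr - base;
    if (gain > best) {
      best = gain;
      cut = 0.5 * (xv[i].first + xv[i + 1].first);
    }
  }
  return best;
}

static void grow(Tree &t, int node, const NumericMatrix &X,
                 const NumericVector &y, std::vector<int> &idx,
                 int lo, int hi, int mtry, int min_node) {
  const int n = hi - lo;
  double mean = 0.0;
  for (int i = lo; i < hi; ++i) mean += y[idx[i]];
  mean /= n;
  t.pred[node] = mean;
  if (n < 2 * min_node) return;
  const int p = X.ncol();
  // sample mtry distinct predictors via R's RNG
  std::vector<int> vars(p);
  for (int j = 0; j < p; ++j) vars[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(vars[j], vars[k]);
  }
  double best = 0.0, best_cut = NA_REAL;
  int best_var = -1;
  for (int j = 0; j < m; ++j) {
    double cut;
    const double g = best_split_var(X, y, idx, lo, hi, vars[j], min_node,
                                    cut);
    if (g > best && R_finite(cut)) { best = g; best_cut = cut;
                                     best_var = vars[j]; }
  }
  if (best_var < 0) return;
  // partition idx[lo,hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_var) <= best_cut) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;  // degenerate, keep leaf
  t.var[node] = best_var; t.split[node] = best_cut;
  const int l = new_node(t), r = new_node(t);
  t.left[node] = l; t.right[node] = r;
  grow(t, l, X, y, idx, lo, mid, mtry, min_node);
  grow(t, r, X, y, idx, mid, hi, mtry, min_node);
}

// [[Rcpp::export(name = ".bagged_forest_train")]]
List bagged_forest_train(NumericMatrix X, NumericVector y, int ntree,
                         int mtry, int min_node) {
  const int n = X.nrow();
  if (n < 1) stop("empty training set");
  RNGScope scope;
  List trees(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    Tree t;
    const int root = new_node(t);
    grow(t, root, X, y, idx, 0, n, mtry, min_node);
    trees[b] = List::create(
      _["var"] = IntegerVector(t.var.begin(), t.var.end()),
      _["split"] = NumericVector(t.split.begin(), t.split.end()),
      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
      _["pred"] = NumericVector(t.pred.begin(), t.pred.end()));
  }
  return trees;
}

// [[Rcpp::export(name = ".bagged_forest_predict")]]
NumericVector bagged_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    List t = trees[b];
    IntegerVector var = t["var"], left = t["left"], right = t["right"];
    NumericVector split = t["split"], pred = t["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (var[node] >= 0)
        node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
      out[i] += pred[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
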
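// Weighted regression trees, bagged forests and logistic gradient boosting.
//
// The machine-learning SDM family needs a random forest and a boosted
// regression tree honouring per-record case weights. Both are built on one
// primitive: a CART-style regression tree with weighted variance-reduction
// splits. RF = weighted bootstrap + mtry feature subsampling, averaging
// tree means (probability forest). BRT = Friedman gradient boosting with
// logistic loss and Newton leaf updates.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Tree {
  std::vector<int> var, left, right;     // var = -1 for leaves
  std::vector<double> split, pred;
  int add_node() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    split.push_back(NA_REAL); pred.push_back(0.0);
    return (int)var.size() - 1;
  }
};

// Recursive growth on row indices [lo, hi) of idx (reordered in place).
// leaf_of (optional, length n over original rows) records terminal nodes.
static void grow(Tree &t, int node, const NumericMatrix &X,
                 const std::vector<double> &y, const std::vector<double> &w,
                 std::vector<int> &idx, int lo, int hi, int depth,
                 int max_depth, int min_node, int mtry,
                 std::mt19937 &rng, std::vector<int> *leaf_of) {
  const int n = hi - lo, p = X.ncol();
  double sw = 0, swy = 0;
  for (int i = lo; i < hi; ++i) { sw += w[idx[i]]; swy += w[idx[i]] * y[idx[i]]; }
  const double mean = swy / sw;
  t.pred[node] = mean;

  bool stop_here = (depth >= max_depth) || (n < 2 * min_node);
  if (!stop_here) {             // purity check
    bool pure = true;
    for (int i = lo + 1; i < hi; ++i)
      if (y[idx[i]] != y[idx[lo]]) { pure = false; break; }
    stop_here = pure;
  }

  int best_var = -1;
  double best_split = 0, best_gain = 1e-12;
  std::vector<int> feats(p);
  if (!stop_here) {
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {     // partial Fisher-Yates
      std::uniform_int_distribution<int> u(j, p - 1);
      std::swap(feats[j], feats[u(rng)]);
    }
    std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
    for (int jj = 0; jj < m; ++jj) {
      const int j = feats[jj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, j) < X(b, j);
      });
      double wl = 0, wyl = 0;
      for (int k = 0; k < n - 1; ++k) {
        const int r = ord[k];
        wl += w[r]; wyl += w[r] * y[r];
        if (X(ord[k], j) == X(ord[k + 1], j)) continue;  // no gap
        if (k + 1 < min_node || n - k - 1 < min_node) continue;
        const double wr = sw - wl, wyr = swy - wyl;
        if (wl <= 0 || wr <= 0) continue;
        const double gain = wyl * wyl / wl + wyr * wyr / wr - swy * swy / sw;
        if (gain > best_gain) {
          best_gain = gain; best_var = j;
          best_split = 0.5 * (X(ord[k], j) + X(ord[k + 1], j));
        }
      }
    }
  }

  if (stop_here || best_var < 0) {
    if (leaf_of) for (int i = lo; i < hi; ++i) (*leaf_of)[idx[i]] = node;
    return;
  }

  // partition idx[lo,hi) by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_var) < best_split) std::swap(idx[i], idx[mid++]);
  t.var[node] = best_var; t.split[node] = best_split;
  const int L = t.add_node(), R = t.add_node();
  t.left[node] = L; t.right[node] = R;
  grow(t, L, X, y, w, idx, lo, mid, depth + 1, max_depth, min_node, mtry, rng, leaf_of);
  grow(t, R, X, y, w, idx, mid, hi, depth + 1, max_depth, min_node, mtry, rng, leaf_of);
}

static List tree_to_list(const Tree &t) {
  return List::create(_["var"] = wrap(t.var), _["split"] = wrap(t.split),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["pred"] = wrap(t.pred));
}

// accumulate one tree's predictions over all rows of X into out
static void predict_tree(const List &tr, const NumericMatrix &X,
                         NumericVector &out, double scale) {
  const IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
  const NumericVector split = tr["split"], pred = tr["pred"];
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) < split[node]) ? left[node] : right[node];
    out[i] += scale * pred[node];
  }
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                int ntree, int mtry, int max_depth, int min_node, int seed) {
  const int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::discrete_distribution<int> boot(w.begin(), w.end());
  std::vector<double> yy(y.begin(), y.end());
  std::vector<double> unit(n, 1.0);
  List trees(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);   // weighted bootstrap
    Tree t; t.add_node();
    grow(t, 0, X, yy, unit, idx, 0, n, 0, max_depth, min_node, mtry, rng, nullptr);
    trees[b] = tree_to_list(t);
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    predict_tree(tr, X, out, 1.0 / B);
  }
  for (int i = 0; i < n; ++i) out[i] = std::min(1.0, std::max(0.0, out[i]));
  return out;
}

// [[Rcpp::export(name = ".brt_fit_cpp")]]
List brt_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                 int ntree, int interaction_depth, double shrinkage,
                 int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  double sw = 0, swy = 0;
  for (int i = 0; i < n; ++i) { sw += w[i]; swy += w[i] * y[i]; }
  double pbar = std::min(1 - 1e-6, std::max(1e-6, swy / sw));
  const double F0 = std::log(pbar / (1 - pbar));
  std::vector<double> F(n, F0), ww(w.begin(), w.end());
  List trees(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<double> resid(n);
    std::vector<double> prob(n);
    for (int i = 0; i < n; ++i) {
      prob[i] = 1.0 / (1.0 + std::exp(-F[i]));
      resid[i] = y[i] - prob[i];
    }
    std::vector<int> idx(n), leaf_of(n, -1);
    for (int i = 0; i < n; ++i) idx[i] = i;
    Tree t; t.add_node();
    grow(t, 0, X, resid, ww, idx, 0, n, 0, interaction_depth, min_node, p,
         rng, &leaf_of);
    // Newton step per terminal node: gamma = sum(w r) / sum(w p (1-p))
    const int nn = (int)t.var.size();
    std::vector<double> num(nn, 0), den(nn, 0);
    for (int i = 0; i < n; ++i) {
      num[leaf_of[i]] += ww[i] * resid[i];
      den[leaf_of[i]] += ww[i] * prob[i] * (1 - prob[i]);
    }
    for (int k = 0; k < nn; ++k)
      if (t.var[k] < 0) {
        double g = (den[k] > 1e-12) ? num[k] / den[k] : 0.0;
        t.pred[k] = std::min(4.0, std::max(-4.0, g));
      }
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (t.var[node] >= 0)
        node = (X(i, t.var[node]) < t.split[node]) ? t.left[node] : t.right[node];
      F[i] += shrinkage * t.pred[node];
    }
    trees[b] = tree_to_list(t);
  }
  return List::create(_["F0"] = F0, _["shrinkage"] = shrinkage,
                      _["trees"] = trees);
}

// [[Rcpp::export(name = ".brt_predict_cpp")]]
NumericVector brt_predict_cpp(List fit, NumericMatrix X) {
  const double F0 = fit["F0"], shrink = fit["shrinkage"];
  List trees = fit["trees"];
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n, F0);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    predict_tree(tr, X, out, shrink);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
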
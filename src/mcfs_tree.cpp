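#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Binary decision trees with base-2 entropy impurity, grown to purity
// (min-leaf constraint, no pruning).  Used both standalone and inside the
// Monte Carlo feature-selection loop, where per-node information gain and
// node sample counts feed the relative-importance score
//   RI_g = sum over trees (wAcc)^u * IG(node) * (n_node / n_root)^v.

static double entropy2(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double h = 0.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    if (cnt[c] > 0) {
      double pr = (double)cnt[c] / n;
      h -= pr * std::log2(pr);
    }
  }
  return h;
}

struct TreeBuilder {
  const NumericMatrix &X;    // n x m (already restricted to the feature subset)
  const IntegerVector &y;    // 0-based class codes
  int K;
  int min_leaf;
  double v_exp;
  int n_root;

  // flat tree arrays; feat = -1 marks a leaf
  std::vector<int> feat;
  std::vector<double> thr;
  std::vector<int> left, right, pred, nnode;
  std::vector<double> ig;

  // per-local-feature accumulated IG * (n_node/n_root)^v
  std::vector<double> contrib;

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_, int K_,
              int min_leaf_, double v_exp_)
      : X(X_), y(y_), K(K_), min_leaf(min_leaf_), v_exp(v_exp_), n_root(0),
        contrib(X_.ncol(), 0.0) {}

  int new_leaf(const std::vector<int> &cnt) {
    int best = 0;
    for (int c = 1; c < K; ++c)
      if (cnt[c] > cnt[best]) best = c;   // tie -> smallest class code
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    pred.push_back(best); ig.push_back(0.0);
    nnode.push_back(0);
    return (int)feat.size() - 1;
  }

  int build(std::vector<int> &idx) {
    int n = (int)idx.size();
    std::vector<int> cnt(K, 0);
    for (int i = 0; i < n; ++i) cnt[y[idx[i]]]++;
    int present = 0;
    for (int c = 0; c < K; ++c) if (cnt[c] > 0) present++;
    if (present <= 1 || n < 2 * min_leaf) {
      int node = new_leaf(cnt);
      nnode[node] = n;
      return node;
    }
    double H = entropy2(cnt, n);

    int m = X.ncol();
    int best_j = -1, best_i = -1;
    double best_ig = 1e-12, best_thr = 0.0;
    std::vector<std::pair<double,int> > vals(n);
    std::vector<std::pair<double,int> > best_vals;
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], j), (int)y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      std::vector<int> cl(K, 0);
      for (int i = 0; i < n - 1; ++i) {
        cl[vals[i].second]++;
        if (vals[i].first >= vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        std::vector<int> cr(K);
        for (int c = 0; c < K; ++c) cr[c] = cnt[c] - cl[c];
        double igv = H - (nl * entropy2(cl, nl) + nr * entropy2(cr, nr)) / n;
        if (igv > best_ig) {           // strict > : ties keep the first
          best_ig = igv;               // (lowest feature index, lowest threshold)
          best_j = j;
          best_i = i;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
          best_vals = vals;
        }
      }
    }
    if (best_j < 0) {
      int node = new_leaf(cnt);
      nnode[node] = n;
      return node;
    }

    contrib[best_j] += best_ig * std::pow((double)n / n_root, v_exp);

    std::vector<int> li, ri_;
    li.reserve(best_i + 1); ri_.reserve(n - best_i - 1);
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_j) <= best_thr) li.push_back(idx[i]);
      else ri_.push_back(idx[i]);
    }
    feat.push_back(best_j); thr.push_back(best_thr);
    left.push_back(-1); right.push_back(-1);
    pred.push_back(-1); ig.push_back(best_ig); nnode.push_back(n);
    int node = (int)feat.size() - 1;
    int l = build(li);
    int r = build(ri_);
    left[node] = l;
    right[node] = r;
    return node;
  }

  int predict_one(int root, int row) const {
    int node = root;
    while (feat[node] >= 0)
      node = (X(row, feat[node]) <= thr[node]) ? left[node] : right[node];
    return pred[node];
  }
};

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y, int K, int min_leaf,
                   double v_exp) {
  TreeBuilder tb(X, y, K, min_leaf, v_exp);
  int n = X.nrow();
  tb.n_root = n;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int root = tb.build(idx);
  return List::create(
      _["root"] = root,
      _["feature"] = IntegerVector(tb.feat.begin(), tb.feat.end()),
      _["threshold"] = NumericVector(tb.thr.begin(), tb.thr.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["pred"] = IntegerVector(tb.pred.begin(), tb.pred.end()),
      _["ig"] = NumericVector(tb.ig.begin(), tb.ig.end()),
      _["n_node"] = IntegerVector(tb.nnode.begin(), tb.nnode.end()),
      _["n_root"] = n,
      _["contrib"] = NumericVector(tb.contrib.begin(), tb.contrib.end()));
}

// [[Rcpp::export]]
IntegerVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector thr = tree["threshold"];
  int root = as<int>(tree["root"]);
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = root;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = pred[node];
  }
  return out;
}

// Monte Carlo feature selection: t random feature subsets of size m, p trees
// per subset, each tree on a bootstrap resample and scored by balanced
// accuracy (mean per-class recall) on its out-of-bag samples.
// Uses R's RNG, so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List mcfs_run_cpp(NumericMatrix X, IntegerVector y, int K, int m, int t,
                  int p, double u, double v, int min_leaf, bool collect) {
  int n = X.nrow(), M = X.ncol();
  NumericVector ri(M);
  List trees(collect ? t * p : 0);
  IntegerVector all_feats(M);
  for (int j = 0; j < M; ++j) all_feats[j] = j;

  NumericMatrix Xs(n, m);
  std::vector<int> inbag(n);
  int tree_slot = 0;

  for (int s = 0; s < t; ++s) {
    IntegerVector sub = Rcpp::sample(all_feats, m, false);  // R RNG
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) Xs(i, j) = X(i, sub[j]);

    for (int q = 0; q < p; ++q) {
      std::fill(inbag.begin(), inbag.end(), 0);
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) {
        int r = (int)std::floor(unif_rand() * n);
        if (r == n) r = n - 1;
        idx[i] = r;
        inbag[r] = 1;
      }
      TreeBuilder tb(Xs, y, K, min_leaf, v);
      tb.n_root = n;
      int root = tb.build(idx);

      // out-of-bag balanced accuracy
      std::vector<int> tru(K, 0), cor(K, 0);
      for (int i = 0; i < n; ++i) {
        if (inbag[i]) continue;
        int ph = tb.predict_one(root, i);
        tru[y[i]]++;
        if (ph == y[i]) cor[y[i]]++;
      }
      double wacc = 0.0;
      int nc = 0;
      for (int c = 0; c < K; ++c)
        if (tru[c] > 0) { wacc += (double)cor[c] / tru[c]; nc++; }
      wacc = (nc > 0) ? wacc / nc : 0.0;
      double w = std::pow(wacc, u);

      for (int j = 0; j < m; ++j) ri[sub[j]] += w * tb.contrib[j];

      if (collect) {
        std::vector<int> nz_f;
        std::vector<double> nz_c;
        for (int j = 0; j < m; ++j)
          if (tb.contrib[j] > 0) {
            nz_f.push_back(sub[j] + 1);         // 1-based for R
            nz_c.push_back(w * tb.contrib[j]);
          }
        trees[tree_slot++] = List::create(
            _["features"] = IntegerVector(nz_f.begin(), nz_f.end()),
            _["contrib"] = NumericVector(nz_c.begin(), nz_c.end()),
            _["wacc"] = wacc);
      }
    }
  }
  if (collect)
    return List::create(_["ri"] = ri, _["trees"] = trees);
  return List::create(_["ri"] = ri, _["trees"] = R_NilValue);
}
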
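// Random forest of CART trees (Gini), bootstrap sampling, random feature
// subsets per node, majority vote per tree. Scores are tree-vote fractions
// so decision thresholds on [0,1] are directly meaningful. All randomness
// goes through R's RNG, so set.seed() makes training bit-reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;    // go left if x[feat] <= thr
  std::vector<int> left, right;
  std::vector<int> pred;      // leaf class (0/1); majority also kept for internal
};

static int new_node(TreeBuf &t) {
  t.feat.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(0);
  return (int)t.feat.size() - 1;
}

// sample `k` distinct values from 0..n-1 via partial Fisher-Yates on `pool`
static void sample_features(std::vector<int> &pool, int k) {
  int n = (int)pool.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
}

static void build_node(TreeBuf &t, int node, const NumericMatrix &X,
                       const IntegerVector &y, std::vector<int> &idx,
                       int lo, int hi, int mtry, int min_node, int depth,
                       std::vector<int> &fpool,
                       std::vector<std::pair<double, int> > &buf) {
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  t.pred[node] = (2 * n1 > n) ? 1 : 0;  // ties -> negative class
  if (n1 == 0 || n1 == n || n < 2 * min_node || depth > 64) return;

  sample_features(fpool, mtry);
  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  double parent = (double)n1 / n;
  double gini_parent = 2.0 * parent * (1.0 - parent);
  for (int fi = 0; fi < mtry; ++fi) {
    int f = fpool[fi];
    buf.clear();
    for (int i = lo; i < hi; ++i)
      buf.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
    std::sort(buf.begin(), buf.end());
    int lcnt = 0, l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      lcnt++;
      l1 += buf[i].second;
      if (buf[i].first == buf[i + 1].first) continue;
      if (lcnt < min_node || n - lcnt < min_node) continue;
      double pl = (double)l1 / lcnt;
      double pr = (double)(n1 - l1) / (n - lcnt);
      double g = gini_parent -
                 ((double)lcnt / n) * 2.0 * pl * (1.0 - pl) -
                 ((double)(n - lcnt) / n) * 2.0 * pr * (1.0 - pr);
      if (g > best_gain + 1e-12) {
        best_gain = g;
        best_f = f;
        best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;  // no useful split among sampled features -> leaf

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[mid++], idx[i]);
  if (mid == lo || mid == hi) return;

  t.feat[node] = best_f;
  t.thr[node] = best_thr;
  int l = new_node(t), r = new_node(t);
  t.left[node] = l;
  t.right[node] = r;
  build_node(t, l, X, y, idx, lo, mid, mtry, min_node, depth + 1, fpool, buf);
  build_node(t, r, X, y, idx, mid, hi, mtry, min_node, depth + 1, fpool, buf);
}

// [[Rcpp::export(name = ".rf_build")]]
List rf_build(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
              int min_node) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  List forest(n_trees);
  std::vector<int> fpool(p), idx(n);
  std::vector<std::pair<double, int> > buf;
  for (int f = 0; f < p; ++f) fpool[f] = f;
  for (int tr = 0; tr < n_trees; ++tr) {
    for (int i = 0; i < n; ++i) {
      int j = (int)std::floor(unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;  // bootstrap sample with replacement
    }
    TreeBuf t;
    int root = new_node(t);
    build_node(t, root, X, y, idx, 0, n, mtry, min_node, 0, fpool, buf);
    forest[tr] = List::create(_["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
                              _["left"] = wrap(t.left),
                              _["right"] = wrap(t.right),
                              _["pred"] = wrap(t.pred));
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_votes")]]
NumericVector rf_votes(List forest, NumericMatrix X) {
  int n = X.nrow(), m = forest.size();
  NumericVector out(n);
  for (int tr = 0; tr < m; ++tr) {
    List t = forest[tr];
    IntegerVector feat = t["feat"], left = t["left"], right = t["right"],
                  pred = t["pred"];
    NumericVector thr = t["thr"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += pred[node];
    }
  }
  if (m > 0) out = out / (double)m;
  return out;
}
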
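// Bagged variance-reduction regression trees with per-split feature
// subsampling. All randomness comes from R's RNG (unif_rand), so forests
// are bit-for-bit reproducible from set.seed() in R.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var, left, right;
  std::vector<double> split, pred;
};

int grow(const NumericMatrix& X, const NumericVector& y,
         std::vector<int>& samp, int lo, int hi, int mtry, int nodesize,
         Tree& t) {
  const int node = (int)t.var.size();
  t.var.push_back(-1);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.split.push_back(0.0);
  t.pred.push_back(0.0);
  const int n = hi - lo;
  double sum = 0.0;
  for (int i = lo; i < hi; ++i) sum += y[samp[i]];
  t.pred[node] = sum / n;
  if (n <= nodesize) return node;
  bool pure = true;
  for (int i = lo + 1; i < hi; ++i)
    if (y[samp[i]] != y[samp[lo]]) { pure = false; break; }
  if (pure) return node;

  const int p = X.ncol();
  const int m = std::min(mtry, p);
  // partial Fisher-Yates draw of m candidate features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double best_gain = -1.0, best_split = 0.0;
  int best_var = -1;
  std::vector<std::pair<double, double> > vals(n);
  for (int jj = 0; jj < m; ++jj) {
    const int v = feats[jj];
    for (int i = 0; i < n; ++i) {
      const int s = samp[lo + i];
      vals[i] = std::make_pair(X(s, v), y[s]);
    }
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;
    double sl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      const double sr = sum - sl;
      const double gain = sl * sl / nl + sr * sr / nr;
      if (gain > best_gain) {
        best_gain = gain;
        best_var = v;
        best_split = (vals[i].first + vals[i + 1].first) / 2.0;
      }
    }
  }
  if (best_var < 0) return node;  // all sampled features constant here

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(samp[i], best_var) <= best_split) std::swap(samp[i], samp[mid++]);
  if (mid == lo || mid == hi) return node;  // numeric guard
  t.var[node] = best_var;
  t.split[node] = best_split;
  t.left[node] = grow(X, y, samp, lo, mid, mtry, nodesize, t);
  t.right[node] = grow(X, y, samp, mid, hi, mtry, nodesize, t);
  return node;
}

NumericMatrix pack(const Tree& t) {
  const int k = (int)t.var.size();
  NumericMatrix m(k, 5);
  for (int i = 0; i < k; ++i) {
    m(i, 0) = t.var[i];
    m(i, 1) = t.split[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.pred[i];
  }
  colnames(m) = CharacterVector::create("var", "split", "left", "right",
                                        "pred");
  return m;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int nodesize) {
  const int n = X.nrow();
  if (n < 2) stop("need at least 2 training rows");
  if (y.size() != n) stop("X and y are not aligned");
  List forest(ntree);
  std::vector<int> samp(n);
  for (int b = 0; b < ntree; ++b) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      samp[i] = (k >= n) ? n - 1 : k;
    }
    Tree t;
    grow(X, y, samp, 0, n, mtry, nodesize, t);
    forest[b] = pack(t);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), B = forest.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix t = forest[b];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (t(node, 0) >= 0)
        node = (X(i, (int)t(node, 0)) <= t(node, 1)) ? (int)t(node, 2)
                                                     : (int)t(node, 3);
      out[i] += t(node, 4);
    }
  }
  return out / B;
}
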
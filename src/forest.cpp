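#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// CART random forest specialised for sparse binary 0/1 feature matrices.
// Bootstrap per tree, per-node mtry feature subsampling, Gini impurity,
// out-of-bag accuracy, mean-decrease-in-impurity importances.
// Splits are always "x == 0 vs x == 1", so no threshold search is needed;
// split statistics are gathered by scanning each candidate feature's
// nonzero-row list (columns are typically a few percent dense), falling
// back to a dense scan of the node when that is smaller.
// Uses R's RNG (determinism via set.seed()).

namespace {

struct Tree {
  std::vector<int> feat;     // -1 for leaf
  std::vector<int> left, right;
  std::vector<double> prob;  // P(y = 1)
};

inline double gini(double n1, double n) {
  if (n <= 0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

struct Task { int lo, hi, depth, node; };

}  // namespace

// [[Rcpp::export]]
List grow_forest_cpp(const IntegerMatrix& X, const IntegerVector& y,
                     int ntree, int mtry, int min_node, int max_depth,
                     bool keep_oob) {
  const int n = X.nrow(), d = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > d) mtry = d;

  // sparse column structure: rows where x == 1, per feature
  std::vector<std::vector<int> > col_rows(d);
  for (int f = 0; f < d; ++f) {
    const int* xp = &X(0, f);
    for (int i = 0; i < n; ++i)
      if (xp[i] != 0) col_rows[f].push_back(i);
  }

  std::vector<double> importance(d, 0.0);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  List trees(ntree);

  std::vector<int> idx(n), in_bag(n), featbuf(d);
  std::vector<int> mark(n, -1), mult(n, 0);
  int cur_mark = 0;

  for (int t = 0; t < ntree; ++t) {
    std::fill(in_bag.begin(), in_bag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
      in_bag[k] = 1;
    }

    Tree tr;
    std::vector<Task> stack;
    tr.feat.push_back(-1); tr.left.push_back(-1); tr.right.push_back(-1);
    tr.prob.push_back(0.0);
    stack.push_back({0, n, 0, 0});

    while (!stack.empty()) {
      Task tk = stack.back(); stack.pop_back();
      const int m = tk.hi - tk.lo;

      // mark node rows with multiplicities; accumulate label count
      ++cur_mark;
      double n1 = 0;
      for (int i = tk.lo; i < tk.hi; ++i) {
        const int r = idx[i];
        if (mark[r] != cur_mark) { mark[r] = cur_mark; mult[r] = 0; }
        ++mult[r];
        n1 += y[r];
      }
      const double node_prob = m > 0 ? n1 / m : 0.0;
      tr.prob[tk.node] = node_prob;

      const double g_parent = gini(n1, m);
      if (m < min_node || tk.depth >= max_depth || n1 == 0 || n1 == m) continue;

      for (int f = 0; f < d; ++f) featbuf[f] = f;
      int best_f = -1;
      double best_dec = 0.0;
      for (int s = 0; s < mtry; ++s) {
        int rpos = s + (int)(unif_rand() * (d - s));
        if (rpos >= d) rpos = d - 1;
        std::swap(featbuf[s], featbuf[rpos]);
        const int f = featbuf[s];
        double n_one = 0, n1_one = 0;
        const std::vector<int>& rows = col_rows[f];
        if ((int)rows.size() < m) {
          for (size_t k = 0; k < rows.size(); ++k) {
            const int r = rows[k];
            if (mark[r] == cur_mark) {
              n_one += mult[r];
              n1_one += (double)mult[r] * y[r];
            }
          }
        } else {
          for (int i = tk.lo; i < tk.hi; ++i) {
            const int r = idx[i];
            if (X(r, f) != 0) { n_one += 1; n1_one += y[r]; }
          }
        }
        const double nl = m - n_one, nr = n_one;
        if (nl == 0 || nr == 0) continue;
        const double n1l = n1 - n1_one;
        const double dec = g_parent -
          (nl * gini(n1l, nl) + nr * gini(n1_one, nr)) / m;
        if (dec > best_dec + 1e-15) { best_dec = dec; best_f = f; }
      }
      if (best_f < 0 || best_dec <= 0) continue;

      // in-place partition: x == 0 first
      int i = tk.lo, j = tk.hi - 1;
      while (i <= j) {
        if (X(idx[i], best_f) == 0) { ++i; }
        else { std::swap(idx[i], idx[j]); --j; }
      }
      const int li = (int)tr.feat.size();
      tr.feat.push_back(-1); tr.left.push_back(-1); tr.right.push_back(-1); tr.prob.push_back(0.0);
      const int ri = (int)tr.feat.size();
      tr.feat.push_back(-1); tr.left.push_back(-1); tr.right.push_back(-1); tr.prob.push_back(0.0);
      tr.feat[tk.node] = best_f;
      tr.left[tk.node] = li;
      tr.right[tk.node] = ri;
      importance[best_f] += ((double)m / n) * best_dec;
      stack.push_back({tk.lo, i, tk.depth + 1, li});
      stack.push_back({i, tk.hi, tk.depth + 1, ri});
    }

    if (keep_oob) {
      for (int i = 0; i < n; ++i) {
        if (in_bag[i]) continue;
        int node = 0;
        while (tr.feat[node] >= 0)
          node = X(i, tr.feat[node]) == 0 ? tr.left[node] : tr.right[node];
        oob_sum[i] += tr.prob[node];
        oob_cnt[i] += 1;
      }
    }

    trees[t] = List::create(_["feat"] = IntegerVector(tr.feat.begin(), tr.feat.end()),
                            _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
                            _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
                            _["prob"] = NumericVector(tr.prob.begin(), tr.prob.end()));
  }

  double imp_total = 0;
  for (int f = 0; f < d; ++f) imp_total += importance[f];
  NumericVector imp(d);
  for (int f = 0; f < d; ++f)
    imp[f] = imp_total > 0 ? importance[f] / imp_total : 0.0;

  double correct = 0, seen = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] == 0) continue;
    seen += 1;
    const int pred = oob_sum[i] / oob_cnt[i] > 0.5 ? 1 : 0;
    if (pred == y[i]) correct += 1;
  }

  return List::create(_["trees"] = trees,
                      _["importance"] = imp,
                      _["oob_score"] = seen > 0 ? correct / seen : NA_REAL);
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(const List& trees, const IntegerMatrix& X) {
  const int n = X.nrow();
  const int ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
    NumericVector prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = X(i, feat[node]) == 0 ? left[node] : right[node];
      out[i] += prob[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
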
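// Small random-forest classifier for binary labels: bootstrap of n rows per
// tree, `mtry` candidate features per node, unpruned CART with Gini splits,
// majority vote across trees. This is deliberately the classic forest
// configuration (10 trees, mtry = floor(log2 M) + 1 by the caller) rather
// than a tuned learner; determinism for a fixed seed is part of the contract.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNodes {
  // feat[i] == -1 marks a leaf; pred then holds the majority class (0/1).
  std::vector<int> feat;
  std::vector<double> thr;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<int> pred;

  int add_node() {
    feat.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0);
    return static_cast<int>(feat.size()) - 1;
  }
};

double gini(int n_pos, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(n_pos) / n;
  return 2.0 * p * (1.0 - p);
}

struct SplitResult {
  int feat = -1;
  double thr = 0.0;
  double score = std::numeric_limits<double>::infinity();  // weighted child impurity
};

// Work item for the explicit growth stack (trees are fully grown; recursion
// depth can reach the sample count, so no C-stack recursion).
struct WorkItem {
  int node;
  int begin;
  int end;  // half-open range into idx
};

void grow_tree(const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int mtry, std::mt19937& rng,
               TreeNodes& tree) {
  const int M = X.ncol();
  std::vector<int> feat_pool(M);
  for (int j = 0; j < M; ++j) feat_pool[j] = j;

  std::vector<WorkItem> stack;
  int root = tree.add_node();
  stack.push_back({root, 0, static_cast<int>(idx.size())});

  std::vector<std::pair<double, int>> vals;  // (feature value, label)

  while (!stack.empty()) {
    WorkItem w = stack.back();
    stack.pop_back();
    int n = w.end - w.begin;
    int n_pos = 0;
    for (int i = w.begin; i < w.end; ++i) n_pos += y[idx[i]];

    if (n_pos == 0 || n_pos == n || n < 2) {
      tree.pred[w.node] = (2 * n_pos > n) ? 1 : 0;
      continue;
    }

    // Sample mtry distinct candidate features (partial Fisher-Yates). The
    // pool is re-sorted each node so draws depend only on the RNG stream.
    int m = std::min(mtry, M);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> pick(j, M - 1);
      std::swap(feat_pool[j], feat_pool[pick(rng)]);
    }
    // Deterministic tie-breaking: evaluate candidates in ascending index.
    std::sort(feat_pool.begin(), feat_pool.begin() + m);

    double parent_imp = gini(n_pos, n);
    SplitResult best;
    for (int j = 0; j < m; ++j) {
      int f = feat_pool[j];
      vals.clear();
      for (int i = w.begin; i < w.end; ++i)
        vals.emplace_back(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant
      int left_pos = 0;
      for (int i = 1; i < n; ++i) {
        left_pos += vals[i - 1].second;
        if (vals[i].first == vals[i - 1].first) continue;
        double score = (i * gini(left_pos, i) +
                        (n - i) * gini(n_pos - left_pos, n - i)) / n;
        if (score < best.score - 1e-12) {
          best.score = score;
          best.feat = f;
          best.thr = vals[i - 1].first +
                     (vals[i].first - vals[i - 1].first) / 2.0;
        }
      }
    }

    if (best.feat < 0 || best.score >= parent_imp - 1e-12) {
      // No candidate feature yields an impurity decrease: stop here.
      tree.pred[w.node] = (2 * n_pos > n) ? 1 : 0;
      continue;
    }

    // In-place partition of idx[begin, end) by the chosen split.
    int mid = w.begin;
    for (int i = w.begin; i < w.end; ++i)
      if (X(idx[i], best.feat) <= best.thr) std::swap(idx[i], idx[mid++]);
    if (mid == w.begin || mid == w.end) {
      // Midpoint thresholds make this unreachable for finite input; guard
      // against degenerate floating-point anyway.
      tree.pred[w.node] = (2 * n_pos > n) ? 1 : 0;
      continue;
    }

    tree.feat[w.node] = best.feat;
    tree.thr[w.node] = best.thr;
    int l = tree.add_node();
    int r = tree.add_node();
    tree.left[w.node] = l;
    tree.right[w.node] = r;
    stack.push_back({r, mid, w.end});
    stack.push_back({l, w.begin, mid});
  }
}

int predict_one(const TreeNodes& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feat[node] >= 0)
    node = (X(row, tree.feat[node]) <= tree.thr[node]) ? tree.left[node]
                                                       : tree.right[node];
  return tree.pred[node];
}

int predict_one_list(const IntegerVector& feat, const NumericVector& thr,
                     const IntegerVector& left, const IntegerVector& right,
                     const IntegerVector& pred, const NumericMatrix& X,
                     int row) {
  int node = 0;
  while (feat[node] >= 0)
    node = (X(row, feat[node]) <= thr[node]) ? left[node] : right[node];
  return pred[node];
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y must have the same number of rows");
  if (n < 1) stop("cannot fit a forest on zero rows");
  for (int i = 0; i < n; ++i)
    if (y[i] != 0 && y[i] != 1) stop("labels must be 0/1");

  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::uniform_int_distribution<int> row_pick(0, n - 1);

  List trees(n_trees);
  // Out-of-bag vote bookkeeping (computed, reported, never used to select).
  std::vector<int> oob_pos(n, 0), oob_tot(n, 0);
  std::vector<char> in_bag(n);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    std::fill(in_bag.begin(), in_bag.end(), 0);
    for (int i = 0; i < n; ++i) {
      idx[i] = row_pick(rng);
      in_bag[idx[i]] = 1;
    }
    TreeNodes tree;
    grow_tree(X, y, idx, mtry, rng, tree);
    for (int i = 0; i < n; ++i) {
      if (!in_bag[i]) {
        oob_tot[i] += 1;
        oob_pos[i] += predict_one(tree, X, i);
      }
    }
    trees[t] = List::create(_["feat"] = wrap(tree.feat),
                            _["thr"] = wrap(tree.thr),
                            _["left"] = wrap(tree.left),
                            _["right"] = wrap(tree.right),
                            _["pred"] = wrap(tree.pred));
  }

  int oob_err = 0, oob_n = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_tot[i] > 0) {
      ++oob_n;
      int vote = (2 * oob_pos[i] > oob_tot[i]) ? 1 : 0;
      if (vote != y[i]) ++oob_err;
    }
  }
  double oob = oob_n > 0 ? static_cast<double>(oob_err) / oob_n : NA_REAL;

  return List::create(_["trees"] = trees, _["n_trees"] = n_trees,
                      _["mtry"] = mtry, _["seed"] = seed,
                      _["oob_error"] = oob);
}

//' @noRd
// [[Rcpp::export(name = ".rf_votes_cpp")]]
NumericVector rf_votes_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int T = trees.size();
  const int n = X.nrow();
  NumericVector frac(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector pred = tr["pred"];
    for (int i = 0; i < n; ++i)
      frac[i] += predict_one_list(feat, thr, left, right, pred, X, i);
  }
  if (T > 0)
    for (int i = 0; i < n; ++i) frac[i] /= T;
  return frac;
}
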
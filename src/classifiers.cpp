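// Binary classifiers used by the leave-one-subject-out pipeline.
//
// Self-contained implementations of a random forest (CART trees, gini
// impurity, bootstrap resampling, random feature subsets, trees grown to
// purity) and a soft-margin RBF-kernel SVM fitted with sequential minimal
// optimisation.  Both take a train/test pair and return test-set scores;
// no model object crosses the R boundary.  All randomness comes from an
// explicit integer seed so cross-validation is reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNode {
  int feat = -1;      // -1 marks a leaf
  double thr = 0.0;
  int left = -1;
  int right = -1;
  int pred = 0;       // majority class at the node
};

// Grow one CART node over `idx`; appends to `nodes` and returns its index.
int grow_node(const NumericMatrix &X, const IntegerVector &y,
              std::vector<int> idx, int mtry, int min_node,
              std::vector<TreeNode> &nodes, std::mt19937 &rng) {
  const int p = X.ncol();
  int n1 = 0;
  for (int i : idx) n1 += y[i];
  const int n = static_cast<int>(idx.size());
  const int n0 = n - n1;

  TreeNode node;
  node.pred = (n1 > n0) ? 1 : 0;  // ties go to class 0

  if (n1 == 0 || n0 == 0 || n < min_node) {
    nodes.push_back(node);
    return static_cast<int>(nodes.size()) - 1;
  }

  // sample mtry candidate features without replacement
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {
    std::uniform_int_distribution<int> pick(j, p - 1);
    std::swap(feats[j], feats[pick(rng)]);
  }

  const double parent_gini =
      1.0 - std::pow(double(n1) / n, 2) - std::pow(double(n0) / n, 2);
  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);
  for (int jj = 0; jj < mtry; ++jj) {
    const int f = feats[jj];
    for (int k = 0; k < n; ++k)
      vals[k] = {X(idx[k], f), y[idx[k]]};
    std::sort(vals.begin(), vals.end());
    int left1 = 0;
    for (int k = 0; k < n - 1; ++k) {
      left1 += vals[k].second;
      if (vals[k + 1].first <= vals[k].first) continue;  // no gap to split in
      const int nl = k + 1, nr = n - nl;
      const int l1 = left1, r1 = n1 - left1;
      const double gl =
          1.0 - std::pow(double(l1) / nl, 2) - std::pow(double(nl - l1) / nl, 2);
      const double gr =
          1.0 - std::pow(double(r1) / nr, 2) - std::pow(double(nr - r1) / nr, 2);
      const double gain =
          parent_gini - (double(nl) / n) * gl - (double(nr) / n) * gr;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }

  if (best_feat < 0) {  // no admissible split
    nodes.push_back(node);
    return static_cast<int>(nodes.size()) - 1;
  }

  std::vector<int> left_idx, right_idx;
  for (int i : idx)
    (X(i, best_feat) <= best_thr ? left_idx : right_idx).push_back(i);

  node.feat = best_feat;
  node.thr = best_thr;
  nodes.push_back(node);
  const int me = static_cast<int>(nodes.size()) - 1;
  idx.clear();
  idx.shrink_to_fit();
  const int li = grow_node(X, y, std::move(left_idx), mtry, min_node, nodes, rng);
  const int ri = grow_node(X, y, std::move(right_idx), mtry, min_node, nodes, rng);
  nodes[me].left = li;
  nodes[me].right = ri;
  return me;
}

int tree_predict(const std::vector<TreeNode> &nodes, const NumericMatrix &X,
                 int row) {
  int cur = 0;
  while (nodes[cur].feat >= 0)
    cur = (X(row, nodes[cur].feat) <= nodes[cur].thr) ? nodes[cur].left
                                                      : nodes[cur].right;
  return nodes[cur].pred;
}

}  // namespace

// Random forest: fit on (Xtr, ytr) and return the class-1 vote fraction for
// every row of Xte.  ytr must be 0/1.  mtry <= 0 selects floor(sqrt(p)).
// [[Rcpp::export(name = ".rf_fit_predict_cpp")]]
NumericVector rf_fit_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                 NumericMatrix Xte, int ntree, int mtry,
                                 int min_node, int seed) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), m = Xte.nrow();
  if (ytr.size() != n) stop("ytr length must match nrow(Xtr)");
  if (mtry <= 0) mtry = std::max(1, static_cast<int>(std::sqrt(double(p))));
  if (mtry > p) mtry = p;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_int_distribution<int> boot(0, n - 1);
  NumericVector votes(m);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    std::vector<TreeNode> nodes;
    nodes.reserve(2 * n);
    grow_node(Xtr, ytr, std::move(idx), mtry, min_node, nodes, rng);
    for (int r = 0; r < m; ++r) votes[r] += tree_predict(nodes, Xte, r);
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  for (int r = 0; r < m; ++r) votes[r] /= ntree;
  return votes;
}

namespace {

inline double rbf(const NumericMatrix &A, int i, const NumericMatrix &B, int j,
                  double gamma) {
  double s = 0.0;
  for (int k = 0; k < A.ncol(); ++k) {
    const double d = A(i, k) - B(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

}  // namespace

// Soft-margin SVM with RBF kernel, trained by simplified SMO.  ytr is 0/1;
// returns the decision value f(x) for each test row (classify by sign).
// [[Rcpp::export(name = ".svm_fit_predict_cpp")]]
NumericVector svm_fit_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                  NumericMatrix Xte, double C, double gamma,
                                  double tol, int max_passes, int seed) {
  const int n = Xtr.nrow(), m = Xte.nrow();
  if (ytr.size() != n) stop("ytr length must match nrow(Xtr)");

  std::vector<double> y(n);
  for (int i = 0; i < n; ++i) y[i] = ytr[i] == 1 ? 1.0 : -1.0;

  // kernel matrix; n stays small (hundreds) in this package's use
  std::vector<double> K(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[i * n + j] = K[j * n + i] = rbf(Xtr, i, Xtr, j, gamma);

  std::vector<double> alpha(n, 0.0);
  double b = 0.0;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_int_distribution<int> pick(0, n - 2);

  auto fval = [&](int i) {
    double s = b;
    for (int k = 0; k < n; ++k)
      if (alpha[k] > 0.0) s += alpha[k] * y[k] * K[k * n + i];
    return s;
  };

  int passes = 0, guard = 0;
  const int guard_max = 200 * std::max(n, max_passes);
  while (passes < max_passes && guard++ < guard_max) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      const double Ei = fval(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = pick(rng);
        if (j >= i) ++j;
        const double Ej = fval(j) - y[j];
        const double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj_old - ai_old);
          H = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          H = std::min(C, ai_old + aj_old);
        }
        if (L >= H) continue;
        const double eta = 2.0 * K[i * n + j] - K[i * n + i] - K[j * n + j];
        if (eta >= 0) continue;
        double aj = aj_old - y[j] * (Ei - Ej) / eta;
        aj = std::min(H, std::max(L, aj));
        if (std::fabs(aj - aj_old) < 1e-6) continue;
        const double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        const double b1 = b - Ei - y[i] * (ai - ai_old) * K[i * n + i] -
                          y[j] * (aj - aj_old) * K[i * n + j];
        const double b2 = b - Ej - y[i] * (ai - ai_old) * K[i * n + j] -
                          y[j] * (aj - aj_old) * K[j * n + j];
        alpha[i] = ai;
        alpha[j] = aj;
        if (ai > 0 && ai < C)
          b = b1;
        else if (aj > 0 && aj < C)
          b = b2;
        else
          b = 0.5 * (b1 + b2);
        ++changed;
      }
    }
    passes = (changed == 0) ? passes + 1 : 0;
    Rcpp::checkUserInterrupt();
  }

  NumericVector out(m);
  for (int r = 0; r < m; ++r) {
    double s = b;
    for (int k = 0; k < n; ++k)
      if (alpha[k] > 0.0) s += alpha[k] * y[k] * rbf(Xtr, k, Xte, r, gamma);
    out[r] = s;
  }
  return out;
}
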
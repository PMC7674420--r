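#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Bagged CART forest for binary classification, matching the fixed
// hyper-parameter conventions of the classifier the analysis standardises on:
// Gini impurity, all features eligible at every split, bootstrap sampling,
// split accepted only when the weighted impurity decrease
//   N_t/N * (imp - N_l/N_t * imp_l - N_r/N_t * imp_r)
// reaches min_impurity_decrease, leaf probabilities = class fractions in the
// leaf, and MDI importances that sum to 1 per tree.
//
// Each tree presorts its bootstrap sample once per feature and keeps every
// feature's order array partitioned alongside the node ranges, so no sorting
// happens below the root. A self-contained xorshift RNG keeps fits
// bit-reproducible for a given seed across platforms and independent of R's
// RNG state.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;
  double p1;        // class-1 fraction (leaves)
};

struct Tree {
  std::vector<Node> nodes;
};

inline double gini(int n0, int n1) {
  const double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  const double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct StackItem {
  int node;
  int lo, hi;  // slot range, shared by all feature order arrays
};

// idx: bootstrap sample slots (values = training-row indices, with repeats).
// orders[j]: the slots sorted by feature j, partitioned in step with nodes.
void build_tree(const NumericMatrix& X, const IntegerVector& y,
                const std::vector<int>& idx, int n_total,
                double min_decrease, Tree& tree,
                std::vector<double>& imp_accum) {
  const int p = X.ncol();
  const int n = static_cast<int>(idx.size());

  std::vector<std::vector<int>> orders(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    const double* col = &X(0, j);
    std::vector<int>& ord = orders[j];
    for (int k = 0; k < n; ++k) ord[k] = idx[k];
    std::sort(ord.begin(), ord.end(),
              [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<char> goes_left(X.nrow(), 0);
  std::vector<int> buf(n);
  std::vector<StackItem> stack;
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  stack.push_back(StackItem{0, 0, n});

  while (!stack.empty()) {
    StackItem it = stack.back();
    stack.pop_back();
    const int lo = it.lo, hi = it.hi, nt = hi - lo;

    int n1 = 0;
    for (int k = lo; k < hi; ++k) n1 += y[orders[0][k]];
    const int n0 = nt - n1;
    tree.nodes[it.node].p1 = nt > 0 ? static_cast<double>(n1) / nt : 0.0;

    if (nt < 2 || n0 == 0 || n1 == 0) continue;  // pure or too small: leaf

    const double node_imp = gini(n0, n1);
    const double w_node = static_cast<double>(nt) / n_total;
    double best_dec = -1.0, best_thr = 0.0;
    int best_feat = -1;

    for (int j = 0; j < p; ++j) {
      const double* col = &X(0, j);
      const std::vector<int>& ord = orders[j];
      int l0 = 0, l1 = 0;
      for (int k = lo; k < hi - 1; ++k) {
        const int i = ord[k];
        l0 += 1 - y[i];
        l1 += y[i];
        const double v = col[i], vnext = col[ord[k + 1]];
        if (vnext <= v) continue;  // no threshold between equal values
        const int nl = k + 1 - lo, nr = nt - nl;
        const double dec =
            w_node * (node_imp -
                      (static_cast<double>(nl) / nt) * gini(l0, l1) -
                      (static_cast<double>(nr) / nt) * gini(n0 - l0, n1 - l1));
        if (dec > best_dec + 1e-15) {
          best_dec = dec;
          best_feat = j;
          best_thr = v + (vnext - v) / 2.0;
        }
      }
    }

    if (best_feat < 0 || best_dec < min_decrease) continue;  // leaf

    imp_accum[best_feat] += best_dec;

    // partition every feature's order segment, preserving sorted order
    const double* scol = &X(0, best_feat);
    int nl = 0;
    for (int k = lo; k < hi; ++k) {
      const int i = orders[best_feat][k];
      const char gl = scol[i] <= best_thr ? 1 : 0;
      goes_left[i] = gl;  // rows repeat in bootstrap but share the same side
      nl += gl;
    }
    for (int j = 0; j < p; ++j) {
      std::vector<int>& ord = orders[j];
      int wl = 0, wr = nl;
      for (int k = lo; k < hi; ++k) {
        const int i = ord[k];
        buf[(goes_left[i] ? wl++ : wr++)] = i;
      }
      std::copy(buf.begin(), buf.begin() + nt, ord.begin() + lo);
    }

    const int left = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    Node& nd = tree.nodes[it.node];
    nd.feature = best_feat;
    nd.threshold = best_thr;
    nd.left = left;
    nd.right = left + 1;
    stack.push_back(StackItem{left, lo, lo + nl});
    stack.push_back(StackItem{left + 1, lo + nl, hi});
  }
}

inline double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0) {
    const Node& nd = tree.nodes[cur];
    cur = X(row, nd.feature) <= nd.threshold ? nd.left : nd.right;
  }
  return tree.nodes[cur].p1;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".rf_fit_predict")]]
List rf_fit_predict_cpp(NumericMatrix Xtr, IntegerVector ytr, NumericMatrix Xte,
                        int n_trees, double min_impurity_decrease, int seed,
                        bool bootstrap) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), m = Xte.nrow();
  if (n < 1) stop("empty training set");
  if (ytr.size() != n) stop("label length does not match training rows");

  XorShift rng(static_cast<uint64_t>(seed) * 0x2545F4914F6CDD1DULL + 1ULL);

  NumericVector prob(m, 0.0);
  NumericVector importance(p, 0.0);
  std::vector<double> tree_imp(p);
  std::vector<int> idx(n);

  for (int t = 0; t < n_trees; ++t) {
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = rng.below(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Tree tree;
    std::fill(tree_imp.begin(), tree_imp.end(), 0.0);
    build_tree(Xtr, ytr, idx, n, min_impurity_decrease, tree, tree_imp);

    double tot = 0.0;
    for (int j = 0; j < p; ++j) tot += tree_imp[j];
    if (tot > 0.0)
      for (int j = 0; j < p; ++j) importance[j] += tree_imp[j] / tot;

    for (int r = 0; r < m; ++r) prob[r] += predict_tree(tree, Xte, r);
  }

  for (int r = 0; r < m; ++r) prob[r] /= n_trees;
  double tot = 0.0;
  for (int j = 0; j < p; ++j) tot += importance[j];
  if (tot > 0.0)
    for (int j = 0; j < p; ++j) importance[j] /= tot;

  return List::create(_["prob"] = prob, _["importance"] = importance);
}
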
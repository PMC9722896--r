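#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Deterministic splitmix64 stream: forest results must be identical across
// platforms and independent of R's RNG state.
struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) { next(); next(); }
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n); n is tiny here so modulo bias is negligible
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feat;      // -1 for a leaf
  double thr;    // go left if x < thr
  int left, right;
  double prob;   // leaf class-1 probability
};

static inline double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(n1) / n;
  return 2.0 * p * (1.0 - p);
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int p, mtry, min_leaf, n_total;
  SplitMix& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance;    // accumulated across trees
  std::vector<int> feat_pool;
  std::vector<std::pair<double,int>> buf;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_leaf_, int n_total_, SplitMix& rng_, std::vector<double>& imp_)
    : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), min_leaf(min_leaf_),
      n_total(n_total_), rng(rng_), importance(imp_), feat_pool(p) {
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx) {
    int n = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    double g_parent = gini(n1, n);

    Node node;
    node.feat = -1; node.thr = 0.0; node.left = -1; node.right = -1;
    node.prob = n > 0 ? static_cast<double>(n1) / n : 0.0;

    if (n1 == 0 || n1 == n || n < 2 * min_leaf) {
      nodes.push_back(node);
      return static_cast<int>(nodes.size()) - 1;
    }

    // draw mtry distinct candidate features (partial Fisher-Yates)
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + rng.unif_int(p - j);
      std::swap(feat_pool[j], feat_pool[k]);
    }

    double best_impr = 1e-12;
    int best_feat = -1, best_cut = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double,int>> best_sorted;

    for (int j = 0; j < m; ++j) {
      int f = feat_pool[j];
      buf.clear();
      buf.reserve(n);
      for (int i : idx) buf.push_back(std::make_pair(X(i, f), i));
      std::sort(buf.begin(), buf.end());
      if (buf.front().first >= buf.back().first) continue;  // constant in node

      int left1 = 0;
      for (int k = 1; k < n; ++k) {
        left1 += y[buf[k - 1].second];
        if (buf[k - 1].first >= buf[k].first) continue;     // tied values
        if (k < min_leaf || n - k < min_leaf) continue;
        double g = g_parent
          - (static_cast<double>(k) / n) * gini(left1, k)
          - (static_cast<double>(n - k) / n) * gini(n1 - left1, n - k);
        if (g > best_impr) {
          best_impr = g;
          best_feat = f;
          best_cut = k;
          best_thr = 0.5 * (buf[k - 1].first + buf[k].first);
          best_sorted = buf;
        }
      }
    }

    if (best_feat < 0) {
      nodes.push_back(node);
      return static_cast<int>(nodes.size()) - 1;
    }

    importance[best_feat] += (static_cast<double>(n) / n_total) * best_impr;

    std::vector<int> left_idx, right_idx;
    left_idx.reserve(best_cut);
    right_idx.reserve(n - best_cut);
    for (int k = 0; k < best_cut; ++k) left_idx.push_back(best_sorted[k].second);
    for (int k = best_cut; k < n; ++k) right_idx.push_back(best_sorted[k].second);

    node.feat = best_feat;
    node.thr = best_thr;
    nodes.push_back(node);
    int self = static_cast<int>(nodes.size()) - 1;
    int l = build(left_idx);
    int r = build(right_idx);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  double predict_row(const NumericMatrix& M, int row) const {
    int cur = 0;
    while (nodes[cur].feat >= 0)
      cur = (M(row, nodes[cur].feat) < nodes[cur].thr) ? nodes[cur].left : nodes[cur].right;
    return nodes[cur].prob;
  }
};

//' @noRd
// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix Xtr, IntegerVector ytr, NumericMatrix Xte,
                int ntree, int mtry, int min_leaf, double seed, bool keep_inbag) {
  int n = Xtr.nrow(), p = Xtr.ncol(), nte = Xte.nrow();
  SplitMix rng(static_cast<uint64_t>(seed));

  std::vector<double> imp(p, 0.0);
  std::vector<double> test_sum(nte, 0.0);
  std::vector<double> resub_sum(n, 0.0);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_n(n, 0);

  IntegerMatrix inbag_mat;
  NumericMatrix tree_train_pred;
  if (keep_inbag) {
    inbag_mat = IntegerMatrix(ntree, n);
    tree_train_pred = NumericMatrix(ntree, n);
  }

  std::vector<int> inbag(n);
  std::vector<int> idx(n);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int k = rng.unif_int(n);
      idx[i] = k;
      inbag[k]++;
    }

    TreeBuilder tb(Xtr, ytr, mtry, min_leaf, n, rng, imp);
    std::vector<int> root_idx(idx);
    tb.build(root_idx);

    for (int i = 0; i < nte; ++i) test_sum[i] += tb.predict_row(Xte, i);
    for (int i = 0; i < n; ++i) {
      double pr = tb.predict_row(Xtr, i);
      resub_sum[i] += pr;
      if (inbag[i] == 0) { oob_sum[i] += pr; oob_n[i]++; }
      if (keep_inbag) {
        inbag_mat(t, i) = inbag[i];
        tree_train_pred(t, i) = pr;
      }
    }
  }

  NumericVector test_prob(nte), resub_prob(n), oob_prob(n), importance(p);
  IntegerVector oob_count(n);
  for (int i = 0; i < nte; ++i) test_prob[i] = test_sum[i] / ntree;
  for (int i = 0; i < n; ++i) {
    resub_prob[i] = resub_sum[i] / ntree;
    oob_count[i] = oob_n[i];
    oob_prob[i] = oob_n[i] > 0 ? oob_sum[i] / oob_n[i] : NA_REAL;
  }
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / ntree;

  List out = List::create(
    _["test_prob"] = test_prob,
    _["oob_prob"] = oob_prob,
    _["resub_prob"] = resub_prob,
    _["importance"] = importance,
    _["oob_count"] = oob_count);
  if (keep_inbag) {
    out["inbag"] = inbag_mat;
    out["tree_train_pred"] = tree_train_pred;
  }
  return out;
}
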
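// Classification random forest: bagging + per-node random feature subsets,
// Gini splits, majority vote, out-of-bag error. Self-contained because the
// deployment image ships no R forest package. Single-threaded, deterministic
// for a given seed (own mt19937, independent of R's RNG state).
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node ids
  int pred;         // class id at leaf (0-based)
};

struct Tree {
  std::vector<Node> nodes;
};

// majority class; ties broken by lowest class id
int majority(const std::vector<int>& counts) {
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k)
    if (counts[k] > counts[best]) best = (int)k;
  return best;
}

double gini_impurity(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : counts) { double p = (double)c / n; s += p * p; }
  return 1.0 - s;
}

class Grower {
public:
  Grower(const NumericMatrix& X, const IntegerVector& y, int nclass,
         int mtry, int min_node, std::mt19937& rng, std::vector<double>& gini)
    : X_(X), y_(y), nclass_(nclass), mtry_(mtry), min_node_(min_node),
      rng_(rng), gini_(gini), p_((int)X.ncol()) {}

  Tree grow(std::vector<int>& idx) {
    Tree t;
    build(t, idx, 0, (int)idx.size());
    return t;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int nclass_, mtry_, min_node_;
  std::mt19937& rng_;
  std::vector<double>& gini_;
  int p_;
  std::vector<int> feat_pool_;

  // builds node over idx[lo:hi), returns node id
  int build(Tree& t, std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    std::vector<int> counts(nclass_, 0);
    for (int i = lo; i < hi; ++i) counts[y_[idx[i]]]++;

    int me = (int)t.nodes.size();
    t.nodes.push_back(Node{-1, 0.0, -1, -1, majority(counts)});

    bool pure = false;
    for (int k = 0; k < nclass_; ++k) if (counts[k] == n) { pure = true; break; }
    if (pure || n < 2 * min_node_ || n < 2) return me;

    // sample mtry features without replacement
    if ((int)feat_pool_.size() != p_) {
      feat_pool_.resize(p_);
      for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
    }
    for (int j = 0; j < mtry_; ++j) {
      std::uniform_int_distribution<int> d(j, p_ - 1);
      std::swap(feat_pool_[j], feat_pool_[d(rng_)]);
    }

    double parent_imp = gini_impurity(counts, n);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double,int>> vals(n);
    std::vector<int> left_counts(nclass_);
    for (int jj = 0; jj < mtry_; ++jj) {
      int f = feat_pool_[jj];
      for (int i = 0; i < n; ++i)
        vals[i] = {X_(idx[lo + i], f), y_[idx[lo + i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue; // constant
      std::fill(left_counts.begin(), left_counts.end(), 0);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        left_counts[vals[i].second]++; nl++;
        if (vals[i].first == vals[i + 1].first) continue;
        if (nl < min_node_ || n - nl < min_node_) continue;
        double imp_l = gini_impurity(left_counts, nl);
        std::vector<int> rc(nclass_);
        for (int k = 0; k < nclass_; ++k) rc[k] = counts[k] - left_counts[k];
        double imp_r = gini_impurity(rc, n - nl);
        double gain = parent_imp -
          ((double)nl / n) * imp_l - ((double)(n - nl) / n) * imp_r;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return me; // no impurity-reducing split among candidates

    // partition idx[lo:hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X_(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return me; // numeric degenerate; keep leaf

    gini_[best_f] += best_gain * n; // total impurity decrease, sample-weighted
    t.nodes[me].feature = best_f;
    t.nodes[me].threshold = best_thr;
    t.nodes[me].left = build(t, idx, lo, mid);
    t.nodes[me].right = build(t, idx, mid, hi);
    return me;
  }
};

int tree_predict(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.nodes[node].feature >= 0) {
    node = (X(row, t.nodes[node].feature) <= t.nodes[node].threshold)
             ? t.nodes[node].left : t.nodes[node].right;
  }
  return t.nodes[node].pred;
}

NumericMatrix tree_to_matrix(const Tree& t) {
  NumericMatrix m((int)t.nodes.size(), 5);
  for (size_t i = 0; i < t.nodes.size(); ++i) {
    m(i, 0) = t.nodes[i].feature;
    m(i, 1) = t.nodes[i].threshold;
    m(i, 2) = t.nodes[i].left;
    m(i, 3) = t.nodes[i].right;
    m(i, 4) = t.nodes[i].pred;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "pred");
  return m;
}

Tree matrix_to_tree(const NumericMatrix& m) {
  Tree t;
  t.nodes.resize(m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    t.nodes[i] = Node{(int)m(i, 0), m(i, 1), (int)m(i, 2), (int)m(i, 3),
                      (int)m(i, 4)};
  return t;
}

std::vector<Tree> unpack_forest(const List& trees) {
  std::vector<Tree> out;
  out.reserve(trees.size());
  for (int b = 0; b < trees.size(); ++b)
    out.push_back(matrix_to_tree(as<NumericMatrix>(trees[b])));
  return out;
}

} // namespace

// [[Rcpp::export(rng = false)]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                  int mtry, int min_node, double seed) {
  int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  IntegerMatrix oob_votes(n, nclass);
  std::mt19937 seeder((uint32_t)seed);
  std::vector<double> gini(X.ncol(), 0.0);

  for (int b = 0; b < ntree; ++b) {
    std::mt19937 rng(seeder());
    std::uniform_int_distribution<int> draw(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = draw(rng);
      idx[i] = j;
      inbag(j, b)++;
    }
    Grower g(X, y, nclass, mtry, min_node, rng, gini);
    Tree t = g.grow(idx);
    for (int i = 0; i < n; ++i)
      if (inbag(i, b) == 0) oob_votes(i, tree_predict(t, X, i))++;
    trees[b] = tree_to_matrix(t);
  }

  // OOB prediction: ties to the lowest class id; rows never OOB -> NA
  IntegerVector oob_pred(n, NA_INTEGER);
  int wrong = 0, used = 0;
  for (int i = 0; i < n; ++i) {
    int tot = 0, best = 0;
    for (int k = 0; k < nclass; ++k) {
      tot += oob_votes(i, k);
      if (oob_votes(i, k) > oob_votes(i, best)) best = k;
    }
    if (tot > 0) {
      oob_pred[i] = best;
      ++used;
      if (best != y[i]) ++wrong;
    }
  }
  double oob_error = used > 0 ? (double)wrong / used : NA_REAL;
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["oob_votes"] = oob_votes, _["oob_pred"] = oob_pred,
                      _["oob_error"] = oob_error,
                      _["gini_importance"] = NumericVector(gini.begin(),
                                                           gini.end()));
}

// [[Rcpp::export(rng = false)]]
IntegerMatrix rf_votes_cpp(List trees, NumericMatrix X, int nclass) {
  std::vector<Tree> forest = unpack_forest(trees);
  int n = X.nrow();
  IntegerMatrix votes(n, nclass);
  for (size_t b = 0; b < forest.size(); ++b)
    for (int i = 0; i < n; ++i)
      votes(i, tree_predict(forest[b], X, i))++;
  return votes;
}

// Votes restricted, per row, to trees in whose bootstrap the row did not
// appear. X must be row-aligned with the training data (possibly with a
// column permuted); used for OOB-based permutation importance.
// [[Rcpp::export(rng = false)]]
IntegerMatrix rf_oob_votes_cpp(List trees, IntegerMatrix inbag,
                               NumericMatrix X, int nclass) {
  std::vector<Tree> forest = unpack_forest(trees);
  int n = X.nrow();
  IntegerMatrix votes(n, nclass);
  for (size_t b = 0; b < forest.size(); ++b)
    for (int i = 0; i < n; ++i)
      if (inbag(i, (int)b) == 0) votes(i, tree_predict(forest[b], X, i))++;
  return votes;
}

// Mean decrease in OOB accuracy per feature, averaged over `repeats`
// independent column permutations.
// [[Rcpp::export(rng = false)]]
NumericMatrix rf_perm_importance_cpp(List trees, IntegerMatrix inbag,
                                     NumericMatrix X, IntegerVector y,
                                     int nclass, int repeats, double seed) {
  std::vector<Tree> forest = unpack_forest(trees);
  int n = X.nrow(), p = X.ncol(), ntree = (int)forest.size();

  // cache OOB tree lists per row
  std::vector<std::vector<int>> oob_trees(n);
  for (int i = 0; i < n; ++i)
    for (int b = 0; b < ntree; ++b)
      if (inbag(i, b) == 0) oob_trees[i].push_back(b);

  auto oob_acc = [&](const NumericMatrix& Xm) {
    int used = 0, right = 0;
    std::vector<int> cnt(nclass);
    for (int i = 0; i < n; ++i) {
      if (oob_trees[i].empty()) continue;
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int b : oob_trees[i]) cnt[tree_predict(forest[b], Xm, i)]++;
      int best = 0;
      for (int k = 1; k < nclass; ++k) if (cnt[k] > cnt[best]) best = k;
      ++used;
      if (best == y[i]) ++right;
    }
    return used > 0 ? (double)right / used : NA_REAL;
  };

  double base = oob_acc(X);
  NumericMatrix drops(p, repeats);
  std::mt19937 rng((uint32_t)seed);
  NumericMatrix Xw = clone(X);
  std::vector<double> orig(n);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) orig[i] = Xw(i, f);
    for (int r = 0; r < repeats; ++r) {
      // Fisher-Yates permutation of column f
      for (int i = 0; i < n; ++i) Xw(i, f) = orig[i];
      for (int i = n - 1; i > 0; --i) {
        std::uniform_int_distribution<int> d(0, i);
        std::swap(Xw(i, f), Xw(d(rng), f));
      }
      drops(f, r) = base - oob_acc(Xw);
    }
    for (int i = 0; i < n; ++i) Xw(i, f) = orig[i];
  }
  return drops;
}
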
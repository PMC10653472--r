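// Weighted classification forest + generalized Random Intersection Trees.
//
// Trees are axis-aligned CART classification trees grown on an in-tree
// bootstrap; at every split, `mtry` distinct candidate features are drawn
// without replacement with probability proportional to `feature_weights`.
// The best candidate maximizes the count-weighted Gini decrease
//   n * G(parent) - n_L * G(left) - n_R * G(right),  G = 1 - sum p_k^2.
// Ties are broken by lowest feature index, then lowest threshold, so runs
// are bit-reproducible under a fixed seed.
//
// Signed items are encoded as +-(feature_index + 1): positive for the ">"
// branch, negative for the "<=" branch.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // left: x <= threshold, right: x > threshold
  int left, right;  // node indices, -1 for leaf
  int n, n1;        // bootstrap sample count / class-1 count at node
  double decrease;  // count-weighted Gini decrease of this split (0 at leaf)
};

inline double gini_from_counts(int n, int n1) {
  if (n == 0) return 0.0;
  double p1 = static_cast<double>(n1) / n;
  return 2.0 * p1 * (1.0 - p1);
}

// mtry distinct indices, probability proportional to w (w >= 0, sum > 0)
void weighted_sample_noreplace(const std::vector<double>& w, int mtry,
                               std::mt19937& rng, std::vector<int>& out) {
  out.clear();
  std::vector<double> wk(w);
  double total = 0.0;
  for (double v : wk) total += v;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int p = static_cast<int>(wk.size());
  for (int d = 0; d < mtry && total > 0.0; ++d) {
    double u = unif(rng) * total;
    double acc = 0.0;
    int pick = -1;
    for (int j = 0; j < p; ++j) {
      if (wk[j] <= 0.0) continue;
      acc += wk[j];
      if (u <= acc) { pick = j; break; }
    }
    if (pick < 0) { // numerical tail: take last positive
      for (int j = p - 1; j >= 0; --j) if (wk[j] > 0.0) { pick = j; break; }
    }
    if (pick < 0) break;
    out.push_back(pick);
    total -= wk[pick];
    wk[pick] = 0.0;
  }
  std::sort(out.begin(), out.end()); // lowest-index-first tie break
}

struct SplitResult {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  double decrease = -1.0;
};

// Node samples as (row, multiplicity) pairs: bootstrap duplicates are
// collapsed, and counts weight the Gini decrease exactly as per-sample
// evaluation would.
struct RowMult {
  int row;
  int mult;
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  const std::vector<double>& w;
  int mtry, min_node, max_depth;
  std::mt19937& rng;
  std::vector<Node>& nodes;
  const std::vector<std::vector<int>>& sorted_idx; // per feature, rows by value
  std::vector<int> node_mult;                      // scratch, size n, zeroed
  // scratch buffers for the boundary scan
  std::vector<double> sv;
  std::vector<int> sm, s1;

  Grower(const NumericMatrix& X_, const IntegerVector& y_,
         const std::vector<double>& w_, int mtry_, int min_node_,
         int max_depth_, std::mt19937& rng_, std::vector<Node>& nodes_,
         const std::vector<std::vector<int>>& sorted_idx_)
      : X(X_), y(y_), w(w_), mtry(mtry_), min_node(min_node_),
        max_depth(max_depth_), rng(rng_), nodes(nodes_),
        sorted_idx(sorted_idx_), node_mult(X_.nrow(), 0) {
    sv.reserve(X_.nrow());
    sm.reserve(X_.nrow());
    s1.reserve(X_.nrow());
  }

  // scan collected (ascending-value) runs for the best boundary of feature f
  void scan_boundaries(int f, int n, int n1, double impurity_parent,
                       SplitResult& best) {
    int k = static_cast<int>(sv.size());
    if (k < 2) return;
    int nl = 0, nl1 = 0;
    for (int i = 0; i + 1 < k; ++i) {
      nl += sm[i];
      nl1 += s1[i];
      int nr = n - nl, nr1 = n1 - nl1;
      if (nl < min_node || nr < min_node) continue;
      double dec = impurity_parent - nl * gini_from_counts(nl, nl1) -
                   nr * gini_from_counts(nr, nr1);
      if (dec > best.decrease + 1e-12) { // strict: keeps lowest feature/threshold
        best.found = true;
        best.feature = f;
        best.threshold = 0.5 * (sv[i] + sv[i + 1]);
        best.decrease = dec;
      }
    }
  }

  SplitResult best_split(const std::vector<RowMult>& rows,
                         const std::vector<int>& candidates, int n, int n1) {
    SplitResult best;
    double impurity_parent = n * gini_from_counts(n, n1);
    int n_total = X.nrow();
    size_t k = rows.size();
    // presorted scan costs O(n_total); local sort costs O(k log k)
    bool use_scan = 2.0 * k * std::log2(static_cast<double>(k) + 1) >
                    static_cast<double>(n_total);
    if (use_scan) {
      for (const RowMult& rm : rows) node_mult[rm.row] = rm.mult;
      for (int f : candidates) {
        sv.clear(); sm.clear(); s1.clear();
        for (int r : sorted_idx[f]) {
          int m = node_mult[r];
          if (m == 0) continue;
          double v = X(r, f);
          if (!sv.empty() && sv.back() == v) {
            sm.back() += m;
            s1.back() += m * y[r];
          } else {
            sv.push_back(v);
            sm.push_back(m);
            s1.push_back(m * y[r]);
          }
        }
        scan_boundaries(f, n, n1, impurity_parent, best);
      }
      for (const RowMult& rm : rows) node_mult[rm.row] = 0;
    } else {
      std::vector<std::pair<double, int>> vals(k); // (value, row index into rows)
      for (int f : candidates) {
        for (size_t i = 0; i < k; ++i) vals[i] = {X(rows[i].row, f), (int)i};
        std::sort(vals.begin(), vals.end());
        sv.clear(); sm.clear(); s1.clear();
        for (size_t i = 0; i < k; ++i) {
          const RowMult& rm = rows[vals[i].second];
          double v = vals[i].first;
          if (!sv.empty() && sv.back() == v) {
            sm.back() += rm.mult;
            s1.back() += rm.mult * y[rm.row];
          } else {
            sv.push_back(v);
            sm.push_back(rm.mult);
            s1.push_back(rm.mult * y[rm.row]);
          }
        }
        scan_boundaries(f, n, n1, impurity_parent, best);
      }
    }
    return best;
  }

  void grow(int node_id, std::vector<RowMult>& rows, int depth) {
    int n = 0, n1 = 0;
    for (const RowMult& rm : rows) {
      n += rm.mult;
      n1 += rm.mult * y[rm.row];
    }
    nodes[node_id].n = n;
    nodes[node_id].n1 = n1;
    bool pure = (n1 == 0 || n1 == n);
    if (pure || n < 2 * min_node || n < 2 ||
        (max_depth >= 0 && depth >= max_depth)) {
      return; // leaf
    }
    std::vector<int> cand;
    weighted_sample_noreplace(w, mtry, rng, cand);
    if (cand.empty()) return;
    SplitResult sp = best_split(rows, cand, n, n1);
    if (!sp.found) return;

    std::vector<RowMult> left_rows, right_rows;
    left_rows.reserve(rows.size());
    right_rows.reserve(rows.size());
    for (const RowMult& rm : rows)
      (X(rm.row, sp.feature) <= sp.threshold ? left_rows : right_rows)
          .push_back(rm);

    int left_id = static_cast<int>(nodes.size());
    nodes.push_back(Node{-1, 0.0, -1, -1, 0, 0, 0.0});
    int right_id = static_cast<int>(nodes.size());
    nodes.push_back(Node{-1, 0.0, -1, -1, 0, 0, 0.0});
    nodes[node_id].feature = sp.feature;
    nodes[node_id].threshold = sp.threshold;
    nodes[node_id].left = left_id;
    nodes[node_id].right = right_id;
    nodes[node_id].decrease = sp.decrease;

    rows.clear();
    rows.shrink_to_fit();
    grow(left_id, left_rows, depth + 1);
    grow(right_id, right_rows, depth + 1);
  }
};

List tree_to_list(const std::vector<Node>& nodes) {
  int m = static_cast<int>(nodes.size());
  IntegerVector feature(m), left(m), right(m), n(m), n1(m);
  NumericVector threshold(m), decrease(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature < 0 ? NA_INTEGER : nodes[i].feature + 1;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left < 0 ? NA_INTEGER : nodes[i].left + 1;
    right[i] = nodes[i].right < 0 ? NA_INTEGER : nodes[i].right + 1;
    n[i] = nodes[i].n;
    n1[i] = nodes[i].n1;
    decrease[i] = nodes[i].decrease;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["n"] = n,
                      _["n1"] = n1, _["decrease"] = decrease);
}

} // namespace

// [[Rcpp::export(name = "cpp_grow_forest")]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y,
                     NumericVector feature_weights, int n_trees, int mtry,
                     int min_node, int max_depth, bool bootstrap, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(feature_weights.begin(), feature_weights.end());
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_int_distribution<int> samp(0, n - 1);

  // per-feature row order by value, shared by all trees
  std::vector<std::vector<int>> sorted_idx(p);
  for (int f = 0; f < p; ++f) {
    if (w[f] <= 0.0) continue; // never a candidate
    sorted_idx[f].resize(n);
    for (int i = 0; i < n; ++i) sorted_idx[f][i] = i;
    std::sort(sorted_idx[f].begin(), sorted_idx[f].end(),
              [&](int a, int b) { return X(a, f) < X(b, f); });
  }

  List trees(n_trees);
  NumericVector importances(p);
  std::vector<int> mult(n);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(mult.begin(), mult.end(), 0);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) mult[samp(rng)] += 1;
    } else {
      std::fill(mult.begin(), mult.end(), 1);
    }
    std::vector<RowMult> rows;
    rows.reserve(n);
    for (int i = 0; i < n; ++i)
      if (mult[i] > 0) rows.push_back(RowMult{i, mult[i]});
    std::vector<Node> nodes;
    nodes.reserve(64);
    nodes.push_back(Node{-1, 0.0, -1, -1, 0, 0, 0.0});
    Grower grower(X, y, w, mtry, min_node, max_depth, rng, nodes, sorted_idx);
    grower.grow(0, rows, 0);
    for (const Node& nd : nodes)
      if (nd.feature >= 0) importances[nd.feature] += nd.decrease;
    trees[t] = tree_to_list(nodes);
  }
  for (int j = 0; j < p; ++j) importances[j] /= n_trees;
  return List::create(_["trees"] = trees, _["importances"] = importances);
}

// [[Rcpp::export(name = "cpp_predict_forest")]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  int n = X.nrow();
  int n_trees = trees.size();
  NumericVector prob(n);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"], nn = tr["n"], n1 = tr["n1"];
    NumericVector threshold = tr["threshold"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] != NA_INTEGER) {
        int f = feature[node] - 1;
        node = (X(i, f) <= threshold[node] ? left[node] : right[node]) - 1;
      }
      prob[i] += nn[node] > 0 ? static_cast<double>(n1[node]) / nn[node] : 0.5;
    }
  }
  for (int i = 0; i < n; ++i) prob[i] /= n_trees;
  return prob;
}

namespace {

// Depth-first path walk emitting, for every leaf with n1 >= 1, the signed
// root-to-leaf feature set. A feature split twice keeps the deepest sign.
void walk_paths(const IntegerVector& feature, const NumericVector& threshold,
                const IntegerVector& left, const IntegerVector& right,
                const IntegerVector& nn, const IntegerVector& n1, int node,
                std::vector<int>& path, std::vector<std::vector<int>>& sets,
                std::vector<int>& weights) {
  if (feature[node] == NA_INTEGER) {
    if (n1[node] >= 1) {
      std::vector<int> s(path);
      std::sort(s.begin(), s.end(),
                [](int a, int b) { return std::abs(a) < std::abs(b); });
      sets.push_back(std::move(s));
      weights.push_back(n1[node]);
    }
    return;
  }
  int f = feature[node];
  for (int sign : {-1, +1}) {
    // deepest-split-wins: drop any earlier occurrence of this feature
    std::vector<int> saved(path);
    path.erase(std::remove_if(path.begin(), path.end(),
                              [f](int it) { return std::abs(it) == f; }),
               path.end());
    path.push_back(sign * f);
    int child = (sign < 0 ? left[node] : right[node]) - 1;
    walk_paths(feature, threshold, left, right, nn, n1, child, path, sets,
               weights);
    path = std::move(saved);
  }
}

} // namespace

// [[Rcpp::export(name = "cpp_extract_itemsets")]]
List cpp_extract_itemsets(List trees) {
  std::vector<std::vector<int>> sets;
  std::vector<int> weights;
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"], nn = tr["n"], n1 = tr["n1"];
    NumericVector threshold = tr["threshold"];
    std::vector<int> path;
    if (feature.size() > 0 && feature[0] != NA_INTEGER) {
      walk_paths(feature, threshold, left, right, nn, n1, 0, path, sets,
                 weights);
    }
    // a root leaf has an empty path: no itemset to emit
  }
  int m = static_cast<int>(sets.size());
  List items(m);
  IntegerVector w(m);
  for (int i = 0; i < m; ++i) {
    items[i] = IntegerVector(sets[i].begin(), sets[i].end());
    w[i] = weights[i];
  }
  return List::create(_["items"] = items, _["weights"] = w);
}

// [[Rcpp::export(name = "cpp_rit")]]
List cpp_rit(List itemsets, NumericVector weights, int n_rit_trees, int depth,
             int n_child, int min_order, int seed) {
  int m = itemsets.size();
  std::vector<std::vector<int>> sets(m);
  for (int i = 0; i < m; ++i) {
    IntegerVector v = itemsets[i];
    sets[i].assign(v.begin(), v.end());
    std::sort(sets[i].begin(), sets[i].end());
  }
  std::vector<double> cum(m);
  double total = 0.0;
  for (int i = 0; i < m; ++i) {
    total += weights[i];
    cum[i] = total;
  }
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto draw = [&]() {
    double u = unif(rng) * total;
    return static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) -
                            cum.begin());
  };
  // a draw that avoids index `avoid`, so every depth>=1 survivor is the
  // intersection of at least two distinct input itemsets
  auto draw_excluding = [&](int avoid) {
    if (m == 1) return 0;
    for (int tries = 0; tries < 64; ++tries) {
      int k = draw();
      if (k != avoid) return k;
    }
    return (avoid + 1) % m;
  };

  std::set<std::vector<int>> survivors;
  // iterative DFS over the n_child-ary intersection tree of depth `depth`
  struct Frame {
    std::vector<int> s;
    int d;
  };
  for (int t = 0; t < n_rit_trees; ++t) {
    int root_idx = draw();
    std::vector<Frame> stack;
    stack.push_back({sets[root_idx], 0});
    while (!stack.empty()) {
      Frame fr = std::move(stack.back());
      stack.pop_back();
      if (static_cast<int>(fr.s.size()) < min_order) continue; // dead branch
      if (fr.d == depth) {
        survivors.insert(fr.s);
        continue;
      }
      for (int c = 0; c < n_child; ++c) {
        int k = fr.d == 0 ? draw_excluding(root_idx) : draw();
        const std::vector<int>& other = sets[k];
        std::vector<int> inter;
        std::set_intersection(fr.s.begin(), fr.s.end(), other.begin(),
                              other.end(), std::back_inserter(inter));
        stack.push_back({std::move(inter), fr.d + 1});
      }
    }
  }
  List out(survivors.size());
  int k = 0;
  for (const auto& s : survivors)
    out[k++] = IntegerVector(s.begin(), s.end());
  return out;
}
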
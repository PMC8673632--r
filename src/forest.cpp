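#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

// A compact CART random forest: Gini impurity splits, bootstrap resampling,
// a random subset of `mtry` features considered at every split (scikit-learn
// semantics), depth cap, no limit on leaf count.  Trees are returned as flat
// numeric matrices so a fitted forest is an ordinary R list, cheap to
// serialise.  All randomness comes from R's RNG (RNGScope), so results are
// reproducible under set.seed().
//
// Tree matrix layout, one row per node:
//   col 0: feature index (0-based) or -1 for a leaf
//   col 1: threshold (go left if x <= threshold)
//   col 2: left child row (0-based), -1 for leaf
//   col 3: right child row (0-based), -1 for leaf
//   col 4..4+nclass-1: training class counts reaching the node (leaf only)

struct NodeJob { int begin, end, depth, row; };

static int rand_int(int n) {             // uniform on 0..n-1 via R RNG
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

static void build_tree(const NumericMatrix &X, const IntegerVector &y,
                       std::vector<int> &idx, int nclass, int mtry,
                       int max_depth, int min_split,
                       std::vector<std::array<double, 4>> &nodes,
                       std::vector<std::vector<double>> &counts) {
  const int p = X.ncol();
  std::vector<NodeJob> stack;
  nodes.push_back({-1.0, 0.0, -1.0, -1.0});
  counts.push_back(std::vector<double>(nclass, 0.0));
  stack.push_back({0, (int)idx.size(), 0, 0});
  std::vector<int> feats(p);
  std::vector<double> cnt(nclass), lcnt(nclass), rcnt(nclass);

  while (!stack.empty()) {
    NodeJob job = stack.back(); stack.pop_back();
    const int n = job.end - job.begin;
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = job.begin; i < job.end; ++i) cnt[y[idx[i]]] += 1.0;
    int nonzero = 0;
    for (int c = 0; c < nclass; ++c) nonzero += (cnt[c] > 0);

    bool make_leaf = (job.depth >= max_depth) || (n < min_split) || (nonzero <= 1);
    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;

    if (!make_leaf) {
      double imp = 0.0;                       // parent Gini * n
      for (int c = 0; c < nclass; ++c) imp += cnt[c] * cnt[c];
      const double parent_score = imp / n;    // sum p_c^2 * n

      // sample mtry distinct features (partial Fisher-Yates)
      for (int j = 0; j < p; ++j) feats[j] = j;
      for (int j = 0; j < mtry; ++j) std::swap(feats[j], feats[j + rand_int(p - j)]);

      std::vector<std::pair<double, int>> vals(n);
      for (int fj = 0; fj < mtry; ++fj) {
        const int f = feats[fj];
        for (int i = 0; i < n; ++i) {
          const int r = idx[job.begin + i];
          vals[i] = {X(r, f), y[r]};
        }
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue;
        std::fill(lcnt.begin(), lcnt.end(), 0.0);
        std::copy(cnt.begin(), cnt.end(), rcnt.begin());
        double ls2 = 0.0, rs2 = imp;
        int nl = 0;
        for (int i = 0; i < n - 1; ++i) {
          const int c = vals[i].second;
          ls2 += 2.0 * lcnt[c] + 1.0;  lcnt[c] += 1.0;
          rs2 -= 2.0 * rcnt[c] - 1.0;  rcnt[c] -= 1.0;
          ++nl;
          if (vals[i].first == vals[i + 1].first) continue;
          const int nr = n - nl;
          const double score = ls2 / nl + rs2 / nr;  // larger = purer
          if (score > parent_score + 1e-12 && score - parent_score > best_gain) {
            best_gain = score - parent_score;
            best_feat = f;
            best_thr = vals[i].first / 2.0 + vals[i + 1].first / 2.0;
          }
        }
      }
      if (best_feat < 0) make_leaf = true;
    }

    if (make_leaf) {
      nodes[job.row] = {-1.0, 0.0, -1.0, -1.0};
      counts[job.row] = std::vector<double>(cnt.begin(), cnt.end());
      continue;
    }

    // partition idx[begin..end) by the chosen split
    int mid = job.begin;
    for (int i = job.begin; i < job.end; ++i)
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);

    const int lrow = (int)nodes.size(), rrow = lrow + 1;
    nodes[job.row] = {(double)best_feat, best_thr, (double)lrow, (double)rrow};
    counts[job.row] = std::vector<double>(nclass, 0.0);
    nodes.push_back({-1.0, 0.0, -1.0, -1.0});
    counts.push_back(std::vector<double>(nclass, 0.0));
    nodes.push_back({-1.0, 0.0, -1.0, -1.0});
    counts.push_back(std::vector<double>(nclass, 0.0));
    stack.push_back({job.begin, mid, job.depth + 1, lrow});
    stack.push_back({mid, job.end, job.depth + 1, rrow});
  }
}

// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int nclass,
                  int n_trees, int max_depth, int mtry, int min_split) {
  RNGScope scope;
  const int n = X.nrow();
  List trees(n_trees);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n);   // bootstrap sample
    std::vector<std::array<double, 4>> nodes;
    std::vector<std::vector<double>> counts;
    build_tree(X, y, idx, nclass, mtry, max_depth, min_split, nodes, counts);
    NumericMatrix tm((int)nodes.size(), 4 + nclass);
    for (size_t r = 0; r < nodes.size(); ++r) {
      for (int c = 0; c < 4; ++c) tm(r, c) = nodes[r][c];
      for (int c = 0; c < nclass; ++c) tm(r, 4 + c) = counts[r][c];
    }
    trees[t] = tm;
  }
  return trees;
}

// Average of per-tree leaf class distributions (scikit-learn's
// predict_proba convention).
// [[Rcpp::export]]
NumericMatrix cpp_rf_proba(List trees, NumericMatrix X, int nclass) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, nclass);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tm(node, 0) >= 0) {
        const int f = (int)tm(node, 0);
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2) : (int)tm(node, 3);
      }
      double tot = 0.0;
      for (int c = 0; c < nclass; ++c) tot += tm(node, 4 + c);
      for (int c = 0; c < nclass; ++c) out(i, c) += tm(node, 4 + c) / tot;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nclass; ++c) out(i, c) /= T;
  return out;
}

// [[Rcpp::export]]
int cpp_rf_max_depth(List trees) {
  int maxd = 0;
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    // depth via BFS from root
    std::vector<int> depth(tm.nrow(), 0);
    for (int r = 0; r < tm.nrow(); ++r) {
      if (tm(r, 0) >= 0) {
        depth[(int)tm(r, 2)] = depth[r] + 1;
        depth[(int)tm(r, 3)] = depth[r] + 1;
        maxd = std::max(maxd, depth[r] + 1);
      }
    }
  }
  return maxd;
}
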
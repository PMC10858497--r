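// Honest regression forest core.
//
// Each tree is grown on a without-replacement subsample that is split into a
// "split half" (used to choose splits) and a disjoint "estimation half"
// (used to compute leaf means), so no leaf mean ever uses an observation
// that influenced the tree's structure. Split search maximises the variance
// reduction of the split-half responses minus an imbalance penalty
// imbalance_penalty * (1/n_left + 1/n_right), subject to each child holding
// at least alpha * (parent split count) split-half points and at least
// min_node_size estimation-half points.
//
// All randomness comes from std::mt19937 streams derived from the supplied
// seed; mt19937 output is specified by the standard, so fits are
// reproducible across platforms.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline uint32_t rand_below(std::mt19937 &rng, uint32_t n) {
  // rejection sampling: unbiased and implementation-independent
  uint32_t limit = UINT32_MAX - (UINT32_MAX % n);
  uint32_t v;
  do {
    v = rng();
  } while (v >= limit);
  return v % n;
}

// sample k distinct integers from 0..n-1 (partial Fisher-Yates)
static std::vector<int> sample_without_replacement(std::mt19937 &rng, int n,
                                                   int k) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    uint32_t j = i + rand_below(rng, (uint32_t)(n - i));
    std::swap(pool[i], pool[j]);
  }
  pool.resize(k);
  return pool;
}

struct TreeNodes {
  std::vector<int> split_var;     // -1 for leaf
  std::vector<double> split_val;
  std::vector<int> left_child;    // 0-based, -1 for leaf
  std::vector<int> right_child;
  std::vector<double> leaf_value;
  std::vector<int> depth;         // root = 1
  std::vector<int> n_est;         // estimation points in node
};

struct BuildCtx {
  const NumericMatrix &X;
  const NumericVector &y;
  int mtry;
  int min_node_size;
  double alpha;
  double imbalance_penalty;
  std::mt19937 &rng;
  TreeNodes &tree;
};

// returns node index
static int build_node(BuildCtx &ctx, std::vector<int> &split_idx,
                      std::vector<int> &est_idx, int depth) {
  const int p = ctx.X.ncol();
  const int nS = (int)split_idx.size();
  const int nE = (int)est_idx.size();

  int node = (int)ctx.tree.split_var.size();
  ctx.tree.split_var.push_back(-1);
  ctx.tree.split_val.push_back(NA_REAL);
  ctx.tree.left_child.push_back(-1);
  ctx.tree.right_child.push_back(-1);
  ctx.tree.leaf_value.push_back(NA_REAL);
  ctx.tree.depth.push_back(depth);
  ctx.tree.n_est.push_back(nE);

  int min_child_split = std::max(1, (int)std::ceil(ctx.alpha * nS));

  double best_gain = 1e-10;
  int best_var = -1;
  double best_thresh = 0.0;

  bool can_split = nS >= 2 * min_child_split && nE >= 2 * ctx.min_node_size;

  if (can_split) {
    std::vector<int> vars =
        sample_without_replacement(ctx.rng, p, std::min(ctx.mtry, p));

    double sumT = 0.0;
    for (int i : split_idx) sumT += ctx.y[i];

    std::vector<std::pair<double, double>> xy(nS);  // (x, y) split half
    std::vector<double> ex(nE);                     // x estimation half

    for (int v : vars) {
      for (int k = 0; k < nS; ++k) {
        xy[k] = {ctx.X(split_idx[k], v), ctx.y[split_idx[k]]};
      }
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue;  // constant feature

      for (int k = 0; k < nE; ++k) ex[k] = ctx.X(est_idx[k], v);
      std::sort(ex.begin(), ex.end());

      double sumL = 0.0;
      int e_ptr = 0;
      for (int k = 0; k < nS - 1; ++k) {
        sumL += xy[k].second;
        if (xy[k].first == xy[k + 1].first) continue;  // not a boundary
        int nL = k + 1;
        int nR = nS - nL;
        if (nL < min_child_split || nR < min_child_split) continue;
        double thresh = 0.5 * (xy[k].first + xy[k + 1].first);
        while (e_ptr < nE && ex[e_ptr] <= thresh) ++e_ptr;
        int eL = e_ptr;
        int eR = nE - eL;
        if (eL < ctx.min_node_size || eR < ctx.min_node_size) continue;
        double sumR = sumT - sumL;
        double gain = sumL * sumL / nL + sumR * sumR / nR - sumT * sumT / nS -
                      ctx.imbalance_penalty * (1.0 / nL + 1.0 / nR);
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          best_thresh = thresh;
        }
      }
      // reset estimation pointer for next variable
      e_ptr = 0;
    }
  }

  if (best_var < 0) {
    // leaf: honest mean over the estimation half (split half as a guarded
    // fallback if a degenerate configuration leaves no estimation points)
    double s = 0.0;
    if (nE > 0) {
      for (int i : est_idx) s += ctx.y[i];
      ctx.tree.leaf_value[node] = s / nE;
    } else {
      for (int i : split_idx) s += ctx.y[i];
      ctx.tree.leaf_value[node] = nS > 0 ? s / nS : 0.0;
    }
    return node;
  }

  std::vector<int> sL, sR, eL, eR;
  for (int i : split_idx) {
    (ctx.X(i, best_var) <= best_thresh ? sL : sR).push_back(i);
  }
  for (int i : est_idx) {
    (ctx.X(i, best_var) <= best_thresh ? eL : eR).push_back(i);
  }

  ctx.tree.split_var[node] = best_var;
  ctx.tree.split_val[node] = best_thresh;
  int l = build_node(ctx, sL, eL, depth + 1);
  int r = build_node(ctx, sR, eR, depth + 1);
  ctx.tree.left_child[node] = l;
  ctx.tree.right_child[node] = r;
  return node;
}

// [[Rcpp::export]]
List hf_fit(NumericMatrix X, NumericVector y, int num_trees,
            double sample_fraction, int mtry, int min_node_size, double alpha,
            double imbalance_penalty, double honesty_fraction,
            uint32_t seed) {
  const int n = X.nrow();
  int s = (int)std::floor(sample_fraction * n);
  if (s < 2) stop("subsample size below 2; increase sample_fraction or n");
  int n_split = (int)std::round(honesty_fraction * s);
  if (n_split < 1 || n_split >= s) {
    stop("honesty_fraction leaves an empty split or estimation half");
  }

  std::mt19937 master(seed);
  std::vector<uint32_t> tree_seeds(num_trees);
  for (int t = 0; t < num_trees; ++t) tree_seeds[t] = master();

  List trees(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    std::mt19937 rng(tree_seeds[t]);
    std::vector<int> sub = sample_without_replacement(rng, n, s);
    std::vector<int> split_idx(sub.begin(), sub.begin() + n_split);
    std::vector<int> est_idx(sub.begin() + n_split, sub.end());

    TreeNodes tree;
    BuildCtx ctx{X, y, mtry, min_node_size, alpha, imbalance_penalty, rng,
                 tree};
    build_node(ctx, split_idx, est_idx, 1);

    trees[t] = List::create(
        _["split_var"] = IntegerVector(tree.split_var.begin(),
                                       tree.split_var.end()),
        _["split_val"] = NumericVector(tree.split_val.begin(),
                                       tree.split_val.end()),
        _["left"] = IntegerVector(tree.left_child.begin(),
                                  tree.left_child.end()),
        _["right"] = IntegerVector(tree.right_child.begin(),
                                   tree.right_child.end()),
        _["leaf_value"] = NumericVector(tree.leaf_value.begin(),
                                        tree.leaf_value.end()),
        _["depth"] = IntegerVector(tree.depth.begin(), tree.depth.end()),
        _["n_est"] = IntegerVector(tree.n_est.begin(), tree.n_est.end()),
        _["subsample"] = IntegerVector(sub.begin(), sub.end()),
        _["split_idx"] = IntegerVector(split_idx.begin(), split_idx.end()),
        _["est_idx"] = IntegerVector(est_idx.begin(), est_idx.end()));
  }
  return trees;
}

static inline double tree_predict_row(const List &tree,
                                      const NumericMatrix &X, int row) {
  IntegerVector split_var = tree["split_var"];
  NumericVector split_val = tree["split_val"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  NumericVector leaf_value = tree["leaf_value"];
  int node = 0;
  while (split_var[node] >= 0) {
    node = X(row, split_var[node]) <= split_val[node] ? left[node]
                                                      : right[node];
  }
  return leaf_value[node];
}

// [[Rcpp::export]]
NumericVector hf_predict(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Out-of-bag predictions on the training matrix: row i is averaged only over
// trees whose subsample excluded i. n_oob_trees is returned alongside; rows
// with no eligible tree get NA.
// [[Rcpp::export]]
List hf_predict_oob(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector acc(n);
  IntegerVector cnt(n);
  std::vector<char> inbag(n);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector sub = tree["subsample"];
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < sub.size(); ++i) inbag[sub[i]] = 1;
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        acc[i] += tree_predict_row(tree, X, i);
        cnt[i] += 1;
      }
    }
  }
  NumericVector pred(n);
  for (int i = 0; i < n; ++i) {
    pred[i] = cnt[i] > 0 ? acc[i] / cnt[i] : NA_REAL;
  }
  return List::create(_["prediction"] = pred, _["n_oob_trees"] = cnt);
}
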
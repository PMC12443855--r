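// Exact path-dependent Shapley attribution for tree ensembles.
//
// The ensemble value for one class is the sum over trees of the leaf value
// reached by the sample.  Conditional expectations given a feature subset S
// follow the standard path-dependent semantics: at a split on a feature in
// S the sample's branch is taken; otherwise both children are averaged with
// training-cover weights.  Because that expectation decomposes over leaves,
// and the per-leaf game depends only on the (few) distinct features on the
// leaf's path, Shapley values can be computed exactly by enumerating the
// 2^d subsets of each leaf path's distinct features.  This is exponential
// only in per-path feature multiplicity, which is bounded by tree depth.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Tree {
  IntegerVector feature;  // 0-based column, -1 for leaf
  NumericVector split;
  IntegerVector yes, no;  // 0-based node index, -1 for leaf
  NumericVector cover;
  NumericMatrix value;    // n_nodes x n_classes, leaf rows meaningful
  bool le;                // true: go left when x <= split, else x < split
};

Tree unpack(const List& tr) {
  Tree t;
  t.feature = tr["feature"];
  t.split = tr["split"];
  t.yes = tr["yes"];
  t.no = tr["no"];
  t.cover = tr["cover"];
  t.value = as<NumericMatrix>(tr["value"]);
  t.le = as<bool>(tr["le"]);
  return t;
}

}  // namespace

// [[Rcpp::export]]
NumericVector treeshap_cpp(List trees, NumericMatrix X, int n_classes,
                           int max_path_features = 18) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector phi(static_cast<R_xlen_t>(n) * p * n_classes);
  phi.attr("dim") = IntegerVector::create(n, p, n_classes);

  for (int ti = 0; ti < trees.size(); ++ti) {
    Tree t = unpack(trees[ti]);
    const int m = t.feature.size();
    // parent/side links and leaf list
    std::vector<int> parent(m, -1), side(m, 0);
    std::vector<int> leaves;
    for (int v = 0; v < m; ++v) {
      if (t.feature[v] < 0) { leaves.push_back(v); continue; }
      parent[t.yes[v]] = v; side[t.yes[v]] = 0;
      parent[t.no[v]]  = v; side[t.no[v]]  = 1;
    }

    for (size_t li = 0; li < leaves.size(); ++li) {
      const int leaf = leaves[li];
      // collect path bottom-up: nodes (parents) from leaf to root
      std::vector<int> pnode, pside;
      for (int v = leaf; parent[v] >= 0; v = parent[v]) {
        pnode.push_back(parent[v]);
        pside.push_back(side[v]);
      }
      const int plen = pnode.size();
      if (plen == 0) {  // single-leaf tree: constant, no attribution
        continue;
      }
      // distinct features on the path
      std::vector<int> uniq;
      std::vector<int> fidx(plen);  // index into uniq per path entry
      for (int e = 0; e < plen; ++e) {
        int f = t.feature[pnode[e]];
        int j = -1;
        for (size_t u = 0; u < uniq.size(); ++u)
          if (uniq[u] == f) { j = (int)u; break; }
        if (j < 0) { uniq.push_back(f); j = uniq.size() - 1; }
        fidx[e] = j;
      }
      const int d = uniq.size();
      if (d > max_path_features)
        stop("tree path uses %d distinct features; exact enumeration capped at %d",
             d, max_path_features);
      const size_t nmask = ((size_t)1) << d;

      // Shapley kernel weights by |S| over d players
      std::vector<double> W(d);
      for (int s = 0; s < d; ++s) {
        double w = 1.0;  // s! (d-s-1)! / d!
        for (int i = 2; i <= s; ++i) w *= i;
        for (int i = 2; i <= d - s - 1; ++i) w *= i;
        for (int i = 2; i <= d; ++i) w /= i;
        W[s] = w;
      }
      // per-path-entry cover fraction child/parent
      std::vector<double> frac(plen);
      for (int e = 0; e < plen; ++e) {
        int v = pnode[e];
        int child = (pside[e] == 0) ? t.yes[v] : t.no[v];
        frac[e] = t.cover[child] / t.cover[v];
      }
      std::vector<double> wmask(nmask);
      std::vector<int> popcnt(nmask);
      std::vector<double> contrib(d);

      for (int si = 0; si < n; ++si) {
        // branch x takes at each path entry; does it follow the leaf side?
        bool reachable_all = true;
        std::vector<bool> follows(plen);
        for (int e = 0; e < plen; ++e) {
          int v = pnode[e];
          double xv = X(si, t.feature[v]);
          bool goleft = t.le ? (xv <= t.split[v]) : (xv < t.split[v]);
          follows[e] = (goleft == (pside[e] == 0));
          if (!follows[e]) reachable_all = false;
        }
        (void)reachable_all;
        // weight of reaching this leaf for every subset mask of uniq
        for (size_t mask = 0; mask < nmask; ++mask) {
          double w = 1.0;
          int pc = 0;
          for (int e = 0; e < plen && w != 0.0; ++e) {
            if (mask & (((size_t)1) << fidx[e])) {
              if (!follows[e]) w = 0.0;
            } else {
              w *= frac[e];
            }
          }
          for (int b = 0; b < d; ++b) if (mask & (((size_t)1) << b)) ++pc;
          wmask[mask] = w;
          popcnt[mask] = pc;
        }
        // marginal contributions per distinct feature
        for (int b = 0; b < d; ++b) {
          double c = 0.0;
          const size_t bit = ((size_t)1) << b;
          for (size_t mask = 0; mask < nmask; ++mask) {
            if (mask & bit) continue;
            c += W[popcnt[mask]] * (wmask[mask | bit] - wmask[mask]);
          }
          contrib[b] = c;
        }
        for (int k = 0; k < n_classes; ++k) {
          double val = t.value(leaf, k);
          if (val == 0.0) continue;
          for (int b = 0; b < d; ++b) {
            if (contrib[b] == 0.0) continue;
            phi[(R_xlen_t)si + (R_xlen_t)n * uniq[b] +
                (R_xlen_t)n * p * k] += contrib[b] * val;
          }
        }
      }
    }
  }
  return phi;
}

// Expected ensemble output per class under no information (the base value):
// cover-weighted mean leaf value, summed over trees.
// [[Rcpp::export]]
NumericVector treeshap_base_cpp(List trees, int n_classes) {
  NumericVector base(n_classes);
  for (int ti = 0; ti < trees.size(); ++ti) {
    Tree t = unpack(trees[ti]);
    const int m = t.feature.size();
    // probability of reaching each node from the root under cover weights
    std::vector<double> reach(m, 0.0);
    reach[0] = 1.0;
    for (int v = 0; v < m; ++v) {
      if (t.feature[v] < 0) continue;
      reach[t.yes[v]] += reach[v] * t.cover[t.yes[v]] / t.cover[v];
      reach[t.no[v]]  += reach[v] * t.cover[t.no[v]] / t.cover[v];
    }
    for (int v = 0; v < m; ++v)
      if (t.feature[v] < 0)
        for (int k = 0; k < n_classes; ++k)
          base[k] += reach[v] * t.value(v, k);
  }
  return base;
}

// Training-cover computation: route weighted training rows through a tree.
// [[Rcpp::export]]
NumericVector tree_cover_cpp(IntegerVector feature, NumericVector split,
                             IntegerVector yes, IntegerVector no,
                             bool le, NumericMatrix X, NumericVector w) {
  const int m = feature.size(), n = X.nrow();
  NumericVector cover(m);
  for (int i = 0; i < n; ++i) {
    if (w[i] <= 0) continue;
    int v = 0;
    for (;;) {
      cover[v] += w[i];
      if (feature[v] < 0) break;
      double xv = X(i, feature[v]);
      bool goleft = le ? (xv <= split[v]) : (xv < split[v]);
      v = goleft ? yes[v] : no[v];
    }
  }
  return cover;
}

// Round a matrix to float32 precision (xgboost compares features and
// thresholds in single precision; routing must match it exactly).
// [[Rcpp::export]]
NumericMatrix round_float32_cpp(NumericMatrix X) {
  NumericMatrix out(X.nrow(), X.ncol());
  for (R_xlen_t i = 0; i < X.size(); ++i)
    out[i] = static_cast<double>(static_cast<float>(X[i]));
  out.attr("dimnames") = X.attr("dimnames");
  return out;
}
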
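// Path-dependent TreeSHAP for probability forests.
//
// Each tree is passed as flat arrays (0-based node ids): left/right child
// (-1 for a leaf), split feature (0-based column of X, -1 for a leaf),
// threshold (x <= threshold goes left, the ranger convention), per-node
// training cover, and a nodes x classes value matrix (leaf class
// probabilities). Contributions are exact per tree and averaged over the
// forest, so base value + sum of contributions reproduces the forest's
// predicted class probability to floating-point accuracy.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, unsigned unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; i--) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1) / double(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / double(unique_depth + 1);
  }
}

static void unwind_path(PathElement *unique_path, unsigned unique_depth,
                        unsigned path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               double((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                               (unique_depth - i) / double(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               double(zero_fraction * (unique_depth - i));
    }
  }
  for (unsigned i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *unique_path,
                               unsigned unique_depth, unsigned path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         double((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight -
                         tmp * zero_fraction *
                             ((unique_depth - i) / double(unique_depth + 1));
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / double(unique_depth + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *cover;
  const double *values;  // nodes x n_class, column-major
  int n_nodes, n_class;
  double value_at(int node, int cls) const {
    return values[cls * n_nodes + node];
  }
};

static void tree_shap_recursive(const Tree &tree, const double *x,
                                double *phi, int n_feat, int node,
                                unsigned unique_depth,
                                PathElement *parent_unique_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tree.left[node] < 0) {  // leaf
    for (unsigned i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      const double scale = w * (el.one_fraction - el.zero_fraction);
      for (int c = 0; c < tree.n_class; ++c)
        phi[c * n_feat + el.feature_index] += scale * tree.value_at(node, c);
    }
    return;
  }

  const int split_feature = tree.feature[node];
  int hot, cold;
  if (x[split_feature] <= tree.threshold[node]) {
    hot = tree.left[node];
    cold = tree.right[node];
  } else {
    hot = tree.right[node];
    cold = tree.left[node];
  }
  const double w = tree.cover[node];
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  // undo a previous split on the same feature
  unsigned path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (unique_path[path_index].feature_index == split_feature) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, n_feat, hot, unique_depth + 1,
                      unique_path,
                      incoming_zero_fraction * tree.cover[hot] / w,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tree, x, phi, n_feat, cold, unique_depth + 1,
                      unique_path,
                      incoming_zero_fraction * tree.cover[cold] / w, 0.0,
                      split_feature);
}

static int tree_max_depth(const Tree &tree, int node, int depth) {
  if (tree.left[node] < 0) return depth;
  return std::max(tree_max_depth(tree, tree.left[node], depth + 1),
                  tree_max_depth(tree, tree.right[node], depth + 1));
}

// [[Rcpp::export]]
List treeshap_forest(List trees, NumericMatrix X, int n_class) {
  const int n = X.nrow(), p = X.ncol(), n_trees = trees.size();
  // phi: n x p x n_class; base: n_class
  NumericVector phi(double(n) * p * n_class);
  phi.attr("dim") = IntegerVector::create(n, p, n_class);
  NumericVector base(n_class);

  std::vector<double> row(p);
  std::vector<double> phi_row(double(p) * n_class);

  for (int t = 0; t < n_trees; ++t) {
    List tl = trees[t];
    IntegerVector left = tl["left"], right = tl["right"],
                  feature = tl["feature"];
    NumericVector threshold = tl["threshold"], cover = tl["cover"];
    NumericMatrix values = tl["values"];
    Tree tree;
    tree.left = INTEGER(left);
    tree.right = INTEGER(right);
    tree.feature = INTEGER(feature);
    tree.threshold = REAL(threshold);
    tree.cover = REAL(cover);
    tree.values = REAL(values);
    tree.n_nodes = values.nrow();
    tree.n_class = n_class;

    // tree expected value: cover-weighted mean of leaf values
    const double root_cover = tree.cover[0];
    for (int j = 0; j < tree.n_nodes; ++j)
      if (tree.left[j] < 0)
        for (int c = 0; c < n_class; ++c)
          base[c] += tree.cover[j] / root_cover * tree.value_at(j, c) / n_trees;

    const int maxd = tree_max_depth(tree, 0, 0) + 2;
    std::vector<PathElement> path_buf((maxd * (maxd + 1)) / 2 + maxd);

    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) row[j] = X(i, j);
      std::fill(phi_row.begin(), phi_row.end(), 0.0);
      tree_shap_recursive(tree, row.data(), phi_row.data(), p, 0, 0,
                          path_buf.data(), 1.0, 1.0, -1);
      for (int c = 0; c < n_class; ++c)
        for (int j = 0; j < p; ++j)
          phi[std::size_t(c) * n * p + std::size_t(j) * n + i] +=
              phi_row[c * p + j] / n_trees;
    }
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
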
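#include <Rcpp.h>
using namespace Rcpp;

// Exact Shapley attributions for an ensemble of regression trees, computed
// in double precision by the polynomial-time path algorithm. Conditional
// expectations use the per-node sample covers, i.e. the same weighting the
// training data induced. Trees are passed flattened: per node its split
// feature (-1 for a leaf), threshold, left/right child (0-based, -1 for a
// leaf), leaf value and cover.

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; i--) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1) / (double)(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / (double)(unique_depth + 1);
  }
}

static void unwind_path(PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;

  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               (double)((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                         (unique_depth - i) / (double)(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               (zero_fraction * (unique_depth - i));
    }
  }

  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *unique_path,
                               int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;

  if (one_fraction != 0) {
    for (int i = unique_depth - 1; i >= 0; --i) {
      const double tmp = next_one_portion / (double)((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight -
                         tmp * zero_fraction * (unique_depth - i);
    }
  } else {
    for (int i = unique_depth - 1; i >= 0; --i) {
      total += unique_path[i].pweight /
               (zero_fraction * (unique_depth - i));
    }
  }
  return total * (unique_depth + 1);
}

struct Tree {
  const int *feature;       // -1 for leaf
  const double *threshold;
  const int *yes;           // child when x < threshold
  const int *no;
  const double *value;      // leaf value
  const double *cover;
};

static void tree_shap_recursive(const Tree &t, const double *x, double *phi,
                                int node, PathElement *parent_path,
                                int unique_depth, double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_path + unique_depth + 1;
  std::copy(parent_path, parent_path + unique_depth + 1, unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (t.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * t.value[node];
    }
    return;
  }

  const int split = t.feature[node];
  // xgboost compares in single precision; mirror it so routing matches
  const int hot = (float)x[split] < (float)t.threshold[node] ? t.yes[node]
                                                             : t.no[node];
  const int cold = hot == t.yes[node] ? t.no[node] : t.yes[node];
  const double w = t.cover[node];
  const double hot_zero_fraction = t.cover[hot] / w;
  const double cold_zero_fraction = t.cover[cold] / w;
  double incoming_zero_fraction = 1;
  double incoming_one_fraction = 1;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (unique_path[path_index].feature_index == split) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(t, x, phi, hot, unique_path, unique_depth + 1,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split);
  tree_shap_recursive(t, x, phi, cold, unique_path, unique_depth + 1,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split);
}

static int tree_depth(const Tree &t, int node) {
  if (t.feature[node] < 0) return 1;
  return 1 + std::max(tree_depth(t, t.yes[node]), tree_depth(t, t.no[node]));
}

// Cover-weighted expectation of one tree's output.
static double tree_expectation(const Tree &t, int node) {
  if (t.feature[node] < 0) return t.value[node];
  const int l = t.yes[node], r = t.no[node];
  return (t.cover[l] * tree_expectation(t, l) +
          t.cover[r] * tree_expectation(t, r)) / t.cover[node];
}

static double tree_predict(const Tree &t, const double *x) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (float)x[t.feature[node]] < (float)t.threshold[node]
               ? t.yes[node]
               : t.no[node];
  return t.value[node];
}

static Tree as_tree(List tr) {
  Tree t;
  t.feature = INTEGER(tr["feature"]);
  t.threshold = REAL(tr["threshold"]);
  t.yes = INTEGER(tr["yes"]);
  t.no = INTEGER(tr["no"]);
  t.value = REAL(tr["value"]);
  t.cover = REAL(tr["cover"]);
  return t;
}

// [[Rcpp::export(name = ".Call_treeshap")]]
List treeshap_ensemble(List trees, NumericMatrix X, double base_score) {
  const int n = X.nrow(), p = X.ncol(), m = trees.size();
  NumericMatrix phi(n, p);
  NumericVector pred(n), base(n);

  std::vector<Tree> ts(m);
  int max_depth = 0;
  double expectation = base_score;
  for (int k = 0; k < m; ++k) {
    ts[k] = as_tree(trees[k]);
    max_depth = std::max(max_depth, tree_depth(ts[k], 0));
    expectation += tree_expectation(ts[k], 0);
  }
  std::vector<PathElement> arena(((max_depth + 2) * (max_depth + 3)) / 2);

  std::vector<double> x(p), phi_i(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    std::fill(phi_i.begin(), phi_i.end(), 0.0);
    double f = base_score;
    for (int k = 0; k < m; ++k) {
      tree_shap_recursive(ts[k], x.data(), phi_i.data(), 0, arena.data(), 0,
                          1.0, 1.0, -1);
      f += tree_predict(ts[k], x.data());
    }
    for (int j = 0; j < p; ++j) phi(i, j) = phi_i[j];
    pred[i] = f;
    base[i] = expectation;
  }
  return List::create(_["phi"] = phi, _["prediction"] = pred,
                      _["base_value"] = base);
}
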
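#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gradient-boosted binary classification trees with the usual second-order
// regularized gain. Exact greedy splits; R's RNG drives row/column subsampling
// so results are reproducible under set.seed().

struct TreeNode {
  int feat;      // -1 for leaf
  double thr;    // go left if x <= thr
  int left, right;
  double value;  // leaf weight (already scaled by eta)
};

struct SplitResult {
  int feat;
  double thr;
  double gain;
  bool found;
};

static double soft_threshold(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

static double leaf_weight(double G, double H, double lambda, double alpha) {
  return -soft_threshold(G, alpha) / (H + lambda);
}

static double leaf_objective(double G, double H, double lambda, double alpha) {
  double w = soft_threshold(G, alpha);
  return 0.5 * w * w / (H + lambda);
}

static SplitResult best_split(const NumericMatrix &X,
                              const std::vector<double> &g,
                              const std::vector<double> &h,
                              const std::vector<int> &rows,
                              const std::vector<int> &feats,
                              double lambda, double alpha, double gamma,
                              double min_child_weight) {
  SplitResult best;
  best.found = false;
  best.gain = 0.0;
  best.feat = -1;
  best.thr = 0.0;

  const int n = (int)rows.size();
  double Gtot = 0.0, Htot = 0.0;
  for (int i = 0; i < n; ++i) {
    Gtot += g[rows[i]];
    Htot += h[rows[i]];
  }
  double parent_obj = leaf_objective(Gtot, Htot, lambda, alpha);

  std::vector<std::pair<double, int> > vals(n);
  for (size_t f = 0; f < feats.size(); ++f) {
    int j = feats[f];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(rows[i], j), rows[i]);
    std::sort(vals.begin(), vals.end());

    double GL = 0.0, HL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      GL += g[vals[i].second];
      HL += h[vals[i].second];
      if (vals[i].first == vals[i + 1].first) continue; // no split between ties
      double GR = Gtot - GL, HR = Htot - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double gain = leaf_objective(GL, HL, lambda, alpha) +
                    leaf_objective(GR, HR, lambda, alpha) -
                    parent_obj - gamma;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feat = j;
        best.thr = 0.5 * (vals[i].first + vals[i + 1].first);
        best.found = true;
      }
    }
  }
  return best;
}

static int grow_node(const NumericMatrix &X,
                     const std::vector<double> &g,
                     const std::vector<double> &h,
                     const std::vector<int> &rows,
                     const std::vector<int> &feats,
                     int depth, int max_depth,
                     double lambda, double alpha, double gamma, double eta,
                     double min_child_weight,
                     std::vector<TreeNode> &nodes) {
  double G = 0.0, H = 0.0;
  for (size_t i = 0; i < rows.size(); ++i) {
    G += g[rows[i]];
    H += h[rows[i]];
  }

  TreeNode nd;
  nd.feat = -1;
  nd.thr = 0.0;
  nd.left = nd.right = -1;
  nd.value = eta * leaf_weight(G, H, lambda, alpha);

  int idx = (int)nodes.size();
  nodes.push_back(nd);

  if (depth >= max_depth || rows.size() < 2) return idx;

  SplitResult sp = best_split(X, g, h, rows, feats, lambda, alpha, gamma,
                              min_child_weight);
  if (!sp.found) return idx;

  std::vector<int> lrows, rrows;
  for (size_t i = 0; i < rows.size(); ++i) {
    if (X(rows[i], sp.feat) <= sp.thr) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }
  if (lrows.empty() || rrows.empty()) return idx;

  int li = grow_node(X, g, h, lrows, feats, depth + 1, max_depth, lambda,
                     alpha, gamma, eta, min_child_weight, nodes);
  int ri = grow_node(X, g, h, rrows, feats, depth + 1, max_depth, lambda,
                     alpha, gamma, eta, min_child_weight, nodes);
  nodes[idx].feat = sp.feat;
  nodes[idx].thr = sp.thr;
  nodes[idx].left = li;
  nodes[idx].right = ri;
  return idx;
}

static double tree_predict_row(const std::vector<TreeNode> &nodes,
                               const NumericMatrix &X, int row) {
  int cur = 0;
  while (nodes[cur].feat >= 0) {
    cur = (X(row, nodes[cur].feat) <= nodes[cur].thr) ? nodes[cur].left
                                                      : nodes[cur].right;
  }
  return nodes[cur].value;
}

static List tree_to_list(const std::vector<TreeNode> &nodes) {
  int m = (int)nodes.size();
  IntegerVector feat(m), left(m), right(m);
  NumericVector thr(m), value(m);
  for (int i = 0; i < m; ++i) {
    feat[i] = nodes[i].feat;
    thr[i] = nodes[i].thr;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feat"] = feat, _["thr"] = thr, _["left"] = left,
                      _["right"] = right, _["value"] = value);
}

static std::vector<TreeNode> tree_from_list(const List &tl) {
  IntegerVector feat = tl["feat"], left = tl["left"], right = tl["right"];
  NumericVector thr = tl["thr"], value = tl["value"];
  std::vector<TreeNode> nodes(feat.size());
  for (int i = 0; i < feat.size(); ++i) {
    nodes[i].feat = feat[i];
    nodes[i].thr = thr[i];
    nodes[i].left = left[i];
    nodes[i].right = right[i];
    nodes[i].value = value[i];
  }
  return nodes;
}

// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int nrounds, double eta,
                 int max_depth, double min_child_weight, double subsample,
                 double colsample, double lambda, double alpha, double gamma,
                 double base_score) {
  const int n = X.nrow(), p = X.ncol();
  double base_margin = std::log(base_score / (1.0 - base_score));
  std::vector<double> F(n, base_margin), g(n), h(n);
  List trees(nrounds);

  int ncols = std::max(1, (int)std::ceil(colsample * p));

  for (int it = 0; it < nrounds; ++it) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }

    std::vector<int> rows;
    rows.reserve(n);
    if (subsample < 1.0) {
      for (int i = 0; i < n; ++i)
        if (unif_rand() < subsample) rows.push_back(i);
      if (rows.empty()) for (int i = 0; i < n; ++i) rows.push_back(i);
    } else {
      for (int i = 0; i < n; ++i) rows.push_back(i);
    }

    std::vector<int> feats;
    if (ncols < p) {
      // partial Fisher-Yates draw of ncols distinct features via R RNG
      std::vector<int> pool(p);
      for (int j = 0; j < p; ++j) pool[j] = j;
      for (int j = 0; j < ncols; ++j) {
        int k = j + (int)std::floor(unif_rand() * (p - j));
        if (k >= p) k = p - 1;
        std::swap(pool[j], pool[k]);
        feats.push_back(pool[j]);
      }
    } else {
      for (int j = 0; j < p; ++j) feats.push_back(j);
    }

    std::vector<TreeNode> nodes;
    grow_node(X, g, h, rows, feats, 0, max_depth, lambda, alpha, gamma, eta,
              min_child_weight, nodes);
    for (int i = 0; i < n; ++i) F[i] += tree_predict_row(nodes, X, i);
    trees[it] = tree_to_list(nodes);
  }

  return List::create(_["trees"] = trees, _["base_margin"] = base_margin);
}

// [[Rcpp::export]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  double base_margin = as<double>(model["base_margin"]);
  const int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    std::vector<TreeNode> nodes = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(nodes, X, i);
  }
  return out;
}
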
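// Minimal regression-tree ensemble engine backing the random-forest,
// gradient-boosting and XGBoost-style learners.
//
// A single gradient/hessian tree builder covers all three: with g = -y,
// h = 1, lambda = 0 a tree is an exact CART least-squares tree (used for
// bagged forests); boosting fits trees to (g = pred - y, h = 1), with the
// XGBoost variant adding leaf-weight regularisation lambda. Splits are
// exact greedy over sorted feature values; randomness (bootstrap, feature
// subsampling) comes from a seeded Mersenne Twister so fits are
// reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <random>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature = -1;      // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct BuildCfg {
  int max_depth;
  double min_child_weight;
  double lambda;
  int mtry;  // features sampled per split; <=0 means all
};

static double leaf_value(double G, double H, double lambda) {
  return -G / (H + lambda);
}

static void build_node(const NumericMatrix& X, const std::vector<double>& g,
                       const std::vector<double>& h,
                       std::vector<int>& rows, int depth, const BuildCfg& cfg,
                       std::vector<Node>& nodes, int node_id,
                       std::mt19937& rng) {
  const int p = X.ncol();
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  nodes[node_id].value = leaf_value(G, H, cfg.lambda);
  if (depth >= cfg.max_depth || (int)rows.size() < 2 ||
      H < 2.0 * cfg.min_child_weight)
    return;

  // candidate features
  std::vector<int> feats(p);
  std::iota(feats.begin(), feats.end(), 0);
  int n_feats = p;
  if (cfg.mtry > 0 && cfg.mtry < p) {
    std::shuffle(feats.begin(), feats.end(), rng);
    n_feats = cfg.mtry;
  }

  const double parent_score = G * G / (H + cfg.lambda);
  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int> > vals(rows.size());
  for (int f = 0; f < n_feats; ++f) {
    const int j = feats[f];
    for (size_t k = 0; k < rows.size(); ++k)
      vals[k] = std::make_pair(X(rows[k], j), rows[k]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    double GL = 0.0, HL = 0.0;
    for (size_t k = 0; k + 1 < vals.size(); ++k) {
      GL += g[vals[k].second];
      HL += h[vals[k].second];
      if (vals[k].first == vals[k + 1].first) continue;
      const double GR = G - GL, HR = H - HL;
      if (HL < cfg.min_child_weight || HR < cfg.min_child_weight) continue;
      const double gain = GL * GL / (HL + cfg.lambda) +
                          GR * GR / (HR + cfg.lambda) - parent_score;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  if (best_feat < 0) return;

  std::vector<int> left_rows, right_rows;
  for (int r : rows) {
    if (X(r, best_feat) <= best_thr) left_rows.push_back(r);
    else right_rows.push_back(r);
  }
  if (left_rows.empty() || right_rows.empty()) return;

  nodes[node_id].feature = best_feat;
  nodes[node_id].threshold = best_thr;
  nodes[node_id].left = (int)nodes.size();
  nodes.push_back(Node());
  nodes[node_id].right = (int)nodes.size();
  nodes.push_back(Node());
  build_node(X, g, h, left_rows, depth + 1, cfg, nodes,
             nodes[node_id].left, rng);
  build_node(X, g, h, right_rows, depth + 1, cfg, nodes,
             nodes[node_id].right, rng);
}

static NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

static double predict_tree(const NumericMatrix& tree, const NumericMatrix& X,
                           int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    node = (X(row, (int)tree(node, 0)) <= tree(node, 1))
               ? (int)tree(node, 2)
               : (int)tree(node, 3);
  }
  return tree(node, 4);
}

// [[Rcpp::export(name = ".fit_forest_cpp")]]
List fit_forest_cpp(NumericMatrix X, NumericVector y, int n_trees,
                    int max_depth, int min_node, int mtry, int seed) {
  const int n = X.nrow();
  std::mt19937 rng(seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  List trees(n_trees);
  BuildCfg cfg{max_depth, (double)min_node, 0.0, mtry};
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = pick(rng);  // bootstrap
    std::vector<double> g(n), h(n, 1.0);
    for (int i = 0; i < n; ++i) g[i] = -y[i];
    std::vector<Node> nodes(1);
    build_node(X, g, h, rows, 0, cfg, nodes, 0, rng);
    trees[t] = pack_tree(nodes);
  }
  return trees;
}

// [[Rcpp::export(name = ".fit_boosted_cpp")]]
List fit_boosted_cpp(NumericMatrix X, NumericVector y, int n_trees,
                     int max_depth, double learning_rate, double lambda,
                     double min_child_weight, double base_score, int seed) {
  const int n = X.nrow();
  std::mt19937 rng(seed);
  List trees(n_trees);
  std::vector<double> pred(n, base_score);
  BuildCfg cfg{max_depth, min_child_weight, lambda, 0};
  std::vector<int> rows(n);
  std::iota(rows.begin(), rows.end(), 0);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<double> g(n), h(n, 1.0);
    for (int i = 0; i < n; ++i) g[i] = pred[i] - y[i];
    std::vector<Node> nodes(1);
    build_node(X, g, h, rows, 0, cfg, nodes, 0, rng);
    NumericMatrix tree = pack_tree(nodes);
    for (int i = 0; i < n; ++i)
      pred[i] += learning_rate * predict_tree(tree, X, i);
    trees[t] = tree;
  }
  return trees;
}

// [[Rcpp::export(name = ".predict_ensemble_cpp")]]
NumericVector predict_ensemble_cpp(List trees, NumericMatrix X,
                                   double scale, double base_score) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += scale * predict_tree(tree, X, i);
  }
  return out;
}
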
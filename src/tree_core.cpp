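#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Shared exact-greedy binary tree builder used by the CART, random-forest
// and gradient-boosted-tree learners.
//
// criterion 0 (gini): g holds the 0/1 class indicator, h is ignored.
//   Node value is the class-1 proportion; split gain is the count-scaled
//   Gini impurity reduction  n*G(parent) - nL*G(L) - nR*G(R), and a split
//   is kept only when gain > min_gain (the R wrapper converts a cp into
//   this absolute scale).
// criterion 1 (grad): second-order boosting scan. g/h are per-row gradient
//   and hessian of the loss; leaf value is -G/(H+lambda); split gain is
//   0.5*(GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l)) - min_gain with min_gain
//   acting as the minimum-loss-reduction penalty (gamma).
//
// mtry > 0 draws that many candidate features per node through R's RNG so
// forests are reproducible under set.seed(). Ties in gain keep the first
// candidate in scan order.

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& g;
  const NumericVector& h;
  int criterion;
  double lambda, min_gain;
  int max_depth, min_node, mtry;

  std::vector<int> feature, left, right;
  std::vector<double> thr, value;
  std::vector<double> importance;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& g_,
              const NumericVector& h_, int crit, double lambda_,
              double min_gain_, int max_depth_, int min_node_, int mtry_)
      : X(X_), g(g_), h(h_), criterion(crit), lambda(lambda_),
        min_gain(min_gain_), max_depth(max_depth_), min_node(min_node_),
        mtry(mtry_), importance(X_.ncol(), 0.0) {}

  double leaf_value(double G, double H, int n) const {
    if (criterion == 0) return n > 0 ? G / n : 0.0;  // class-1 proportion
    return -G / (H + lambda);
  }

  double node_objective(double G, double H, int n) const {
    if (criterion == 0) {
      if (n == 0) return 0.0;
      double p = G / n;
      return n * 2.0 * p * (1.0 - p);  // count-scaled Gini (lower = purer)
    }
    return -0.5 * G * G / (H + lambda);  // boosting objective (lower better)
  }

  int build(std::vector<int>& rows, int depth) {
    int n = (int)rows.size();
    double G = 0.0, H = 0.0;
    for (int r : rows) { G += g[r]; H += h[r]; }

    int node = (int)feature.size();
    feature.push_back(-1);
    thr.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(leaf_value(G, H, n));

    bool pure = (criterion == 0) && (G <= 0.0 || G >= (double)n);
    if (depth >= max_depth || n < 2 * min_node || n < 2 || pure) return node;

    double parent_obj = node_objective(G, H, n);
    double best_gain = min_gain;
    int best_f = -1;
    double best_thr = 0.0;
    int d = X.ncol();

    std::vector<int> cand(d);
    for (int j = 0; j < d; ++j) cand[j] = j;
    if (mtry > 0 && mtry < d) {
      // partial Fisher-Yates through R's RNG for reproducibility
      for (int j = 0; j < mtry; ++j) {
        int k = j + (int)(unif_rand() * (d - j));
        if (k >= d) k = d - 1;
        std::swap(cand[j], cand[k]);
      }
      cand.resize(mtry);
    }

    std::vector<std::pair<double, int> > ord(n);
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int j = cand[ci];
      for (int i = 0; i < n; ++i) ord[i] = std::make_pair(X(rows[i], j), rows[i]);
      std::sort(ord.begin(), ord.end());
      double GL = 0.0, HL = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        GL += g[ord[i].second];
        HL += h[ord[i].second];
        if (ord[i].first == ord[i + 1].first) continue;
        int nL = i + 1, nR = n - nL;
        if (nL < min_node || nR < min_node) continue;
        double gain = parent_obj - node_objective(GL, HL, nL) -
                      node_objective(G - GL, H - HL, nR);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = j;
          best_thr = 0.5 * (ord[i].first + ord[i + 1].first);
        }
      }
    }

    if (best_f < 0) return node;

    std::vector<int> rl, rr;
    rl.reserve(n); rr.reserve(n);
    for (int r : rows) {
      if (X(r, best_f) <= best_thr) rl.push_back(r); else rr.push_back(r);
    }
    if (rl.empty() || rr.empty()) return node;  // numeric safety

    importance[best_f] += best_gain;
    feature[node] = best_f;
    thr[node] = best_thr;
    int l = build(rl, depth + 1);
    int r2 = build(rr, depth + 1);
    left[node] = l;
    right[node] = r2;
    return node;
  }
};

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, NumericVector g, NumericVector h,
                   IntegerVector rows, int criterion, double lambda,
                   double min_gain, int max_depth, int min_node, int mtry) {
  TreeBuilder tb(X, g, h, criterion, lambda, min_gain, max_depth, min_node,
                 mtry);
  std::vector<int> rv(rows.begin(), rows.end());
  tb.build(rv, 0);
  return List::create(
      _["feature"] = wrap(tb.feature), _["threshold"] = wrap(tb.thr),
      _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
      _["value"] = wrap(tb.value), _["importance"] = wrap(tb.importance));
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector thr = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
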
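#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Weighted least-squares CART used by the tree feature ranker, the random
// forest (bagged trees on 0/1 labels => leaf value is a class-1 fraction) and
// gradient boosting (trees on Newton pseudo-residuals with hessian weights).
// Splits maximize the weighted SSE reduction; a split is accepted only when
// the reduction exceeds min_gain (the boosting min_split_loss analogue).

struct CartNode {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // node indices, -1 for leaf
  double value;     // weighted mean of y in node
  double n;         // row count
};

struct Grower {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  int max_depth, min_split, min_leaf, mtry;
  double min_gain;
  std::mt19937 rng;
  std::vector<CartNode> nodes;
  std::vector<double> importance;

  Grower(const NumericMatrix& X_, const NumericVector& y_,
         const NumericVector& w_, int max_depth_, int min_split_,
         int min_leaf_, int mtry_, double min_gain_, unsigned seed)
      : X(X_), y(y_), w(w_), max_depth(max_depth_), min_split(min_split_),
        min_leaf(min_leaf_), mtry(mtry_), min_gain(min_gain_), rng(seed),
        importance(X_.ncol(), 0.0) {}

  int grow(std::vector<int>& idx, int depth) {
    double sw = 0, swy = 0, swyy = 0;
    for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; swyy += w[i] * y[i] * y[i]; }
    double mean = sw > 0 ? swy / sw : 0.0;
    double sse = swyy - (sw > 0 ? swy * swy / sw : 0.0);

    CartNode node{-1, 0.0, -1, -1, mean, (double)idx.size()};
    int me = (int)nodes.size();
    nodes.push_back(node);

    if (depth >= max_depth || (int)idx.size() < min_split || sse <= 1e-12)
      return me;

    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    if (m < p) std::shuffle(feats.begin(), feats.end(), rng);

    double best_gain = min_gain;
    int best_f = -1;
    double best_thr = 0.0;

    struct Cell { double x, wy, w, wyy; };
    std::vector<Cell> cells(idx.size());
    for (int fi = 0; fi < m; ++fi) {
      int j = feats[fi];
      for (size_t k = 0; k < idx.size(); ++k) {
        int i = idx[k];
        cells[k] = {X(i, j), w[i] * y[i], w[i], w[i] * y[i] * y[i]};
      }
      std::stable_sort(cells.begin(), cells.end(),
                       [](const Cell& a, const Cell& b) { return a.x < b.x; });
      double lw = 0, lwy = 0, lwyy = 0;
      for (size_t k = 0; k + 1 < cells.size(); ++k) {
        lw += cells[k].w; lwy += cells[k].wy; lwyy += cells[k].wyy;
        double xv = cells[k].x, xn = cells[k + 1].x;
        if (xv == xn) continue;
        int nl = (int)k + 1, nr = (int)cells.size() - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double rw = sw - lw, rwy = swy - lwy, rwyy = swyy - lwyy;
        if (lw <= 0 || rw <= 0) continue;
        double child_sse = (lwyy - lwy * lwy / lw) + (rwyy - rwy * rwy / rw);
        double gain = sse - child_sse;
        if (gain > best_gain) {
          best_gain = gain; best_f = j; best_thr = 0.5 * (xv + xn);
        }
      }
    }

    if (best_f < 0) return me;

    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    importance[best_f] += best_gain;
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = grow(li, depth + 1);
    nodes[me].left = l;
    int r = grow(ri, depth + 1);
    nodes[me].right = r;
    return me;
  }
};

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, NumericVector y, NumericVector w,
               int max_depth, int min_split, int min_leaf, int mtry,
               double min_gain, int seed) {
  Grower g(X, y, w, max_depth, min_split, min_leaf, mtry, min_gain,
           (unsigned)seed);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  g.grow(idx, 0);
  int nn = (int)g.nodes.size();
  IntegerVector feature(nn), left(nn), right(nn);
  NumericVector threshold(nn), value(nn), ncount(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = g.nodes[i].feature;
    threshold[i] = g.nodes[i].threshold;
    left[i] = g.nodes[i].left;
    right[i] = g.nodes[i].right;
    value[i] = g.nodes[i].value;
    ncount[i] = g.nodes[i].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["n"] = ncount,
                      _["importance"] = NumericVector(g.importance.begin(),
                                                      g.importance.end()));
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
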
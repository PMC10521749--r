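// Stochastic 2D layout of a fuzzy graph: per-edge attraction with
// epoch-scheduled sampling proportional to edge weight, plus uniform
// negative-sample repulsion, under the 1/(1 + a d^(2b)) kernel. Own
// mt19937 stream, so the layout is deterministic given the seed.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double clip4(double x) {
  return x > 4.0 ? 4.0 : (x < -4.0 ? -4.0 : x);
}

// [[Rcpp::export(name = ".umap_layout")]]
NumericMatrix umap_layout(NumericMatrix init, IntegerVector ei,
                          IntegerVector ej, NumericVector w,
                          int nEpochs, double a, double b,
                          double lr, int negPerEdge, int seed) {
  const int n = init.nrow(), m = ei.size();
  NumericMatrix Y = clone(init);
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  double wmax = 0.0;
  for (int e = 0; e < m; ++e) wmax = std::max(wmax, (double)w[e]);
  std::vector<double> eps(m), next(m);
  for (int e = 0; e < m; ++e) {
    eps[e] = wmax / std::max((double)w[e], 1e-12);
    next[e] = eps[e];
  }
  for (int epoch = 1; epoch <= nEpochs; ++epoch) {
    double alpha = lr * (1.0 - (double)(epoch - 1) / nEpochs);
    for (int e = 0; e < m; ++e) {
      if (next[e] > epoch) continue;
      next[e] += eps[e];
      int i = ei[e] - 1, j = ej[e] - 1;
      double dx = Y(i, 0) - Y(j, 0), dy = Y(i, 1) - Y(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 > 0) {
        double coef = (-2.0 * a * b * std::pow(d2, b - 1.0)) /
          (1.0 + a * std::pow(d2, b));
        double gx = clip4(coef * dx), gy = clip4(coef * dy);
        Y(i, 0) += alpha * gx; Y(i, 1) += alpha * gy;
        Y(j, 0) -= alpha * gx; Y(j, 1) -= alpha * gy;
      }
      for (int s = 0; s < negPerEdge; ++s) {
        int k = pick(rng);
        if (k == i) continue;
        double rx = Y(i, 0) - Y(k, 0), ry = Y(i, 1) - Y(k, 1);
        double r2 = rx * rx + ry * ry;
        double coef = (2.0 * b) /
          ((0.001 + r2) * (1.0 + a * std::pow(r2, b)));
        Y(i, 0) += alpha * clip4(coef * rx);
        Y(i, 1) += alpha * clip4(coef * ry);
      }
    }
  }
  return Y;
}
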
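// Stochastic-gradient layout optimisation of a 2D embedding against a fuzzy
// simplicial edge set (the UMAP objective): attractive moves along sampled
// edges, repulsive moves against negative samples, learning rate decaying
// linearly over epochs. Deterministic given `seed` (mt19937).
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static inline double clip4(double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

// [[Rcpp::export(name = ".umap_layout_cpp")]]
NumericMatrix umap_layout_cpp(NumericMatrix emb, IntegerVector head,
                              IntegerVector tail, NumericVector weight,
                              int n_epochs, double a, double b,
                              double initial_alpha, int neg_samples,
                              int seed) {
  int N = emb.nrow();
  int E = head.size();
  NumericMatrix y = clone(emb);
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, N - 1);
  double wmax = 0.0;
  for (int e = 0; e < E; ++e) wmax = std::max(wmax, weight[e]);
  std::vector<double> eps(E), next_sample(E), eps_neg(E), next_neg(E);
  for (int e = 0; e < E; ++e) {
    eps[e] = wmax / weight[e];  // sample high-weight edges every epoch
    next_sample[e] = eps[e];
    eps_neg[e] = eps[e] / neg_samples;
    next_neg[e] = eps_neg[e];
  }
  for (int n = 1; n <= n_epochs; ++n) {
    double alpha = initial_alpha * (1.0 - (double)(n - 1) / n_epochs);
    for (int e = 0; e < E; ++e) {
      if (next_sample[e] > n) continue;
      int i = head[e], j = tail[e];
      double dx = y(i, 0) - y(j, 0), dy = y(i, 1) - y(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 > 0.0) {
        double coef = -2.0 * a * b * std::pow(d2, b - 1.0) /
                      (1.0 + a * std::pow(d2, b));
        double gx = clip4(coef * dx) * alpha, gy = clip4(coef * dy) * alpha;
        y(i, 0) += gx;
        y(i, 1) += gy;
        y(j, 0) -= gx;
        y(j, 1) -= gy;
      }
      next_sample[e] += eps[e];
      int n_neg = (int)((n - next_neg[e]) / eps_neg[e]) + 1;
      for (int s = 0; s < n_neg; ++s) {
        int k = pick(rng);
        if (k == i) continue;
        double rx = y(i, 0) - y(k, 0), ry = y(i, 1) - y(k, 1);
        double r2 = rx * rx + ry * ry;
        double coef;
        if (r2 > 0.0)
          coef = 2.0 * b / ((0.001 + r2) * (1.0 + a * std::pow(r2, b)));
        else
          coef = 0.0;
        double gx = (coef > 0.0) ? clip4(coef * rx) : 4.0;
        double gy = (coef > 0.0) ? clip4(coef * ry) : 4.0;
        y(i, 0) += gx * alpha;
        y(i, 1) += gy * alpha;
      }
      next_neg[e] += n_neg * eps_neg[e];
    }
  }
  return y;
}
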
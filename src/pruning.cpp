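// Felsenstein pruning kernel. Builds per-edge transition matrices from the
// model's eigendecomposition, runs the postorder pruning pass per rate
// class, and returns the rate-class mixture likelihood per site pattern.

#include <Rcpp.h>
using namespace Rcpp;

// edge: nedge x 2 (parent, child), 1-based ape node ids, postorder.
// tip_partials: 4 x npat x ntip array (IUPAC masks).
// right, left: 4 x 4 eigenvector factors of Q (Q = right diag(vals) left).
// lengths: per-edge branch lengths; rates/weights: rate classes.
// Returns npat vector: sum_c w_c * sum_s pi_s * L_c(pattern | root state s).
// [[Rcpp::export]]
NumericVector mix_lik_cpp(IntegerMatrix edge, int ntip, int nnode,
                          NumericVector tip_partials, NumericMatrix right,
                          NumericMatrix left, NumericVector vals,
                          NumericVector lengths, NumericVector rates,
                          NumericVector weights, NumericVector pi, int root) {
  const int nedge = edge.nrow();
  const int npat = tip_partials.size() / (4 * ntip);
  const int ntot = ntip + nnode;
  const int ncls = rates.size();
  std::vector<double> part(4L * (size_t)npat * ntot);
  std::vector<double> P(16);
  NumericVector out(npat);

  for (int c = 0; c < ncls; ++c) {
    for (int v = ntip; v < ntot; ++v)
      std::fill(part.begin() + 4L * (size_t)npat * v,
                part.begin() + 4L * (size_t)npat * (v + 1), 1.0);
    for (int v = 0; v < ntip; ++v)
      std::copy(tip_partials.begin() + 4L * (size_t)npat * v,
                tip_partials.begin() + 4L * (size_t)npat * (v + 1),
                part.begin() + 4L * (size_t)npat * v);

    for (int e = 0; e < nedge; ++e) {
      const double t = lengths[e] * rates[c];
      // P = right * diag(exp(vals*t)) * left, clamped at 0
      double ev[4];
      for (int k = 0; k < 4; ++k) ev[k] = std::exp(vals[k] * t);
      for (int i = 0; i < 4; ++i) {
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += right(i, k) * ev[k] * left(k, j);
          P[i + 4 * j] = s > 0.0 ? s : 0.0;
        }
      }
      const int par = edge(e, 0) - 1, chi = edge(e, 1) - 1;
      const double *cp = &part[4L * (size_t)npat * chi];
      double *pp = &part[4L * (size_t)npat * par];
      for (int s = 0; s < npat; ++s) {
        const double c0 = cp[4 * s], c1 = cp[4 * s + 1],
                     c2 = cp[4 * s + 2], c3 = cp[4 * s + 3];
        for (int i = 0; i < 4; ++i) {
          pp[4 * s + i] *= P[i] * c0 + P[i + 4] * c1 +
                           P[i + 8] * c2 + P[i + 12] * c3;
        }
      }
    }

    const double *rp = &part[4L * (size_t)npat * (root - 1)];
    const double w = weights[c];
    for (int s = 0; s < npat; ++s) {
      out[s] += w * (pi[0] * rp[4 * s] + pi[1] * rp[4 * s + 1] +
                     pi[2] * rp[4 * s + 2] + pi[3] * rp[4 * s + 3]);
    }
  }
  return out;
}
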
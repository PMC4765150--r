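#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incidence list: for each node, the indices of its edges and whether the
// node is the first endpoint (rows of the 21x21 coupling are indexed by the
// state of the first endpoint; the second endpoint sees the transpose).
static std::vector<std::vector<std::pair<int, bool> > >
make_adjacency(const IntegerMatrix& edges, int L) {
  std::vector<std::vector<std::pair<int, bool> > > adj(L);
  for (int e = 0; e < edges.nrow(); ++e) {
    adj[edges(e, 0) - 1].push_back(std::make_pair(e, true));
    adj[edges(e, 1) - 1].push_back(std::make_pair(e, false));
  }
  return adj;
}

// Pseudo-log-likelihood sum_m sum_i log P(x_i | x_-i) and its gradient.
// v: L x K node weights; W: K x K x E couplings (column-major);
// edges: E x 2 (1-based, i < j); X: M x L states in 1..K.
// edge_visits counts coupling-term accesses (2*M*E): the objective cost is
// linear in the edge count at fixed M, which tests assert directly.
// [[Rcpp::export]]
List smrf_pll_grad(NumericMatrix v, NumericVector W, IntegerMatrix edges,
                   IntegerMatrix X) {
  const int L = v.nrow(), K = v.ncol();
  const int M = X.nrow();
  if (X.ncol() != L) stop("MSA width does not match model size");
  std::vector<std::vector<std::pair<int, bool> > > adj =
      make_adjacency(edges, L);
  NumericMatrix gv(L, K);
  NumericVector gW(W.size());
  const double* Wp = W.begin();
  double* gWp = gW.begin();
  double pll = 0.0, edge_visits = 0.0;
  std::vector<double> logits(K), p(K);

  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < L; ++i) {
      for (int k = 0; k < K; ++k) logits[k] = v(i, k);
      for (size_t t = 0; t < adj[i].size(); ++t) {
        const int e = adj[i][t].first;
        const bool first = adj[i][t].second;
        const int j = first ? edges(e, 1) - 1 : edges(e, 0) - 1;
        const int xj = X(m, j) - 1;
        const double* we = Wp + (size_t)e * K * K;
        if (first) {
          const double* col = we + (size_t)xj * K;  // w[k, xj]
          for (int k = 0; k < K; ++k) logits[k] += col[k];
        } else {
          for (int k = 0; k < K; ++k) logits[k] += we[(size_t)k * K + xj];
        }
        edge_visits += 1.0;
      }
      double mx = logits[0];
      for (int k = 1; k < K; ++k) if (logits[k] > mx) mx = logits[k];
      double Z = 0.0;
      for (int k = 0; k < K; ++k) { p[k] = std::exp(logits[k] - mx); Z += p[k]; }
      const int xi = X(m, i) - 1;
      pll += logits[xi] - (mx + std::log(Z));
      for (int k = 0; k < K; ++k) p[k] /= Z;
      for (int k = 0; k < K; ++k) gv(i, k) += (k == xi ? 1.0 : 0.0) - p[k];
      for (size_t t = 0; t < adj[i].size(); ++t) {
        const int e = adj[i][t].first;
        const bool first = adj[i][t].second;
        const int j = first ? edges(e, 1) - 1 : edges(e, 0) - 1;
        const int xj = X(m, j) - 1;
        double* ge = gWp + (size_t)e * K * K;
        if (first) {
          double* col = ge + (size_t)xj * K;
          for (int k = 0; k < K; ++k) col[k] += (k == xi ? 1.0 : 0.0) - p[k];
        } else {
          for (int k = 0; k < K; ++k)
            ge[(size_t)k * K + xj] += (k == xi ? 1.0 : 0.0) - p[k];
        }
      }
    }
  }
  gW.attr("dim") = IntegerVector::create(K, K, edges.nrow());
  return List::create(_["pll"] = pll, _["grad_v"] = gv, _["grad_w"] = gW,
                      _["edge_visits"] = edge_visits);
}

// Single-site Gibbs sampler over the joint MRF distribution.  One chain:
// uniform random start, `burn_in` full sweeps, then one row every `thin`
// sweeps.  Uses the R RNG, so set.seed() on the R side makes it reproducible.
// [[Rcpp::export]]
IntegerMatrix smrf_gibbs(NumericMatrix v, NumericVector W, IntegerMatrix edges,
                         int M, int burn_in, int thin) {
  const int L = v.nrow(), K = v.ncol();
  std::vector<std::vector<std::pair<int, bool> > > adj =
      make_adjacency(edges, L);
  const double* Wp = W.begin();
  std::vector<int> x(L);
  for (int i = 0; i < L; ++i) {
    int s = (int)std::floor(unif_rand() * K);
    x[i] = s >= K ? K - 1 : s;
  }
  std::vector<double> logits(K), p(K);
  IntegerMatrix out(M, L);

  // one full sweep of single-site updates in fixed order 1..L
  #define SMRF_SWEEP()                                                     \
    for (int i = 0; i < L; ++i) {                                          \
      for (int k = 0; k < K; ++k) logits[k] = v(i, k);                     \
      for (size_t t = 0; t < adj[i].size(); ++t) {                         \
        const int e = adj[i][t].first;                                     \
        const bool first = adj[i][t].second;                               \
        const int j = first ? edges(e, 1) - 1 : edges(e, 0) - 1;           \
        const int xj = x[j];                                               \
        const double* we = Wp + (size_t)e * K * K;                         \
        if (first) {                                                       \
          const double* col = we + (size_t)xj * K;                         \
          for (int k = 0; k < K; ++k) logits[k] += col[k];                 \
        } else {                                                           \
          for (int k = 0; k < K; ++k) logits[k] += we[(size_t)k * K + xj]; \
        }                                                                  \
      }                                                                    \
      double mx = logits[0];                                               \
      for (int k = 1; k < K; ++k) if (logits[k] > mx) mx = logits[k];      \
      double Z = 0.0;                                                      \
      for (int k = 0; k < K; ++k) {                                        \
        p[k] = std::exp(logits[k] - mx); Z += p[k];                        \
      }                                                                    \
      double u = unif_rand() * Z, acc = 0.0;                               \
      int pick = K - 1;                                                    \
      for (int k = 0; k < K; ++k) {                                        \
        acc += p[k];                                                       \
        if (u <= acc) { pick = k; break; }                                 \
      }                                                                    \
      x[i] = pick;                                                        \
    }

  for (int s = 0; s < burn_in; ++s) { SMRF_SWEEP(); }
  for (int m = 0; m < M; ++m) {
    for (int s = 0; s < thin; ++s) { SMRF_SWEEP(); }
    for (int i = 0; i < L; ++i) out(m, i) = x[i] + 1;
  }
  #undef SMRF_SWEEP
  return out;
}
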
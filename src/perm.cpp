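#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Monte-Carlo permutation engine for the rank-association statistic.
//
// For a gene with per-sample ranks r and a grouping with sizes n_k, the
// Kruskal-Wallis-type statistic is monotone in A = sum_k S_k^2 / n_k where
// S_k is the rank sum of group k (the total rank sum and sum of squares are
// permutation-invariant). So per permutation it is enough to accumulate
// group rank sums. Counts permutations with A >= A_observed (within a
// relative epsilon) for every row of `ranks` under a shared permutation
// stream, which is what a multiplicity-adjusted split search needs.
//
// ranks:  genes x samples matrix of within-gene ranks
// groups: 0-based group index per sample
// [[Rcpp::export]]
List cpp_perm_count(NumericMatrix ranks, IntegerVector groups, int n_perm,
                    int seed) {
  const int g = ranks.nrow();
  const int n = ranks.ncol();
  int K = 0;
  for (int i = 0; i < n; ++i) if (groups[i] + 1 > K) K = groups[i] + 1;
  std::vector<double> inv_nk(K, 0.0);
  {
    std::vector<int> nk(K, 0);
    for (int i = 0; i < n; ++i) nk[groups[i]]++;
    for (int k = 0; k < K; ++k) inv_nk[k] = nk[k] > 0 ? 1.0 / nk[k] : 0.0;
  }

  NumericVector obs(g);
  std::vector<double> eps(g);
  std::vector<double> S(K);
  for (int j = 0; j < g; ++j) {
    std::fill(S.begin(), S.end(), 0.0);
    for (int i = 0; i < n; ++i) S[groups[i]] += ranks(j, i);
    double a = 0.0;
    for (int k = 0; k < K; ++k) a += S[k] * S[k] * inv_nk[k];
    obs[j] = a;
    eps[j] = 1e-9 * (1.0 + std::fabs(a));
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  IntegerVector count(g, 0);

  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
      std::uniform_int_distribution<int> u(0, i);
      std::swap(perm[i], perm[u(rng)]);
    }
    for (int j = 0; j < g; ++j) {
      std::fill(S.begin(), S.end(), 0.0);
      for (int i = 0; i < n; ++i) S[groups[i]] += ranks(j, perm[i]);
      double a = 0.0;
      for (int k = 0; k < K; ++k) a += S[k] * S[k] * inv_nk[k];
      if (a >= obs[j] - eps[j]) count[j]++;
    }
  }
  return List::create(_["count"] = count, _["obs"] = obs);
}
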
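#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Weighted sampling without replacement via exponent keys: for each gene draw
// u ~ U(0,1) and form key = u^(1/m_i); the N largest keys are selected. We
// work with log(u)/m_i, which preserves the key order. Ties (measure zero)
// fall back to universe order because std::stable_sort keeps index order.
//
// Uses R's RNG stream (RNGScope) so draws are reproducible under set.seed();
// uniforms are consumed row-major: draw b = 0..B-1, gene i = 0..n-1.

// [[Rcpp::export]]
IntegerMatrix cpp_weighted_draws(NumericVector m, int N, int B) {
  const int n = m.size();
  if (N < 1 || N > n) stop("N must be in [1, n]");
  if (B < 1) stop("B must be >= 1");
  for (int i = 0; i < n; ++i) {
    if (m[i] <= 0.0 || m[i] >= 1.0)
      stop("all mutation rates must lie strictly in (0, 1)");
  }
  RNGScope scope;
  IntegerMatrix out(B, N);
  std::vector<double> key(n);
  std::vector<int> idx(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) key[i] = std::log(unif_rand()) / m[i];
    std::iota(idx.begin(), idx.end(), 0);
    std::partial_sort(idx.begin(), idx.begin() + N, idx.end(),
                      [&](int a, int c) {
                        if (key[a] != key[c]) return key[a] > key[c];
                        return a < c;
                      });
    for (int j = 0; j < N; ++j) out(b, j) = idx[j] + 1;  // 1-based
  }
  return out;
}

// Uniform N-subsets of {1..n} by partial Fisher-Yates, one row per draw.
// Same RNG contract as cpp_weighted_draws.

// [[Rcpp::export]]
IntegerMatrix cpp_regular_draws(int n, int N, int B) {
  if (N < 1 || N > n) stop("N must be in [1, n]");
  if (B < 1) stop("B must be >= 1");
  RNGScope scope;
  IntegerMatrix out(B, N);
  std::vector<int> pool(n);
  for (int b = 0; b < B; ++b) {
    std::iota(pool.begin(), pool.end(), 1);
    for (int j = 0; j < N; ++j) {
      int pick = j + static_cast<int>(unif_rand() * (n - j));
      if (pick >= n) pick = n - 1;  // guard against unif_rand() == 1
      std::swap(pool[j], pool[pick]);
      out(b, j) = pool[j];
    }
  }
  return out;
}

// Per-draw overlap counts with a membership indicator over the universe:
// counts[b] = #{ j : member[draws(b, j)] }.

// [[Rcpp::export]]
IntegerVector cpp_overlap_counts(IntegerMatrix draws, LogicalVector member) {
  const int B = draws.nrow(), N = draws.ncol();
  IntegerVector counts(B);
  for (int b = 0; b < B; ++b) {
    int k = 0;
    for (int j = 0; j < N; ++j)
      if (member[draws(b, j) - 1]) ++k;
    counts[b] = k;
  }
  return counts;
}
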
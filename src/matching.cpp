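#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact maximum-weight matching on a small dense graph by dynamic
// programming over vertex subsets. W is a symmetric n x n matrix of
// non-negative edge weights with NA marking absent edges. Returns the
// 1-based partner of each vertex (0 = unmatched). Ties are broken
// deterministically: the lowest-indexed vertex is matched to the smallest
// partner attaining the optimum, and matching is preferred over leaving a
// vertex free when the totals tie.
// [[Rcpp::export]]
IntegerVector maxWeightMatchingDP(NumericMatrix W) {
  const int n = W.nrow();
  if (n != W.ncol()) stop("weight matrix must be square");
  if (n > 22) stop("exact matching supports at most 22 vertices");
  IntegerVector match(n, 0);
  if (n < 2) return match;
  const size_t full = (size_t(1) << n);
  std::vector<double> dp(full, 0.0);
  const double eps = 1e-9;
  for (size_t mask = 1; mask < full; ++mask) {
    int i = 0;
    while (!((mask >> i) & 1)) ++i;
    const size_t rest = mask & ~(size_t(1) << i);
    double best = dp[rest]; // leave i unmatched
    for (int j = i + 1; j < n; ++j) {
      if (!((mask >> j) & 1)) continue;
      const double w = W(i, j);
      if (NumericVector::is_na(w)) continue;
      const double cand = w + dp[rest & ~(size_t(1) << j)];
      if (cand > best) best = cand;
    }
    dp[mask] = best;
  }
  size_t mask = full - 1;
  while (mask) {
    int i = 0;
    while (!((mask >> i) & 1)) ++i;
    const size_t rest = mask & ~(size_t(1) << i);
    const double target = dp[mask];
    int chosen = -1;
    for (int j = i + 1; j < n; ++j) {
      if (!((mask >> j) & 1)) continue;
      const double w = W(i, j);
      if (NumericVector::is_na(w)) continue;
      if (w + dp[rest & ~(size_t(1) << j)] >= target - eps) { chosen = j; break; }
    }
    if (chosen >= 0) {
      match[i] = chosen + 1;
      match[chosen] = i + 1;
      mask = rest & ~(size_t(1) << chosen);
    } else {
      mask = rest;
    }
  }
  return match;
}
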
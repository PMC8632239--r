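#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Monte-Carlo permutation p-value for the Kruskal-Wallis statistic. Ranks are
// computed once in R (midranks for ties) and shuffled here; with ranks fixed,
// the tie-correction factor is a constant, so comparing the uncorrected
// between-group rank-sum statistic is equivalent to comparing H itself.
// Uses R's RNG, so set.seed() in R controls reproducibility.
// [[Rcpp::export(name = ".cpp_kw_perm")]]
double cpp_kw_perm(NumericVector ranks, IntegerVector group, int k, int nperm, double obs_stat) {
  int n = ranks.size();
  std::vector<double> r(ranks.begin(), ranks.end());
  std::vector<int> gsize(k, 0);
  for (int i = 0; i < n; ++i) gsize[group[i] - 1]++;
  std::vector<double> rs(k);

  auto stat = [&](const std::vector<double>& rr, const IntegerVector& gg) {
    std::fill(rs.begin(), rs.end(), 0.0);
    for (int i = 0; i < n; ++i) rs[gg[i] - 1] += rr[i];
    double s = 0;
    for (int g = 0; g < k; ++g) s += rs[g] * rs[g] / gsize[g];
    return s;
  };

  RNGScope scope;
  int hits = 0;
  const double eps = 1e-9;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle of the rank vector
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(r[i], r[j]);
    }
    if (stat(r, group) >= obs_stat - eps) ++hits;
  }
  return (hits + 1.0) / (nperm + 1.0);
}
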
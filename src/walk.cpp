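#include <Rcpp.h>
using namespace Rcpp;

// Weighted KS-like random-walk enrichment scores for K gene sets in n samples.
//
// ord:        p x n integer matrix; ord(l, j) is the 1-based gene index at
//             rank l (descending kernel-CDF rank) in sample j.
// rstat:      p x n numeric matrix of symmetric rank statistics |p/2 - rank|,
//             indexed by gene (not by rank).
// membership: p x K logical matrix, by gene index.
// tau:        exponent on the rank statistic in the inside-set increment.
// variant:    0 = max-deviation (signed value at the argmax of |nu|),
//             1 = diff-of-extremes (max(nu, 0) + min(nu, 0)).
//
// The walk nu must return to 0 at l = p (both normalized sums reach 1);
// this is asserted to numerical tolerance for every (set, sample).
// [[Rcpp::export]]
NumericMatrix es_walk_batch(IntegerMatrix ord, NumericMatrix rstat,
                            LogicalMatrix membership, double tau,
                            int variant) {
  const int p = ord.nrow();
  const int n = ord.ncol();
  const int K = membership.ncol();
  if (rstat.nrow() != p || rstat.ncol() != n)
    stop("rank statistic matrix does not match the rank order matrix");
  if (membership.nrow() != p)
    stop("membership matrix does not match the gene universe");

  NumericMatrix es(K, n);
  std::vector<double> w(p);
  std::vector<int> genes(p);

  for (int j = 0; j < n; ++j) {
    for (int l = 0; l < p; ++l) {
      int g = ord(l, j) - 1;
      if (g < 0 || g >= p) stop("rank order index out of range");
      genes[l] = g;
      w[l] = (tau == 1.0) ? rstat(g, j) : std::pow(rstat(g, j), tau);
    }
    for (int k = 0; k < K; ++k) {
      double sumw = 0.0;
      int m = 0;
      for (int l = 0; l < p; ++l) {
        if (membership(genes[l], k)) { sumw += w[l]; ++m; }
      }
      if (m == 0) stop("gene set %d has no genes in the universe", k + 1);
      if (m == p) stop("gene set %d covers the whole universe (degenerate complement)", k + 1);
      // all member rank weights zero (e.g. a singleton at the exact
      // mid-rank): fall back to uniform inside weights so the walk still
      // closes at zero
      const bool uniform = (sumw <= 0.0);
      const double dec = 1.0 / (double)(p - m);
      const double inc_uniform = 1.0 / (double)m;
      double nu = 0.0, best = 0.0, absbest = 0.0, vmax = 0.0, vmin = 0.0;
      for (int l = 0; l < p; ++l) {
        if (membership(genes[l], k))
          nu += uniform ? inc_uniform : w[l] / sumw;
        else nu -= dec;
        double a = std::fabs(nu);
        if (a > absbest) { absbest = a; best = nu; }
        if (nu > vmax) vmax = nu;
        if (nu < vmin) vmin = nu;
      }
      if (std::fabs(nu) > 1e-8)
        stop("random walk failed to return to zero (residual %g)", nu);
      es(k, j) = (variant == 0) ? best : (vmax + vmin);
    }
  }
  return es;
}
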
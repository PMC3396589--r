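#include <Rcpp.h>
using namespace Rcpp;

// Exact-test p-value for a contingency table with fixed margins, estimated by
// the Guo & Thompson Markov chain over tables: pick two rows and two columns,
// rotate the 2x2 subtable by +/-1, accept by the Metropolis rule with the
// multivariate hypergeometric stationary distribution (prob proportional to
// 1/prod(x_ij!)). The p-value is the stationary probability of tables whose
// probability is <= that of the observed table. Uses R's RNG, so set.seed()
// makes the chain reproducible.
//
// Returns c(p, n_le, se): add-one estimate (1 + #{steps with logP <=
// logP_obs}) / (steps + 1), the raw count, and a batch-means Monte-Carlo
// standard error (20 batches) that accounts for chain autocorrelation.
// [[Rcpp::export(name = ".ld_mcmc_chain")]]
NumericVector ld_mcmc_chain(IntegerMatrix table, int steps, int burnin) {
  int r = table.nrow(), c = table.ncol();
  IntegerMatrix x = clone(table);
  const int n_batch = 20;
  int batch_len = steps / n_batch > 0 ? steps / n_batch : 1;
  std::vector<double> batch_hits;
  int cur_batch_hits = 0, in_batch = 0;

  auto logp = [&](IntegerMatrix& m) {
    double s = 0.0;
    for (int i = 0; i < r; ++i)
      for (int j = 0; j < c; ++j) s -= lgamma(m(i, j) + 1.0);
    return s;
  };
  double lp_obs = logp(x);
  double lp_cur = lp_obs;
  double tol = 1e-9 * (1.0 + fabs(lp_obs));

  int n_le = 0;
  for (int t = 0; t < burnin + steps; ++t) {
    int i = (int)(unif_rand() * r), j = (int)(unif_rand() * r);
    while (j == i) j = (int)(unif_rand() * r);
    int k = (int)(unif_rand() * c), l = (int)(unif_rand() * c);
    while (l == k) l = (int)(unif_rand() * c);
    int d = unif_rand() < 0.5 ? 1 : -1;
    int a = x(i, k) + d, b = x(i, l) - d, e = x(j, k) - d, f = x(j, l) + d;
    if (a >= 0 && b >= 0 && e >= 0 && f >= 0) {
      double delta =
        lgamma(x(i, k) + 1.0) + lgamma(x(i, l) + 1.0) +
        lgamma(x(j, k) + 1.0) + lgamma(x(j, l) + 1.0) -
        lgamma(a + 1.0) - lgamma(b + 1.0) - lgamma(e + 1.0) - lgamma(f + 1.0);
      if (delta >= 0 || log(unif_rand()) < delta) {
        x(i, k) = a; x(i, l) = b; x(j, k) = e; x(j, l) = f;
        lp_cur += delta;
      }
    }
    if (t >= burnin) {
      bool le = lp_cur <= lp_obs + tol;
      if (le) ++n_le;
      if (le) ++cur_batch_hits;
      if (++in_batch == batch_len) {
        batch_hits.push_back((double)cur_batch_hits / batch_len);
        cur_batch_hits = 0; in_batch = 0;
      }
    }
  }
  double p = (1.0 + n_le) / (steps + 1.0);
  double se = NA_REAL;
  int B = batch_hits.size();
  if (B >= 2) {
    double m = 0.0;
    for (double b : batch_hits) m += b;
    m /= B;
    double v = 0.0;
    for (double b : batch_hits) v += (b - m) * (b - m);
    v /= (B - 1);
    se = sqrt(v / B);
  }
  return NumericVector::create(p, (double)n_le, se);
}
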
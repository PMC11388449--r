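#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis sampler over protonation microstates, one independent chain
// per pH point. Energies are in pK units: G = sum_i s_i (pH - pkint_i)
// + sum_{i<j} w_ij q_i q_j, acceptance exp(-ln10 * dG). One "step" is a
// random-scan sweep of n proposals. Per-site interaction fields
// h_i = sum_j w_ij q_j are cached and updated incrementally on accepted
// flips, so a proposal costs O(1) and an accepted flip O(n).
//
// Uses R's RNG so set.seed() in the calling R code fixes the trajectory.
// partner[i] (0-based) is site i's most strongly coupled partner; pair
// moves flip i and partner[i] together when has_partner[i] is true.
// [[Rcpp::export]]
List mc_titrate_cpp(NumericVector pkint, IntegerVector anionic,
                    NumericMatrix w, NumericVector ph_points,
                    int sweeps, int burn_in, double pair_frac,
                    IntegerVector partner, IntegerVector has_partner,
                    int n_batches) {
  const int n = pkint.size();
  const int nph = ph_points.size();
  const double LN10 = std::log(10.0);
  if (n_batches < 2) n_batches = 2;
  const int kept = sweeps - burn_in;
  if (n_batches > kept) n_batches = kept;

  NumericMatrix prot(nph, n), se(nph, n);
  std::vector<int> s(n);
  std::vector<double> q(n), h(n);
  std::vector<double> batch_sum((size_t)n_batches * n);
  const int batch_len = kept / n_batches; // remainder folds into last batch

  RNGScope scope;
  for (int p = 0; p < nph; ++p) {
    const double ph = ph_points[p];
    // start all-deprotonated; burn-in discards the transient
    for (int i = 0; i < n; ++i) {
      s[i] = 0;
      q[i] = -(double)anionic[i];
    }
    for (int i = 0; i < n; ++i) {
      double hi = 0.0;
      for (int j = 0; j < n; ++j) hi += w(i, j) * q[j]; // w(i,i)=0
      h[i] = hi;
    }
    std::fill(batch_sum.begin(), batch_sum.end(), 0.0);

    for (int t = 0; t < sweeps; ++t) {
      for (int rep = 0; rep < n; ++rep) {
        int i = (int)(unif_rand() * n);
        if (i == n) i = n - 1;
        const bool pair = pair_frac > 0.0 && has_partner[i] &&
                          unif_rand() < pair_frac;
        const double ds_i = 1.0 - 2.0 * s[i];
        double dG = ds_i * (ph - pkint[i] + h[i]);
        int j2 = -1;
        double ds_j = 0.0;
        if (pair) {
          j2 = partner[i];
          ds_j = 1.0 - 2.0 * s[j2];
          // site i's charge has already moved by ds_i when j2 flips
          dG += ds_j * (ph - pkint[j2] + h[j2] + w(j2, i) * ds_i);
        }
        if (dG <= 0.0 || unif_rand() < std::exp(-LN10 * dG)) {
          s[i] += (int)ds_i;
          q[i] += ds_i;
          for (int k = 0; k < n; ++k) h[k] += w(k, i) * ds_i;
          if (pair) {
            s[j2] += (int)ds_j;
            q[j2] += ds_j;
            for (int k = 0; k < n; ++k) h[k] += w(k, j2) * ds_j;
          }
        }
      }
      const int t_kept = t - burn_in;
      if (t_kept >= 0) {
        int b = t_kept / batch_len;
        if (b >= n_batches) b = n_batches - 1;
        double* bs = &batch_sum[(size_t)b * n];
        for (int k = 0; k < n; ++k) bs[k] += s[k];
      }
    }
    // per-site mean and batch-mean standard error
    for (int k = 0; k < n; ++k) {
      double tot = 0.0;
      for (int b = 0; b < n_batches; ++b)
        tot += batch_sum[(size_t)b * n + k];
      const double mean = tot / kept;
      prot(p, k) = mean;
      double ss = 0.0;
      for (int b = 0; b < n_batches; ++b) {
        int len = (b == n_batches - 1) ? kept - batch_len * (n_batches - 1)
                                       : batch_len;
        double bm = batch_sum[(size_t)b * n + k] / len;
        ss += (bm - mean) * (bm - mean);
      }
      se(p, k) = std::sqrt(ss / (n_batches - 1.0) / n_batches);
    }
  }
  return List::create(_["protonation"] = prot, _["se"] = se);
}
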
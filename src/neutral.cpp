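#include <Rcpp.h>
using namespace Rcpp;

// Hubbell death-replacement kernel for one local community.
//
// `community` holds the taxon index (0-based) of each of the N individuals.
// Per step one uniformly chosen individual dies; with probability m the
// replacement is an immigrant drawn from the metacommunity (cumulative
// relative abundances in `cum_meta`), otherwise it is the offspring of an
// individual sampled uniformly from the community at the moment of death.
// Uses R's RNG, so set.seed() on the R side makes runs reproducible.
//
// [[Rcpp::export]]
IntegerVector neutral_moran_steps(IntegerVector community, NumericVector cum_meta,
                                  double m, double steps) {
  IntegerVector comm = clone(community);
  const int N = comm.size();
  const int K = cum_meta.size();
  const long long nstep = (long long) steps;
  for (long long t = 0; t < nstep; ++t) {
    int die = (int)(unif_rand() * N);
    if (die >= N) die = N - 1;
    int newtax;
    if (unif_rand() < m) {
      double u = unif_rand();
      int lo = 0, hi = K - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum_meta[mid] < u) lo = mid + 1; else hi = mid;
      }
      newtax = lo;
    } else {
      int src = (int)(unif_rand() * N);
      if (src >= N) src = N - 1;
      newtax = comm[src];
    }
    comm[die] = newtax;
  }
  return comm;
}
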
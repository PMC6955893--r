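#include <Rcpp.h>
using namespace Rcpp;

// Moran death/replacement chain over a vector of individuals.
//
// ind holds one entry per individual (taxon index, 1-based); each step one
// uniformly chosen individual dies and is replaced, with probability m by a
// draw from the metacommunity (cumulative relative abundances cum_p) and
// otherwise by the offspring of a uniformly chosen local individual.
// Uses R's RNG so results are reproducible under set.seed().
//
// [[Rcpp::export]]
IntegerVector moran_chain(IntegerVector ind, NumericVector cum_p,
                          double m, double steps) {
  int n = ind.size();
  int S = cum_p.size();
  IntegerVector out = clone(ind);
  for (double t = 0; t < steps; ++t) {
    int die = (int)(unif_rand() * n);
    if (die >= n) die = n - 1;
    int newtax;
    if (unif_rand() < m) {
      double u = unif_rand();
      int lo = 0, hi = S - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum_p[mid] < u) lo = mid + 1; else hi = mid;
      }
      newtax = lo + 1;
    } else {
      int src = (int)(unif_rand() * n);
      if (src >= n) src = n - 1;
      newtax = out[src];
    }
    out[die] = newtax;
  }
  return out;
}
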
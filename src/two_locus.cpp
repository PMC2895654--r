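#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Two-locus coalescent with recombination for n haploid samples (n <= 64),
// the Monte-Carlo engine behind the composite-likelihood lookup table.
// One mutation per locus is placed uniformly on that locus's marginal tree
// (the standard theta -> 0 conditioning on segregation), and the resulting
// folded-ready haplotype configuration (n00, n01, n10, n11) is recorded.
//
// Lineages carry descendant bitmasks at each locus (0 = not ancestral).
// Events: pairwise coalescence at rate k(k-1)/2, recombination at rate
// rho/2 per lineage ancestral at both loci. A locus is retired when a
// single lineage carries all samples there. Uniform placement on each
// marginal tree uses weighted reservoir sampling over branch exposure, so
// no genealogy needs to be stored.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// [[Rcpp::export]]
IntegerMatrix cpp_two_locus_configs(int n, double rho, int n_sims) {
  if (n < 4 || n > 64) stop("n must be in 4..64");
  if (rho < 0) stop("rho must be >= 0");
  IntegerMatrix out(n_sims, 4);
  const uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);
  std::vector<uint64_t> seta, setb;
  for (int s = 0; s < n_sims; ++s) {
    seta.assign(n, 0); setb.assign(n, 0);
    for (int i = 0; i < n; ++i) { seta[i] = setb[i] = (1ULL << i); }
    bool done_a = false, done_b = false;
    double la = 0.0, lb = 0.0;      // accumulated tree length per locus
    uint64_t mut_a = 0, mut_b = 0;  // reservoir-sampled mutation carriers
    while (!(done_a && done_b)) {
      int k = (int)seta.size();
      if (k < 2 && !(done_a && done_b)) {
        // lone lineage can only remain if both loci retired; guard anyway
        break;
      }
      int kab = 0;
      for (int i = 0; i < k; ++i) if (seta[i] && setb[i]) ++kab;
      double rate_c = 0.5 * k * (k - 1);
      double rate_r = 0.5 * rho * kab;
      double tot = rate_c + rate_r;
      double dt = R::exp_rand() / tot;
      // branch exposure + weighted reservoir update per locus
      for (int i = 0; i < k; ++i) {
        if (!done_a && seta[i]) {
          la += dt;
          if (R::unif_rand() < dt / la) mut_a = seta[i];
        }
        if (!done_b && setb[i]) {
          lb += dt;
          if (R::unif_rand() < dt / lb) mut_b = setb[i];
        }
      }
      if (R::unif_rand() < rate_r / tot) {
        // recombination: split a random double-locus lineage
        int pick = (int)(R::unif_rand() * kab);
        if (pick >= kab) pick = kab - 1;
        int idx = -1;
        for (int i = 0; i < k; ++i) {
          if (seta[i] && setb[i] && ++idx == pick) { idx = i; break; }
        }
        uint64_t b = setb[idx];
        setb[idx] = 0;
        seta.push_back(0); setb.push_back(b);
      } else {
        // coalescence of a random pair
        int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        int lo = i < j ? i : j, hi = i < j ? j : i;
        seta[lo] |= seta[hi]; setb[lo] |= setb[hi];
        seta.erase(seta.begin() + hi); setb.erase(setb.begin() + hi);
        if (!done_a && seta[lo] == full) { done_a = true; seta[lo] = 0; }
        if (!done_b && setb[lo] == full) { done_b = true; setb[lo] = 0; }
        if (seta[lo] == 0 && setb[lo] == 0) {
          seta.erase(seta.begin() + lo); setb.erase(setb.begin() + lo);
        }
      }
    }
    int n11 = popcount64(mut_a & mut_b);
    int n10 = popcount64(mut_a) - n11;
    int n01 = popcount64(mut_b) - n11;
    int n00 = n - n11 - n10 - n01;
    out(s, 0) = n00; out(s, 1) = n01; out(s, 2) = n10; out(s, 3) = n11;
  }
  return out;
}
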
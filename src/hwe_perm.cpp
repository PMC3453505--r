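#include <Rcpp.h>
using namespace Rcpp;

// Heterozygote counts under random re-pairing of the allele pool.
//
// The pool holds n_a copies of allele A and n_b copies of allele B
// (n_a + n_b = 2N, N diploid samples).  Each permutation shuffles the
// pool with Fisher-Yates (driven by R's RNG so set.seed() controls it)
// and pairs consecutive alleles; the statistic returned is the number
// of heterozygous pairs.
// [[Rcpp::export]]
IntegerVector hwe_perm_het(int n_a, int n_b, int n_perm) {
  if (n_a < 0 || n_b < 0 || n_perm < 1)
    stop("invalid allele counts or permutation count");
  const int total = n_a + n_b;
  if (total % 2 != 0) stop("allele pool size must be even");
  const int n_pairs = total / 2;
  std::vector<int> pool(total, 0);
  for (int i = 0; i < n_b; ++i) pool[i] = 1;
  IntegerVector het(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = total - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;  // guard against unif_rand() == 1.0
      std::swap(pool[i], pool[j]);
    }
    int h = 0;
    for (int k = 0; k < n_pairs; ++k)
      if (pool[2 * k] != pool[2 * k + 1]) ++h;
    het[p] = h;
  }
  return het;
}
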
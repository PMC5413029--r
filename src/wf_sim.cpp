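#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Forward Wright-Fisher simulation of 2N haplotypes on one linear
// chromosome. Discrete generations; each offspring haplotype is a
// recombinant of one random parent's two haplotypes with a
// Poisson(morgans) crossover count at uniform map positions (no
// interference). Optional symmetric per-site mutation. Uses R's RNG so
// results are reproducible under set.seed().
//
// Returns the final-generation haplotype matrix (2N x L, 0/1 alleles).
// [[Rcpp::export]]
IntegerMatrix wf_sim_cpp(int N, int generations, int L, double morgans,
                         double mutation_rate) {
  if (N < 2 || L < 1) stop("need N >= 2 and L >= 1");
  int H = 2 * N;
  IntegerMatrix cur(H, L), nxt(H, L);

  // founder generation: per-SNP frequency U(0.05, 0.95), linkage equilibrium
  std::vector<double> p(L), pos(L);
  for (int j = 0; j < L; j++) {
    p[j] = R::runif(0.05, 0.95);
    pos[j] = morgans * (j + 0.5) / L;   // SNPs evenly spaced in map distance
  }
  for (int i = 0; i < H; i++)
    for (int j = 0; j < L; j++)
      cur(i, j) = (R::unif_rand() < p[j]) ? 1 : 0;

  std::vector<double> xo;
  for (int g = 0; g < generations; g++) {
    for (int h = 0; h < H; h++) {
      int parent = (int)(R::unif_rand() * N);
      if (parent >= N) parent = N - 1;
      int a = 2 * parent, b = a + 1;
      int k = (int)R::rpois(morgans);
      xo.clear();
      for (int c = 0; c < k; c++) xo.push_back(R::runif(0.0, morgans));
      std::sort(xo.begin(), xo.end());
      int phase = (R::unif_rand() < 0.5) ? 0 : 1;
      size_t ci = 0;
      for (int j = 0; j < L; j++) {
        while (ci < xo.size() && xo[ci] < pos[j]) { phase ^= 1; ci++; }
        int allele = phase ? cur(b, j) : cur(a, j);
        if (mutation_rate > 0 && R::unif_rand() < mutation_rate)
          allele ^= 1;
        nxt(h, j) = allele;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
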
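---
title: "Methods and design notes for divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`divscan` quantifies genetic diversity and selection history in
multi-breed SNP-array cohorts — the kind of data produced by
medium-density livestock panels such as the ovine 50K chip. This
vignette explains the statistical machinery stage by stage, states every
tunable parameter with its default and rationale, and records the design
decisions made where conventions genuinely diverge.

## The cohort model

All stages share one container: a dosage matrix (individuals x SNPs,
codes 0/1/2/NA counting copies of the cohort-wide minor allele), a SNP
map with physical (bp, 1-based inclusive) and optional genetic (cM)
coordinates, per-animal breed labels, and an optional pedigree. The
counted allele is fixed at read time because every downstream statistic
(F\_ST, r², homozygosity) is invariant to allele labelling; freezing it
prevents subtle per-breed relabelling inconsistencies. Minor-allele
frequencies are computed from integer allele counts rather than ratios
of means so that the result is *exactly* symmetric under allele
relabelling — a knife-edge MAF otherwise lands on different sides of a
strict threshold depending on which allele is counted.

## Quality control

Filters run in a fixed order, each on the survivors of the previous
one: individual call rate (>= 0.95), SNP call rate (>= 0.95, computed on
retained individuals), autosome restriction, MAF (>= 0.01, strict `<`
removal so a SNP exactly at the threshold survives), and a within-breed
Hardy–Weinberg exact test (discard when p < 1e-7 in *any* single
breed). Re-running the chain on its own output is a no-op, which the
test suite asserts.

The HWE test is the exact conditional test: given the observed allele
counts, the heterozygote count is distributed as a doubled
hypergeometric under the null, and the two-sided p-value sums the
probabilities of all heterozygote counts no more probable than the
observed one. Probabilities are built with the stable ratio recurrence;
no mid-p correction is applied. The test suite checks *every* genotype
table on up to 30 alleles against a log-factorial enumeration oracle.

LD pruning (for structure-sensitive analyses) slides a 50-SNP block one
SNP at a time; in each block, any pair with genotype-correlation
r² > 0.1 marks its *later* (higher-bp) member for removal — a
deterministic tie-break. Passes repeat until no within-block pair of
the survivors exceeds the threshold, so the output is a stable set.
Missing genotypes are pairwise-deleted in the correlations.

## Runs of homozygosity

The scan follows the sliding-window genotype logic of standard array
ROH callers:

1. every 50-SNP window is *compliant* if it has at most 1 heterozygous
   and at most 2 missing calls;
2. a SNP qualifies if at least 5% of the windows overlapping it are
   compliant (`window_hit_threshold = 0.05`; widely used default of the
   scanning software family, configurable);
3. maximal runs of qualifying SNPs are split wherever consecutive SNPs
   are more than 250 kb apart;
4. surviving runs must contain at least `min_snps` SNPs, span at least
   1 Mb, and average at least one SNP per 100 kb.

Gap-splitting precedes the run-level checks because gaps define run
boundaries, whereas SNP count, length and density are properties of a
finished run. No run-level heterozygote cap is imposed beyond what
window compliance implies. Lengths use the closed-interval convention
(`end − start + 1`); conversion to half-open coordinates belongs at
BED export only.

`min_snps` comes from the false-positive bound
`l = ceil( ln(α / (n_s · n_i)) / ln(1 − het̄) )` with α = 0.05: the
shortest all-homozygous run unlikely to occur by chance anywhere in a
panel of `n_s` SNPs times `n_i` individuals at mean SNP heterozygosity
`het̄` (computed from the post-QC cohort, since the quantity the bound
needs is the realised typing heterozygosity).

Summaries: physical length classes are left-closed
([1,5), [5,10), [10,15), [15,20), >=20 Mb — the "1 to <5" phrasing);
per-breed class means average over *all* animals of the breed, counting
animals without ROH as zero. Per-SNP incidence is the fraction of
in-scope individuals whose ROH cover the SNP; hotspots are maximal runs
of map-adjacent SNPs in the top 1% of incidence (threshold = the k-th
largest value with k = floor(0.01·n); an empirical quantile collapses
under the heavy ties this statistic produces). Chromosome fractions
divide mean per-individual coverage by the SNP-covered span.

Genetic ROH lengths support demographic binning: a segment inherited
intact from an ancestor `g` generations back has expected map length
`100/(2g)` cM, giving bin edges 10, 5 and 2.5 cM for horizons of 5, 10
and 20 generations (left-closed). Recombination-rate context comes
from 500-kb tiles: (ΔcM)/(Δbp in Mb) between the first and last mapped
SNP in the tile, absent when fewer than two SNPs fall inside.

Unmapped SNPs get genetic positions by linear interpolation on physical
position between mapped anchors, with constant extrapolation beyond the
mapped span — the natural monotone choice where the source linkage map
is silent.

## Inbreeding coefficients

Four per-animal measures:

* **F\_ROH** — summed ROH length at thresholds 1/5/10 Mb over the
  autosome length. The denominator defaults to the SNP-covered map
  span; a fixed constant (2.44 Gb for the ovine panel) can be supplied
  to mirror published practice. The 1/5/10-Mb triple is monotone
  non-increasing by construction.
* **F\_PED** — the Meuwissen–Luo algorithm: per animal, accumulate the
  generation coefficients L over its ancestor set and combine with the
  Mendelian-sampling variances D (`A_ii = Σ L² D`), in topological
  order. Verified against an independently coded tabular
  relationship-matrix oracle on random pedigrees — agreement is exact,
  as both are exact algorithms.
* **F\_GRM** — the VanRaden genomic-relationship diagonal,
  `Σ(x−2p)² / (2Σp(1−p)) − 1`, per-individual sums restricted to typed
  SNPs (unbiased under missingness at random), fixed SNPs excluded.
* **F\_HOM** — Wright-style excess homozygosity
  `(O − E)/(m − E)` with `E = Σ(1 − 2p(1−p))` over typed SNPs.

Allele frequencies for the genomic measures are estimated in the
analysed set, with pooled vs within-breed scope selectable
(`freq_scope`), since published comparisons exist in both conventions.
Pedigree depth is measured in complete generation equivalents,
`CGE = Σ (1/2)^g` over known ancestors; the comparison report restricts
to animals with CGE >= 6 (configurable) so that F\_PED is meaningful,
then computes all pairwise Pearson correlations (within breed and
pooled) and OLS regressions of each F\_ROH measure on F\_PED.

## Selection signatures from F\_ST

Per SNP, the Weir–Cockerham (1984) variance components: among-breed
(a), among-individual-within-breed (b) and within-individual (c), using
observed heterozygote fractions, with θ = a/(a+b+c). Breeds untyped at
a SNP drop out of that SNP; SNPs monomorphic across the included breeds
are undefined and excluded from ranking. The implementation is checked
against a scalar brute-force coding of the same components to 1e-12 on
hundreds of random configurations, and θ is property-tested for
invariance to allele relabelling and individual order.

Smoothing: a centred 5-SNP mean assigned to the middle SNP. Windows
never span chromosome boundaries, so the two outermost SNPs per
chromosome carry no windowed value; undefined per-SNP thetas drop out
of a window's mean; negative thetas are retained (clamping would bias
window means upward). The extension percentile is taken over windowed
values, consistent with treating the windowed statistic as the object
of inference.

Region calling: seed SNPs reach the top 0.1% of windowed values
(k-th-largest thresholding as above); regions extend SNP-by-SNP in both
directions until **two consecutive** SNPs rank outside the top 5%, with
the first sub-threshold SNP included and the second excluded; regions
from multiple seeds merge when they touch. Pairwise-breed scans reuse
the same machinery over all breed pairs.

## Effective population size from LD decay

For one breed, all same-chromosome SNP pairs (within-breed MAF > 0.05,
distance <= `max_pair_distance_kb`) contribute a squared genotype
correlation r², adjusted for sampling as r² − 1/n (unphased genotype
data; 1/(2n) available for phased input). Physical distance maps to a
recombination fraction c — linear 1 cM/Mb (capped at 0.5) by default,
with Haldane and a Sved–Feldman-style `c = m/(1+2m)` mapping available
behind the same interface, because the exact historical form of the
latter is reported inconsistently across the literature and deserves to
stay pluggable. Pairs are binned equal-width in c (30 bins, >= 100
pairs each), and each bin yields

  `N_t = (4c)^{-1} (E[r²_adj]^{-1} − α)`,  at depth `t = (2c)^{-1}`
  generations,

with α = 2 by default (the mutation-drift convention) and α = 1 for
drift-only settings such as the package's own forward simulations,
which have no mutation. A years axis uses a 4-year generation interval
typical of sheep.

The inversion `1/(1+4Nc)` is a small-c approximation: beyond c ≈ 0.1
it increasingly overestimates N (at c = 0.5 the unlinked-locus
expectation is nearer 1/(3N)). Distance caps that keep c at or below
about 0.1 are therefore recommended, and the recovery tests use a
10-Mb cap.

## The synthetic-data generators

Every analysis stage is validated against simulators whose ground truth
is known by construction:

* **Balding–Nichols breed divergence** — per SNP an ancestral frequency
  p ~ U(0.05, 0.95); per breed a frequency from
  Beta(p(1−c)/c, (1−p)(1−c)/c) and genotypes Binomial(2, ·). Expected
  θ ≈ c, making mean-F\_ST recovery a closed-loop check. The default
  design mirrors a six-breed ovine cohort at one-tenth scale
  (66/6/67/78/49/63 animals, ~4,900 SNPs on 26 autosomes of 94 Mb —
  about 2.44 Gb of coverage at one SNP per 500 kb).
* **Pedigree designs** — random mating plus two deterministic loops
  whose offspring inbreeding is textbook-exact (full sibs 0.25, half
  sibs 0.125).
* **Gene dropping** — founder haplotypes labelled by origin; meioses
  recombine with Poisson(map length) crossovers at uniform map
  positions (no interference — adequate for ROH/LD structure and keeps
  the oracle arithmetic simple); mutation is deliberately omitted so
  label identity *is* identity by descent. True autozygous segments are
  recorded at marker resolution, so segment bookkeeping conserves the
  chromosome exactly.
* **Forward Wright–Fisher** — 2N haplotypes on one linear chromosome,
  discrete generations, Poisson recombination, optional symmetric
  mutation (compiled core using R's RNG, so runs are reproducible under
  `set.seed`). The constant N is the ground truth for Ne recovery.

What these simulators do **not** emulate: genotyping error, call-rate
structure, ascertainment bias of array SNPs, crossover interference,
overlapping generations, and selection acting *during* forward
simulation (sweeps are injected post hoc by resampling a region toward
fixation in target breeds). Passing tests therefore demonstrate
correctness of the estimators under their own model assumptions, not
robustness to array artefacts.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen for stable statistics:
F\_ST recovery at 6 breeds x 100 individuals x 5,000 SNPs for drift
c ∈ {0.02, 0.1, 0.3}; ROH recovery on a 40-founder, 4-generation
random-mating cohort over six 100-Mb chromosomes at 50-kb spacing
(recovery of >= 95% of true tracts >= 2 Mb, endpoint slack of one window
span, and zero-to-one chance segments among outbred founders under the
α = 0.05 design bound); Ne recovery at N ∈ {100, 200, 400} with 200
generations and 2,000 SNPs on a 1-Morgan chromosome — 200 generations
is enough for LD at c >= 0.0125 (the most ancient time depth scored) to
equilibrate, while preserving segregating sites at N = 100, where
longer runs drift most SNPs to fixation. Recovered N is summarised as
the mean over bins with t <= N/10 and lands within ±30% of truth across
seeds.

Degenerate inputs are handled explicitly rather than by accident:
chromosomes shorter than a window are scanned at the available size
down to 20 SNPs and skipped below; monomorphic SNPs are undefined for
θ and excluded from means and ranking; zero-variance measures are
flagged `NA` in correlation reports; bins with non-positive adjusted r²
are marked invalid rather than silently dropped; all-missing
breed-SNP combinations are skipped in the HWE filter.

## Known limitations

Real-cohort headline numbers (specific correlation values, hotspot
coordinates, Ne ranges) depend on the particular animals genotyped and
are not reproducible from simulation; the package validates machinery,
not historical datasets. F\_ST region calling assumes exchangeable
breeds of comparable effective size — the classical caveat that
structure and size heterogeneity inflate false positives applies.
F\_PED is bounded by recorded pedigree depth; the CGE >= 6 restriction
mitigates but does not remove this. The Ne estimator inherits the
equilibrium assumptions of the drift-LD relation and should be read as
a smoothed trajectory, not generation-resolved history.
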
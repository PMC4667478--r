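# mhcdrift

Population-genetic analysis of hyper-polymorphic loci in bottlenecked
populations: did drift alone shape the diversity you see, or did selection
keep it alive?

The package was built for the classic study design around genes of the
major histocompatibility complex (MHC): phased haplotype sequences of a
short, highly variable coding fragment (say, 250 bp of a class I exon
encoding part of the peptide-binding region) sampled from a large source
population, an island population founded by a handful of colonisers, and a
domesticated population — plus a mitochondrial fragment as a neutral
benchmark. It provides, in one coherent toolkit:

* **Diversity** — nucleotide diversity
  `π = Σ_{i<j} d_ij / (C(n,2) · L)`; synonymous/nonsynonymous diversity
  `π_s`, `π_a` by Nei–Gojobori counting (pathway-averaged difference
  counts, Jukes–Cantor corrected); haplotype diversity
  `HD = n/(n−1) · (1 − Σ x_i²)` with a neutral-coalescent confidence
  interval conditioned on the observed segregating sites.
* **Differentiation** — Hudson's `K_ST = 1 − K_S/K_T` with permutation
  p-values (exact enumeration on small samples).
* **Selection** — a counting-based sitewise `ω = (N_d/N)/(S_d/S)` scan
  with a permutation flag for codons carrying an excess of nonsynonymous
  variation, and projection of peptide-binding-region annotations from a
  reference protein onto query codons.
* **Haplotype networks** — statistical-parsimony (TCS-style) networks with
  inferred intermediate haplotypes, a Jukes–Cantor-derived connection
  limit, group-to-group mutational distances, and GraphML export.
* **Bottleneck simulation** — a forward-time, individual-based simulator
  of allelic-diversity loss through a founder event with overlapping
  generations (lifespan 2, maturity at 1 year by default) and exponential
  recovery, reporting mean retained alleles ± SE over many iterations.
* **Synthetic data** — a generator producing codon alignments with
  controlled allele counts, frequency models, population sharing and
  per-codon ω profiles, so the whole pipeline runs without any downloads.

See `vignette("mhcdrift-methods")` for the models, assumptions and
numerical choices.

## A worked example

```r
library(mhcdrift)

# A bundled synthetic study design: "mainland" (50 gene copies),
# bottlenecked "island" (28), "captive" (64), 249 bp coding locus.
d <- demo_dataset()
d$table
#> <haplotype_table> H = 76 haplotypes among N = 142 gene copies
#>   per population: captive n=64, island n=28, mainland n=50

haplotypes_per_copy(d$table)           # 0.535: most haplotypes are rare
shared_haplotypes(d$table, "island", "mainland")   # 1

diversity_stats(d$alignment, d$popmap, "island", ci_reps = 5000, seed = 7)
#> <diversity_stats> island: n=28, H=9, S=19
#>   pi=0.0218  pi_s=0.0141  pi_a=0.0248  HD=0.902 (95% CI 0.651-0.937)

kst(d$alignment, d$popmap, c("mainland", "island"), n_perm = 1000, seed = 8)
#> <kst_result> mainland vs island: K_ST = 0.0354 (K_S = 5.164, K_T = 5.354),
#>   p = 0.000999 [1000 perms]

build_network(d$table)
#> <haplo_network> 216 nodes (140 inferred), 264 edges, 1 component(s);
#>   parsimony limit 6 steps at 95%

# Could a 10-founder colonisation followed by 50%/year recovery explain
# the island's allele count by drift alone?
run_scenario(bottleneck_config(allele_frequencies(d$table, "mainland"),
                               founders = 10, growth_rate = 0.5,
                               years = 34, iterations = 200, seed = 9))
#> <bottleneck_result> N0=10, r=0.50, 34 y, 200 iterations:
#>   9.04 (+/- 0.107) alleles retained of 34
```

Reading the output: the island keeps high haplotype diversity (HD 0.90,
against a neutral-coalescent band of 0.65–0.94 for its sample size and
segregating sites) and nonsynonymous diversity exceeding synonymous
(`π_a > π_s`), while `K_ST` shows small but significant differentiation
from the mainland. The simulator says a severe 10-founder bottleneck with
fast recovery retains ~9 of 34 source alleles under drift alone — so an
island sample with about that many alleles does not, by itself, require
selection; slower recovery scenarios retain far fewer.

`run_all(run_config(...))` chains every stage (stats → K_ST over all
population pairs → ω scan → network → bottleneck) and writes one TSV per
stage plus a `manifest.json` recording seeds and a config hash.

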
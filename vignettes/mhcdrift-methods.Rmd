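---
title: "Models and methods behind mhcdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mhcdrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcdrift)
```

`mhcdrift` analyses phased haplotype sequences from a highly polymorphic
locus — the motivating case is exon 3 of a passerine MHC class I gene —
sampled from several populations, some of which passed through founder
events or domestication bottlenecks. The scientific question it is built
around is: *is the allelic diversity retained in a bottlenecked population
more than genetic drift alone would leave behind?* Answering it requires
five pieces, which map onto the package's modules: diversity statistics,
differentiation tests, a sitewise selection scan, a haplotype network, and
a forward-time bottleneck simulator. A synthetic-data generator ties them
together so everything can be exercised without downloading sequences.

## Data model

The unit of observation is a *gene copy*: one phased haplotype sequence per
chromosome. A nuclear locus contributes two copies per diploid individual,
a mitochondrial locus one. Sequences must be equal-length, ungapped and
strictly A/C/G/T; ambiguity codes are rejected rather than collapsed,
because resolving them is the job of the (upstream, out-of-scope) phasing
step. Haplotype identity is exact string equality. A population map
(3-column TSV) assigns copies to individuals and populations; population
labels are free strings.

## Diversity statistics

**Nucleotide diversity** is the plain mean over all $\binom{n}{2}$ pairs of
the per-site Hamming distance, $\pi = \frac{1}{L}\binom{n}{2}^{-1}
\sum_{i<j} d_{ij}$, with *no* $n/(n-1)$ correction. **Haplotype
diversity** does use the correction: $HD = \frac{n}{n-1}(1 - \sum_i
x_i^2)$. The two conventions differ in the third decimal at the sample
sizes this package targets, so the choice is stated here prominently; it
matches the definitions used by the standard desktop tools for these
statistics.

**Synonymous and nonsynonymous diversity** follow Nei–Gojobori (1986)
counting. Per codon, each of the three positions contributes the fraction
of its three possible changes that are synonymous; changes creating stop
codons count as nonsynonymous so that synonymous plus nonsynonymous sites
always total 3 per codon. Differences between codons are resolved by
enumerating all minimal mutational pathways (orders of applying the
differing positions), excluding pathways through stop codons, and
averaging synonymous/nonsynonymous step counts. Per pair, $p_s = S_d/S$
and $p_a = N_d/N$ (site counts averaged over the two sequences) receive the
Jukes–Cantor correction $d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$, and
$\pi_s, \pi_a$ are means over pairs. Both corrected and raw values are
returned; at the divergences this package targets (a few percent) the
correction is mild. $p \ge 3/4$ raises an error rather than returning a
complex number — it can occur on tiny toy alignments where the synonymous
site count is a fraction of a site.

**Confidence interval for HD.** The observed $HD$ of a small sample is
compared against neutral expectation by simulating Kingman coalescent
genealogies for $n$ tips, conditioning on the observed number of
segregating sites $S$: exactly $S$ mutations are placed on branches with
probability proportional to branch length, each at a fresh site
(infinite-sites, no recombination), and the $HD$ of the induced haplotype
partition is recorded. The 2.5th/97.5th percentiles over 10,000 replicates
(default) form the interval. Conditioning on $S$ rather than on an
estimate of $\theta$ is a deliberate choice: $S$ is observed, $\theta$ is
not; the resulting interval is interpreted as "what $HD$ a neutral locus
showing this much segregation would produce". With $n$ around 28 and the
segregating-site counts typical of a 250 bp MHC fragment the lower bound
lands near 0.7, which is the regime where the comparison against neutral
reference loci is informative.

## Differentiation: Hudson's K_ST

$K_{ST} = 1 - K_S/K_T$, where $K_j$ is the mean pairwise difference count
within population $j$, $K_S = \sum_j (n_j/n) K_j$, and $K_T$ is the mean
over the pooled sample. Sample-size weighting $w_j = n_j/n$ is the
default; pair-count weighting is available behind the `weighting`
argument because the original software's exact choice is not documented —
neither option is asserted to be "the" published one. This statistic is
preferred over $F_{ST}$-style estimators for small samples at
hyper-polymorphic loci, where within-population heterozygosity is close to
saturation.

Significance comes from permuting population labels with sizes fixed.
Random permutations use the add-one convention $p = (b+1)/(m+1)$, so $p$
is never exactly zero; `n_perm = "exhaustive"` enumerates all label
assignments and returns the exact tail proportion. Note a subtlety the
test suite encodes: for two populations holding *identical* multisets of
sequences, $K_{ST}$ is slightly negative (the pooled mean includes
cross-population pairs), so "no differentiation" shows up as $K_{ST} \le
0$ with a large p-value, not as $K_{ST} = 0$ exactly.

## Sitewise selection scan

The scan is a transparent counting surrogate for full Bayesian sitewise
codon models (which belong in dedicated software and are out of scope
here): it is designed to recover the *location* of codons with an excess
of nonsynonymous variation, not posterior $\omega$ magnitudes. Per codon,
pathway-averaged $N_d$ and $S_d$ accumulate over all pairs, and $\omega =
(N_d/N)/(S_d/S)$. Codons with $S_d = 0$ but $N_d > 0$ report $\omega =
\infty$ plus a finite ranking value with $S_d$ replaced by 0.5; codons with
no differences report `NA`. Two estimator caveats are worth knowing:

* `mean_omega()` (the mean of per-codon ratios) is heavy-tailed and
  Jensen-biased on sparse data; for an alignment-wide neutrality check use
  the pooled ratio $(\sum N_d/\sum N)/(\sum S_d/\sum S)$, which is the
  consistent summary and is what the test suite calibrates against
  neutral simulations.
* The positive-site flag tests each codon's nonsynonymous fraction
  $N_d/(N_d+S_d)$ against a leave-one-out permutation null: mutation
  events are counted as distinct codon states minus one (pairwise
  difference counts overstate the information, being $O(n^2)$ views of
  $O(n)$ mutations), and a codon's labels are redrawn without replacement
  from the labels at all *other* codons. Leave-one-out matters because at
  a locus under balancing selection the selected codons themselves carry
  much of the nonsynonymous signal and would otherwise contaminate the
  null. The scan is conservative by construction: on synthetic data it
  flags a subset of the truly elevated codons and essentially no false
  positives. A codon must also show $\omega > 1$ to be flagged.

**PBR mapping.** Peptide-binding-region annotations live on a reference
protein (supplied by the user; a synthetic example ships in
`inst/extdata/`, clearly labelled as such). The query alignment's
consensus translation is globally aligned to the reference (match +1,
mismatch 0, gap −1, via `Biostrings::pairwiseAlignment`), and annotated
residue indices are projected through the alignment onto 1-based query
codon indices; PBR residues falling on gaps are reported as unmapped, and
an alignment leaving more than 20% of the reference on gaps raises a
homology error rather than returning a silent mis-mapping.

## Statistical-parsimony haplotype network

Haplotypes are joined, in increasing order of mutational distance, while
the probability that a connection of that length is free of superimposed
changes stays at or above the confidence level (default 95%). The
connection probability is computed under a Jukes–Cantor multiple-hit
model: from the observed proportion of differing sites $p = j/L$, the
per-site mutation load is $D = -\tfrac{3}{4}\log(1-\tfrac{4}{3}p)$; hits
per site are Poisson($D$), and a site showing a difference is a single hit
with probability $De^{-D} / \left(\tfrac{3}{4}(1-e^{-4D/3})\right)$. The
parsimony probability for $j$ differences is that quantity to the power
$j$, and the connection limit is the largest $j$ keeping it $\ge \alpha$
— 6 steps for 250 bp and 8 for 483 bp at 95%, the magnitudes familiar
from the statistical-parsimony literature.

Connections longer than one step insert inferred (unsampled) haplotypes —
the "missing alleles" drawn as black nodes in classic network figures —
along the canonical path that mutates differing sites in ascending
position order; path choice affects inferred node identity but not any
distance. Pairs already connected through the graph by a path no longer
than their distance are skipped. Ties at equal distance are broken by
connecting the pair whose more frequent member is larger first (common
haplotypes are the likely interiors), then lexicographically for
determinism. Group-to-group separation is the minimum shortest-path length
in unit-mutation edges, and the graph exports to GraphML with
per-population counts as node attributes.

## Bottleneck simulator

The simulator asks what a founder event does to allelic diversity under
pure drift: no mutation, selection, migration or sexes. It is
individual-based with overlapping generations:

* **Founding.** $2N_0$ gene copies are drawn multinomially from the source
  allele frequencies (the source population, nominally 20,000 individuals,
  is treated as an infinite pool — at these timescales its own drift is
  negligible next to the founder event) and paired into $N_0$ diploids
  with ages uniform on $\{0, \dots, \text{lifespan}-1\}$.
* **Yearly cycle.** Ages increment; individuals past the lifespan die;
  newborns are recruited up to the census target $N_t = \min(N_0
  (1+r)^t, \text{cap})$, each receiving one random allele from each of two
  distinct parents drawn uniformly from the mature survivors. With
  lifespan 2 and maturity at 1 — the default life history — an individual
  breeds at ages 1 and 2 and then dies, so roughly half the census turns
  over each year: the "50% generation overlap" arises from the mechanics
  rather than from a separate parameter.
* **Corner cases.** A single mature survivor triggers a selfing fallback
  (recorded); a year with no mature individuals simply recruits nobody
  (the juvenile cohort waits); a fully extinct iteration records zero
  alleles and is flagged, not restarted.
* **Census cap.** Exponential growth at 50%/year reaches millions of
  individuals within 34 years; the default cap of 50,000 bounds the cost.
  The cap is safe because allele loss saturates: once the census is large
  relative to the allele count, per-year expected loss is far below 0.01
  alleles (the test suite checks the monotonicity and scaling properties
  that underpin this).
* **Durations.** Default scenario lengths are 100 years at $r=0.10$, 60 at
  $r=0.20$ and 34 at $r=0.50$; by those horizons loss has saturated in all
  three, so the exact duration within that range is immaterial.

Each scenario runs 1,000 iterations by default and reports the mean
retained allele count, its standard error, the yearly mean trajectory and
the final-count histogram, reproducibly from a single seed. The closed
form $\sum_i \left(1-(1-p_i)^{2N_0}\right)$ for the expected number of
distinct founder alleles provides an analytic cross-check on the founding
step.

## Synthetic data generator

The generator produces codon alignments with the statistical structure the
analyses assume: a stop-free ancestral sequence evolves along a random
genealogy into a pool of alleles; populations draw gene copies
multinomially from frequency models (uniform, geometric, or explicit) over
configurable allele subsets, and copies are paired into diploids. Three
design points matter:

* **Mutation placement.** A codon's total mutation rate is weighted by
  $k_s + \omega_c k_n$ (its synonymous/nonsynonymous single-step neighbour
  counts under the genetic code), and the substitution class is chosen so
  the realized synonymous:nonsynonymous ratio tracks the per-codon
  $\omega$ profile — the standard codon-model convention in which
  $\omega > 1$ inflates both the bias *and* the rate at a codon. Stop
  codons are never created; a draw demanding an unavailable class redraws
  the codon and counts the event.
* **Divergence knobs.** Under `pool_structure = "mixed"` alleles attach
  anywhere in the genealogy (populations interleave, as island alleles do
  in the motivating system) and `divergence_steps` sets per-branch
  mutations. Under `"pop_clades"` each population's private alleles form
  their own clade and `divergence_steps` sets the between-population
  separation — needed for differentiation-recovery experiments, because
  uniformly scaling all branches leaves $K_{ST}$, a ratio, unchanged.
* **Homoplasy control.** With `infinite_sites = TRUE` every mutation hits
  a fresh site, so genealogy distances equal Hamming distances exactly —
  the regime the network-recovery tests exploit. The bundled demo instead
  allows recurrent substitution, which is what strongly selected codons do
  in real data.

`demo_dataset()` fixes a three-population design shaped like a realistic
field study: a large mainland sample (50 copies, dozens of alleles, near
the 35-of-50 allele-to-copy ratio typical of hyper-polymorphic loci), a
bottlenecked island sample (28 copies, few alleles, two shared with the
other populations, top-heavy geometric frequencies), and a captive
population (64 copies) broadly overlapping the mainland pool; 83 codons at
249 bp with a purifying background ($\omega = 0.15$) and nine strongly
selected codons ($\omega = 8$). Realized pooled richness is ~70 haplotypes
among 142 copies and π ≈ 0.02–0.03, the order observed at such loci. The
generator does *not* emulate several features of real data — recombination
and gene conversion, sequencing or phasing error, related individuals,
locus duplication — so passing tests demonstrate correctness of the
statistics under the stated model, not robustness to those complications.

## Problem sizes and numerical choices

Defaults were chosen as the sizes a desk analysis of one locus needs: HD
intervals use 10,000 coalescent replicates; permutation tests 1,000
shuffles (exhaustive enumeration available below ~10 copies per group);
bottleneck scenarios 1,000 iterations with a 50,000 census cap. The test
suite runs reduced versions of the stochastic experiments (hundreds of
replicates) sized to keep Monte-Carlo assertions at three standard errors
stable. Floating-point assertions in the tests are exact for counting
quantities and 1e-12 for closed formulas. Seeds are explicit everywhere
randomness occurs; deterministic statistics are verified to be
seed-invariant.

## Known limitations

* The sitewise scan trades power for transparency; it will under-flag
  when many codons are simultaneously under selection (their events
  dominate the label pool even with leave-one-out nulls).
* The parsimony-connection probability is derived from the Jukes–Cantor
  single-hit argument stated above; other statistical-parsimony
  implementations may differ in the third decimal of the probability,
  though the resulting step limits agree at these sequence lengths.
* $K_{ST}$ inherits the known compression of differentiation measures at
  hyper-polymorphic loci; comparing its value across loci with different
  diversity levels needs care.
* The simulator's hermaphroditic random mating slightly understates drift
  relative to a two-sex model with unequal sex ratios.
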
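Package: mhcdrift
Title: Diversity, Differentiation, Selection Scans and Bottleneck
    Simulation for Highly Polymorphic Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sequence variation at highly polymorphic
    loci (such as MHC class I) against neutral benchmarks in small,
    bottlenecked populations. Computes nucleotide diversity, synonymous and
    nonsynonymous diversity by Nei-Gojobori counting with Jukes-Cantor
    correction, haplotype diversity with coalescent confidence intervals,
    and Hudson's K_ST differentiation statistic with permutation tests.
    Builds statistical-parsimony (TCS-style) haplotype networks with
    inferred intermediate nodes, performs a counting-based sitewise dN/dS
    scan with peptide-binding-region annotation, and runs a forward-time
    individual-based simulator of allelic diversity loss through founder
    events with overlapping generations. Includes a synthetic-data
    generator so the whole pipeline runs without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
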
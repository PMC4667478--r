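test_that("sitewise omega classifies monomorphic and synonymous-only codons", {
  # codon 1 monomorphic, codon 2 synonymous-only (TTT/TTC), codon 3 mixed
  seqs <- c("AAATTTGCT", "AAATTCGCT", "AAATTTGAT", "AAATTCGCT")
  scan <- sitewise_omega(seqs)
  expect_true(is.na(scan$omega[1]))
  expect_false(scan$positive[1])
  expect_equal(scan$omega[2], 0)
  expect_true(is.finite(scan$omega[3]) || is.infinite(scan$omega[3]))
  expect_equal(scan$N_sites + scan$S_sites, rep(3, 3))
})

test_that("per-codon Nd/Sd equal the exhaustive pathway oracle", {
  set.seed(41)
  for (rep in 1:3) {
    seqs <- mutate_family(stopfree_random_seq(5), 4, muts_per_seq = 2)
    scan <- sitewise_omega(seqs)
    want <- oracle_sitewise(seqs)
    expect_equal(scan$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(scan$Sd, want$Sd, tolerance = 1e-12)
  }
})

test_that("difference counts conserve total pairwise distances", {
  set.seed(42)
  seqs <- mutate_family(stopfree_random_seq(15), 6, muts_per_seq = 3)
  scan <- sitewise_omega(seqs)
  d <- pairwise_differences(seqs)
  expect_equal(sum(scan$Nd + scan$Sd), mean(d[upper.tri(d)]),
               tolerance = 1e-10)
})

test_that("mean omega averages defined codons and handles the Sd=0 sentinel", {
  fake <- data.frame(codon = 1:4, Nd = c(0, 1, 2, 1), Sd = c(0, 1, 1, 1),
                     N_sites = 2.5, S_sites = 0.5,
                     omega = c(NA, 0, 2, 4), omega_ranking = c(NA, 0, 2, 4),
                     positive = FALSE, is_pbr = NA)
  class(fake) <- c("omega_scan", "data.frame")
  expect_equal(mean_omega(fake), 2.0)
  fake$omega <- c(NA, 1, 1, 1)
  expect_equal(mean_omega(fake), 1.0)
  fake$omega <- rep(NA_real_, 4)
  expect_error(mean_omega(fake), "insufficient data")

  # Sd = 0 with Nd > 0: infinite sentinel, finite ranking value
  seqs <- c("AAAGCTTTTCCC", "AAAGATTTTCCC", "AAAGCTTTTCCC")
  scan <- sitewise_omega(seqs)
  expect_true(is.infinite(scan$omega[2]))
  expect_true(is.finite(scan$omega_ranking[2]))
})

test_that("positive-site flagging finds a concentrated nonsynonymous signal", {
  # codon 2 segregates six amino acids (five nonsynonymous mutation
  # events); six other codons carry one synonymous event each
  seqs <- c(
    "TTTGCTCCAGGACGAGCAACAAAA",
    "TTCGTTCCGGGTCGTGCGACGAAA",
    "TTTGATCCAGGACGTGCAACGAAA",
    "TTCCCTCCGGGTCGAGCGACAAAA",
    "TTTACTCCAGGTCGTGCAACAAAA",
    "TTCTCTCCGGGACGAGCGACGAAA",
    "TTTGCTCCAGGACGTGCAACAAAA"
  )
  scan <- flag_positive_sites(seqs, n_perm = 400, seed = 1)
  expect_true(scan$positive[2])
  expect_false(any(scan$positive[-2]))

  # flags are stable across seeds for a clear signal
  scan2 <- flag_positive_sites(seqs, n_perm = 400, seed = 99)
  expect_equal(scan$positive, scan2$positive)

  # with no nonsynonymous differences nothing is flagged
  syn_only <- c("TTTGCTCCAGGACGA", "TTCGCTCCAGGACGA", "TTTGCCCCAGGACGA")
  scan3 <- flag_positive_sites(syn_only, n_perm = 200, seed = 2)
  expect_false(any(scan3$positive))

  expect_error(flag_positive_sites(seqs, n_perm = 50), "configuration error")
})

test_that("PBR mapping projects reference residues through the alignment", {
  seqs <- c("TTTGCTAAACCCGGG", "TTTGCTAAACCCGGG")
  query_aa <- mhcdrift:::consensus_translation(seqs) # FAKPG
  # identity reference
  ann <- pbr_annotation("ref", query_aa, c(2, 5))
  flags <- map_pbr(seqs, ann)
  expect_equal(which(flags), c(2, 5))
  # one leading extra residue shifts flags by -1
  ann2 <- pbr_annotation("ref2", paste0("M", query_aa), c(3, 6))
  flags2 <- map_pbr(seqs, ann2)
  expect_equal(which(flags2), c(2, 5))
  expect_length(attr(flags2, "unmapped"), 0)
  # mapping is idempotent and invariant to record order
  expect_equal(which(map_pbr(rev(seqs), ann)), which(flags))
  # hopeless reference triggers a homology error
  ann3 <- pbr_annotation("junk", "WWWWWWWWWWWWWWWWWWWW", c(1, 2))
  expect_error(map_pbr(seqs, ann3), "homology error")
})

test_that("a mutated reference still maps its annotated residues correctly", {
  set.seed(44)
  d <- demo_dataset(seed = 13)
  query_aa <- mhcdrift:::consensus_translation(d$alignment)
  # corrupt a few non-PBR residues of the reference copy
  ref <- strsplit(query_aa, "")[[1]]
  pbr_pos <- sort(sample(seq_along(ref), 17))
  free <- setdiff(seq_along(ref), pbr_pos)
  ref[sample(free, 5)] <- "A"
  ann <- pbr_annotation("synthetic-ref", paste(ref, collapse = ""), pbr_pos)
  flags <- map_pbr(d$alignment, ann)
  expect_equal(which(flags), pbr_pos)
  scan <- annotate_pbr(sitewise_omega(d$alignment), flags)
  expect_equal(sum(scan$is_pbr), 17)
})

test_that("the bundled synthetic PBR annotation loads and maps onto a matching query", {
  fa <- system.file("extdata", "synthetic_pbr_reference.fasta",
                    package = "mhcdrift")
  tsv <- system.file("extdata", "synthetic_pbr_positions.tsv",
                     package = "mhcdrift")
  ann <- read_pbr_annotation(fa, tsv)
  expect_s3_class(ann, "pbr_annotation")
  expect_length(ann$pbr_positions, 17)
  expect_equal(nchar(ann$reference_sequence), 83)
})

test_that("a neutral generator yields an alignment-wide omega near one", {
  # the alignment-wide ratio (pooled differences over pooled sites) is the
  # consistent neutral summary; per-codon ratios are too noisy at neutral
  # mutation densities to average meaningfully
  set.seed(45)
  agg <- replicate(20, {
    spec <- generator_spec(n_pops = 1, copies_per_pop = 40, length = 90,
                           n_alleles = 30, frequency_model = "uniform",
                           divergence_steps = 3, infinite_sites = FALSE)
    sc <- sitewise_omega(generate_allele_pool(spec)$sequences)
    (sum(sc$Nd) / sum(sc$N_sites)) / (sum(sc$Sd) / sum(sc$S_sites))
  })
  se <- sd(agg) / sqrt(length(agg))
  expect_lt(abs(mean(agg) - 1), 3 * se + 0.1)
})

test_that("strong omega profiles are recovered in rank order", {
  set.seed(46)
  nc <- 45
  profile <- rep(c(0.02, 1, 50), each = 15)
  rhos <- replicate(10, {
    spec <- generator_spec(n_pops = 1, copies_per_pop = 80, length = 3 * nc,
                           n_alleles = 70, frequency_model = "uniform",
                           divergence_steps = 12, omega_profile = profile,
                           infinite_sites = FALSE)
    scan <- sitewise_omega(generate_allele_pool(spec)$sequences)
    ok <- !is.na(scan$omega_ranking)
    suppressWarnings(cor(profile[ok], scan$omega_ranking[ok],
                         method = "spearman"))
  })
  expect_gte(mean(rhos), 0.8)
})
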
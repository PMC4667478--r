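test_that("nucleotide diversity matches direct pairwise computation", {
  expect_equal(nucleotide_diversity(rep("ACGTACGTAC", 4)), 0)
  expect_equal(nucleotide_diversity(c("AAAAAAAAAA", "AAAAAAAAAT")), 0.1)
  expect_error(nucleotide_diversity("ACGT"), "insufficient data")

  set.seed(31)
  for (rep in 1:5) {
    seqs <- mutate_family(stopfree_random_seq(20), 6, muts_per_seq = 3)
    expect_equal(nucleotide_diversity(seqs), oracle_pi(seqs),
                 tolerance = 1e-12)
  }
})

test_that("pairwise difference counts agree with an established distance routine", {
  set.seed(32)
  seqs <- mutate_family(stopfree_random_seq(30), 8, muts_per_seq = 2)
  d_pkg <- pairwise_differences(seqs)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  d_ape <- as.matrix(ape::dist.dna(bin, model = "N"))
  dimnames(d_pkg) <- dimnames(d_ape)
  expect_equal(d_pkg, d_ape)
})

test_that("synonymous/nonsynonymous diversity follows Nei-Gojobori counting", {
  # identical sequences
  sn0 <- syn_nonsyn_diversity(rep("TTTAAACCC", 3))
  expect_equal(sn0$pi_s, 0)
  expect_equal(sn0$pi_a, 0)

  # purely synonymous pair (Phe TTT <-> TTC), padded so JC stays defined
  sn1 <- syn_nonsyn_diversity(c("TTTAAACCCGGGTTT", "TTCAAACCCGGGTTT"))
  expect_equal(sn1$pi_a, 0)
  expect_gt(sn1$pi_s, 0)

  # internal stop codons are rejected with their positions
  expect_error(syn_nonsyn_diversity(c("TTTTAAAAA", "TTTTAAAAA")),
               "stop codon.*2")

  # randomized small codon alignments match the exhaustive-pathway oracle
  set.seed(33)
  for (rep in 1:4) {
    seqs <- mutate_family(stopfree_random_seq(12), 5, muts_per_seq = 2)
    got <- syn_nonsyn_diversity(seqs)
    want <- oracle_syn_nonsyn_diversity(seqs)
    expect_equal(got$pi_s, want$pi_s, tolerance = 1e-12)
    expect_equal(got$pi_a, want$pi_a, tolerance = 1e-12)
  }
})

test_that("haplotype diversity uses the small-sample correction", {
  ids <- paste0("c", 1:6)
  pm <- data.frame(copy_id = ids, individual_id = ids,
                   population = rep("p", 6), stringsAsFactors = FALSE)
  tab_same <- build_haplotype_table(hap_alignment(rep("AAAA", 6), ids), pm)
  expect_equal(haplotype_diversity(tab_same, "p"), 0)

  tab2 <- build_haplotype_table(hap_alignment(c("AAAA", "CCCC"), ids[1:2]),
                                pm[1:2, ])
  expect_equal(haplotype_diversity(tab2), 1.0)

  # counts (3,2,1): HD = (6/5)(1 - 14/36)
  seqs <- c(rep("AAAA", 3), rep("CCCC", 2), "GGGG")
  tab3 <- build_haplotype_table(hap_alignment(seqs, ids), pm)
  expect_equal(haplotype_diversity(tab3), (6 / 5) * (1 - 14 / 36),
               tolerance = 1e-12)

  tab1 <- build_haplotype_table(hap_alignment("AAAA", "c1"), pm[1, ])
  expect_error(haplotype_diversity(tab1), "insufficient data")
})

test_that("coalescent HD interval honours degenerate cases and grows with S", {
  expect_equal(unname(hd_confidence_interval(10, 0, reps = 1000)), c(0, 0))
  ci <- hd_confidence_interval(2, 3, reps = 1000, seed = 5)
  expect_equal(unname(ci), c(1, 1))
  expect_error(hd_confidence_interval(1, 3), "insufficient data")
  expect_error(hd_confidence_interval(10, 2, reps = 10), "at least 1000")

  # mean simulated HD weakly increases with S at fixed n
  set.seed(6)
  mean_hd <- function(S) {
    mean(replicate(400, mhcdrift:::coalescent_hd_replicate(12, S)))
  }
  m <- vapply(c(1, 4, 16), mean_hd, numeric(1))
  expect_true(all(diff(m) > 0))
  # interval bounds are ordered
  ci2 <- hd_confidence_interval(12, 8, reps = 1500, seed = 7)
  expect_lte(ci2[1], ci2[2])
})

test_that("K_ST separates fixed populations and matches exact enumeration", {
  ids <- paste0("c", 1:8)
  pm <- function(pops) data.frame(copy_id = ids[seq_along(pops)],
                                  individual_id = ids[seq_along(pops)],
                                  population = pops, stringsAsFactors = FALSE)
  # each population fixed for a distinct haplotype: K_S = 0, K_ST = 1
  aln_fix <- hap_alignment(c(rep("AAAA", 3), rep("TTTT", 3)), ids[1:6])
  r <- kst(aln_fix, pm(rep(c("x", "y"), each = 3)), c("x", "y"),
           n_perm = 200, seed = 1)
  expect_equal(r$K_S, 0)
  expect_equal(r$K_ST, 1)

  # all sequences identical: statistic undefined
  expect_error(
    kst(hap_alignment(rep("AAAA", 6), ids[1:6]),
        pm(rep(c("x", "y"), each = 3)), c("x", "y")),
    "undefined statistic")

  # exhaustive permutation p-value equals independent enumeration
  set.seed(34)
  seqs <- mutate_family(stopfree_random_seq(15), 4, muts_per_seq = 2)
  seqs <- c(seqs, seqs[1:2])
  labels <- c("x", "x", "x", "y", "y", "y")
  aln <- hap_alignment(seqs, ids[1:6])
  r2 <- kst(aln, pm(labels), c("x", "y"), n_perm = "exhaustive")
  expect_equal(r2$K_ST, oracle_kst_stat(seqs, labels), tolerance = 1e-12)
  expect_equal(r2$p_value, oracle_kst_exact_p(seqs, labels), tolerance = 1e-12)
})

test_that("K_ST is symmetric, order-invariant, and exchangeable data are unremarkable", {
  set.seed(35)
  seqs <- mutate_family(stopfree_random_seq(20), 5, muts_per_seq = 2)
  seqs <- sample(seqs, 12, replace = TRUE)
  ids <- paste0("c", 1:12)
  pops <- rep(c("x", "y"), each = 6)
  pm <- data.frame(copy_id = ids, individual_id = ids, population = pops,
                   stringsAsFactors = FALSE)
  aln <- hap_alignment(seqs, ids)
  r_xy <- kst(aln, pm, c("x", "y"), n_perm = 300, seed = 2)
  r_yx <- kst(aln, pm, c("y", "x"), n_perm = 300, seed = 2)
  expect_equal(r_xy$K_ST, r_yx$K_ST, tolerance = 1e-12)

  perm <- sample(12)
  aln_p <- hap_alignment(seqs[perm], ids[perm])
  r_perm <- kst(aln_p, pm, c("x", "y"), n_perm = 300, seed = 2)
  expect_equal(r_perm$K_ST, r_xy$K_ST, tolerance = 1e-12)

  # both populations carry the same multiset: label permutation null holds,
  # so the p-value is large and the observed K_ST is not positive
  half <- mutate_family(stopfree_random_seq(20), 6, muts_per_seq = 2)
  aln_same <- hap_alignment(c(half, half), ids)
  r_same <- kst(aln_same, pm, c("x", "y"), n_perm = "exhaustive")
  expect_lte(r_same$K_ST, 0)
  expect_gt(r_same$p_value, 0.2)
})

test_that("pooled diversity bounds the within-population component", {
  # mixture inequality: K_T >= K_S, so K_ST >= 0 for structured data
  set.seed(36)
  poolA <- mutate_family(stopfree_random_seq(25), 4, muts_per_seq = 1)
  poolB <- mutate_family(stopfree_random_seq(25), 4, muts_per_seq = 1)
  seqs <- c(sample(poolA, 6, TRUE), sample(poolB, 6, TRUE))
  ids <- paste0("c", 1:12)
  pm <- data.frame(copy_id = ids, individual_id = ids,
                   population = rep(c("x", "y"), each = 6),
                   stringsAsFactors = FALSE)
  r <- kst(hap_alignment(seqs, ids), pm, c("x", "y"), n_perm = 100, seed = 3)
  expect_gte(r$K_T, r$K_S)
  expect_gte(r$K_ST, 0)
})

test_that("diversity_stats assembles all components coherently", {
  d <- demo_dataset(seed = 42)
  st <- diversity_stats(d$alignment, d$popmap, "island", ci_reps = 1000,
                        seed = 9)
  expect_equal(st$n, 28)
  expect_gte(st$pi, 0)
  expect_true(st$hd >= 0 && st$hd <= 1)
  expect_lte(st$hd_ci[1], st$hd_ci[2])
  expect_gte(st$S, 1)
  expect_error(diversity_stats(d$alignment, d$popmap, "atlantis"),
               "lookup error")
})
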
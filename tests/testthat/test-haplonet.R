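test_that("parsimony probability and connection limit behave and match the oracle", {
  expect_error(parsimony_limit(0), "input error")
  expect_error(prob_parsimony(3, 0), "input error")

  # monotone decreasing in j
  p <- prob_parsimony(1:10, 250)
  expect_true(all(diff(p) < 0))

  # near-certain confidence keeps the limit at 0 or 1 for short sequences
  expect_lte(parsimony_limit(10, alpha = 0.999), 1)

  # limit is non-decreasing in L at fixed alpha
  lims <- vapply(c(50, 100, 250, 483, 1000), parsimony_limit, numeric(1))
  expect_true(all(diff(lims) >= 0))

  # exact agreement with an independent numeric-series implementation
  for (L in c(100, 250, 483)) {
    for (j in 1:8) {
      expect_equal(prob_parsimony(j, L), oracle_prob_parsimony(j, L),
                   tolerance = 1e-9)
    }
    expect_equal(parsimony_limit(L), oracle_parsimony_limit(L))
  }
})

simple_table <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1, length(seqs))
  copies <- rep(seqs, counts)
  ids <- paste0("c", seq_along(copies))
  pm <- data.frame(copy_id = ids, individual_id = ids,
                   population = "p", stringsAsFactors = FALSE)
  build_haplotype_table(hap_alignment(copies, ids), pm)
}

test_that("network construction inserts unit edges and inferred intermediates", {
  base <- strrep("A", 200) # long enough that the 95% limit allows 3+ steps
  one <- sub("^A", "T", base)
  net1 <- build_network(simple_table(c(base, one)))
  expect_equal(igraph::ecount(net1$graph), 1)
  expect_equal(sum(net1$nodes$inferred), 0)

  three <- base
  substr(three, 1, 3) <- "TTT"
  net3 <- build_network(simple_table(c(base, three)))
  expect_equal(igraph::ecount(net3$graph), 3)
  expect_equal(sum(net3$nodes$inferred), 2)
  # every edge spans exactly one mutation
  tabs <- network_tables(net3)
  seq_of <- setNames(net3$nodes$sequence, net3$nodes$id)
  d_edge <- mapply(function(a, b) {
    sum(strsplit(seq_of[[a]], "")[[1]] != strsplit(seq_of[[b]], "")[[1]])
  }, tabs$edges$from, tabs$edges$to)
  expect_true(all(d_edge == 1))
})

test_that("a star-shaped haplotype set yields a star network", {
  center <- strrep("ACGT", 10)
  leaves <- vapply(seq(1, 40, by = 8), function(p) {
    s <- center
    substr(s, p, p) <- "T"
    s
  }, character(1))
  leaves <- unique(leaves)[1:5]
  tab <- simple_table(c(center, leaves), counts = c(5, rep(1, 5)))
  net <- build_network(tab)
  expect_equal(igraph::ecount(net$graph), 5)
  deg <- igraph::degree(net$graph)
  central_id <- net$nodes$id[net$nodes$sequence == center]
  expect_equal(unname(deg[central_id]), 5)
})

test_that("networks connect whenever distances sit inside the parsimony limit", {
  set.seed(51)
  for (rep in 1:3) {
    seqs <- unique(mutate_family(stopfree_random_seq(40), 9, muts_per_seq = 1))
    tab <- simple_table(seqs)
    net <- build_network(tab)
    dmax <- max(pairwise_differences(seqs))
    if (dmax <= net$parsimony_limit) {
      expect_equal(net$components, 1)
      expect_gte(igraph::ecount(net$graph), length(seqs) - 1)
    }
  }
})

test_that("group separation is a symmetric graph metric over populations", {
  base <- strrep("G", 300) # 95% limit for 300 sites comfortably exceeds 4
  far <- base
  substr(far, 1, 4) <- "TTTT"
  copies <- c(base, base, far, far)
  ids <- paste0("c", 1:4)
  pm <- data.frame(copy_id = ids, individual_id = ids,
                   population = c("x", "x", "y", "y"), stringsAsFactors = FALSE)
  tab <- build_haplotype_table(hap_alignment(copies, ids), pm)
  net <- build_network(tab)
  expect_equal(group_separation(net, "x", "y"), 4L)
  expect_equal(group_separation(net, "y", "x"), 4L)
  # overlapping groups
  expect_equal(group_separation(net, c("H01", "H02"), c("H02")), 0L)

  # triangle inequality over three populations of the demo network
  d <- demo_dataset(seed = 19)
  netd <- build_network(d$table)
  if (netd$components == 1) {
    ab <- group_separation(netd, "mainland", "island")
    bc <- group_separation(netd, "island", "captive")
    ac <- group_separation(netd, "mainland", "captive")
    expect_lte(ac, ab + bc)
  }
})

test_that("disconnected groups raise an informative error", {
  near <- c(strrep("A", 12), sub("^A", "C", strrep("A", 12)))
  far <- chartr("A", "T", strrep("A", 12))
  ids <- paste0("c", 1:3)
  pm <- data.frame(copy_id = ids, individual_id = ids,
                   population = c("x", "x", "y"), stringsAsFactors = FALSE)
  tab <- build_haplotype_table(hap_alignment(c(near, far), ids), pm)
  net <- build_network(tab)
  expect_gt(net$components, 1)
  expect_error(group_separation(net, "x", "y"), "disconnected.*parsimony limit")
})

test_that("network path lengths reproduce genealogy distances without homoplasy", {
  set.seed(52)
  spec <- generator_spec(n_pops = 1, copies_per_pop = 20, length = 120,
                         n_alleles = 10, frequency_model = "uniform",
                         divergence_steps = 1)
  pool <- generate_allele_pool(spec)
  expect_true(pool$homoplasy_free)
  tab <- simple_table(pool$sequences)
  net <- build_network(tab)
  ord <- match(pool$sequences, net$nodes$sequence)
  gd <- igraph::distances(net$graph, v = net$nodes$id[ord],
                          to = net$nodes$id[ord])
  expect_equal(unname(gd), unname(pool$tree_distances))
})

test_that("GraphML export round-trips through igraph", {
  base <- strrep("C", 16)
  tab <- simple_table(c(base, sub("^C", "A", base), sub("C$", "G", base)))
  net <- build_network(tab)
  f <- tempfile(fileext = ".graphml")
  write_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), igraph::ecount(net$graph))
})
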
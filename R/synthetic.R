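# Download-free synthetic datasets with the statistical structure the
# analyses assume: ungapped codon alignments, many low-frequency alleles,
# several populations with controlled allele sharing, and a tunable
# synonymous/nonsynonymous substitution profile.

#' Specification for the synthetic-data generator
#'
#' @param n_pops Number of populations.
#' @param copies_per_pop Integer vector of gene copies per population (even
#'   numbers for nuclear loci, one copy per individual for mitochondrial).
#' @param length Alignment length in bp, divisible by 3.
#' @param n_alleles Number of distinct alleles in the source pool.
#' @param frequency_model `"geometric"` (frequencies `q (1-q)^(rank-1)`,
#'   normalised), `"uniform"`, or `"explicit"` (supply
#'   `explicit_frequencies`).
#' @param q Geometric decay parameter in (0, 1) (geometric model only).
#' @param explicit_frequencies For the explicit model: a list (one numeric
#'   vector per population, indexed over that population's allele set).
#' @param divergence_steps Divergence knob. With `pool_structure = "mixed"`
#'   (default), the expected mutations per branch of the allele genealogy
#'   (each new allele differs from its parent by
#'   `1 + Poisson(divergence_steps - 1)` mutations). With
#'   `pool_structure = "pop_clades"`, the expected pairwise mutational
#'   separation between population allele pools: each population's private
#'   alleles grow on a clade whose root sits
#'   `1 + Poisson(divergence_steps/2 - 1)` mutations from the common
#'   ancestor.
#' @param pool_structure `"mixed"` (alleles attach anywhere in the
#'   genealogy, so populations interleave) or `"pop_clades"` (each
#'   population's private alleles form their own clade; requires
#'   `pop_allele_sets`).
#' @param branch_mutations Expected mutations per within-clade branch under
#'   `"pop_clades"` (default 1).
#' @param omega_profile Per-codon target nonsynonymous:synonymous rate
#'   ratio; default neutral (all 1).
#' @param pop_allele_sets Optional list of allele-index vectors restricting
#'   each population to a subset of the pool (controls sharing); default all
#'   alleles everywhere.
#' @param pop_labels Population labels; default `pop1, pop2, ...`.
#' @param locus_type Passed through to [hap_alignment()].
#' @param infinite_sites If `TRUE` (default) each mutation hits a previously
#'   unmutated site, so genealogy distances equal Hamming distances (no
#'   homoplasy).
#' @param seed Integer seed used by [synthesize_dataset()].
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_pops, copies_per_pop, length, n_alleles,
                           frequency_model = c("geometric", "uniform", "explicit"),
                           q = 0.2, explicit_frequencies = NULL,
                           divergence_steps = 2, omega_profile = NULL,
                           pop_allele_sets = NULL, pop_labels = NULL,
                           locus_type = "nuclear-codon",
                           pool_structure = c("mixed", "pop_clades"),
                           branch_mutations = 1,
                           infinite_sites = TRUE, seed = NULL) {
  frequency_model <- match.arg(frequency_model)
  pool_structure <- match.arg(pool_structure)
  if (pool_structure == "pop_clades" && is.null(pop_allele_sets)) {
    stop("pop_clades structure requires pop_allele_sets", call. = FALSE)
  }
  if (length < 3 || length %% 3 != 0) {
    stop("length must be at least 3 and divisible by 3", call. = FALSE)
  }
  if (length(copies_per_pop) != n_pops) {
    stop("copies_per_pop must have one entry per population", call. = FALSE)
  }
  if (n_alleles > sum(copies_per_pop)) {
    stop("n_alleles must not exceed the total number of copies", call. = FALSE)
  }
  if (is.null(omega_profile)) omega_profile <- rep(1, length %/% 3)
  if (length(omega_profile) != length %/% 3) {
    stop("omega_profile needs one value per codon", call. = FALSE)
  }
  if (any(omega_profile < 0) || divergence_steps < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(n_pops))
  structure(
    list(n_pops = n_pops, copies_per_pop = as.integer(copies_per_pop),
         length = as.integer(length), n_alleles = as.integer(n_alleles),
         frequency_model = frequency_model, q = q,
         explicit_frequencies = explicit_frequencies,
         divergence_steps = divergence_steps, omega_profile = omega_profile,
         pop_allele_sets = pop_allele_sets, pop_labels = pop_labels,
         locus_type = locus_type, pool_structure = pool_structure,
         branch_mutations = branch_mutations,
         infinite_sites = infinite_sites, seed = seed),
    class = "generator_spec"
  )
}

# Enumerate the single-nucleotide neighbours of a codon, classified as
# synonymous / nonsynonymous, excluding stops and (optionally) positions
# already mutated elsewhere in the pool's history.
codon_neighbours <- function(codon, blocked_pos = integer(0)) {
  bases <- c("A", "C", "G", "T")
  aa0 <- codon_aa(codon)
  out <- list(syn = list(), nonsyn = list())
  for (pos in setdiff(1:3, blocked_pos)) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      aa1 <- codon_aa(alt)
      if (aa1 == "*") next
      cls <- if (aa1 == aa0) "syn" else "nonsyn"
      out[[cls]] <- c(out[[cls]], list(list(pos = pos, codon = alt)))
    }
  }
  out
}

#' Generate a pool of related alleles
#'
#' Starts from a random stop-free ancestral codon sequence and grows a
#' random genealogy: each new allele copies a uniformly chosen existing
#' allele with `1 + Poisson(divergence_steps - 1)` point mutations. At each
#' mutation a codon is chosen uniformly and the substitution is drawn
#' nonsynonymous with probability `w k_n / (w k_n + k_s)` where `w` is that
#' codon's `omega_profile` entry and `k_n`, `k_s` the numbers of available
#' nonsynonymous/synonymous single-step neighbours, so the realised
#' syn:nonsyn ratio tracks the profile. Stop codons are never created.
#'
#' @param spec A `generator_spec`.
#' @return A list of class `allele_pool`: `sequences` (character vector),
#'   `tree_distances` (matrix of mutation counts along genealogy paths),
#'   `n_syn`, `n_nonsyn` (realised mutation class totals), `syn_by_codon`,
#'   `nonsyn_by_codon`, `homoplasy_free`, `redraws` (infeasible-codon
#'   redraw count).
#' @export
generate_allele_pool <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  nc <- spec$length %/% 3
  codons <- .codon_alphabet()
  ok <- codons[!is_stop_codon(codons)]
  ancestral <- sample(ok, nc, replace = TRUE)
  n <- spec$n_alleles

  # state shared by the mutation placer
  used_sites <- logical(spec$length)
  n_syn <- n_nonsyn <- 0L
  syn_by_codon <- nonsyn_by_codon <- integer(nc)
  redraws <- 0L
  homoplasy_free <- spec$infinite_sites
  infinite_sites <- spec$infinite_sites

  # mutation rate per codon follows the codon-model convention that omega
  # scales the nonsynonymous rate: rate_c proportional to k_s + w_c * k_n,
  # with neighbour counts taken from the ancestral state
  codon_weights <- vapply(seq_len(nc), function(cpos) {
    nb <- codon_neighbours(ancestral[cpos])
    length(nb$syn) + spec$omega_profile[cpos] * length(nb$nonsyn)
  }, numeric(1))
  if (all(codon_weights == 0)) {
    stop("omega_profile leaves no codon mutable", call. = FALSE)
  }

  # apply one profile-guided, stop-free point mutation to a codon vector;
  # an infeasible class draw (no neighbour of the requested kind) triggers
  # a codon re-draw
  place_mutation <- function(cur) {
    for (try in seq_len(500)) {
      cpos <- sample.int(nc, 1, prob = codon_weights)
      blocked <- integer(0)
      if (infinite_sites) {
        site_idx <- (cpos - 1L) * 3L + 1:3
        blocked <- which(used_sites[site_idx])
      }
      nb <- codon_neighbours(cur[cpos], blocked)
      ks <- length(nb$syn)
      kn <- length(nb$nonsyn)
      if (ks + kn == 0L) {
        redraws <<- redraws + 1L
        next
      }
      w <- spec$omega_profile[cpos]
      denom <- w * kn + ks
      if (denom == 0) {
        redraws <<- redraws + 1L
        next
      }
      pick_nonsyn <- stats::runif(1) < (w * kn) / denom
      cls <- if (pick_nonsyn) nb$nonsyn else nb$syn
      if (length(cls) == 0L) {
        redraws <<- redraws + 1L
        next
      }
      choice <- cls[[sample.int(length(cls), 1)]]
      cur[cpos] <- choice$codon
      used_sites[(cpos - 1L) * 3L + choice$pos] <<- TRUE
      if (pick_nonsyn) {
        n_nonsyn <<- n_nonsyn + 1L
        nonsyn_by_codon[cpos] <<- nonsyn_by_codon[cpos] + 1L
      } else {
        n_syn <<- n_syn + 1L
        syn_by_codon[cpos] <<- syn_by_codon[cpos] + 1L
      }
      return(cur)
    }
    warning("generation warning: could not place a mutation under the ",
            "infinite-sites constraint; relaxing it")
    homoplasy_free <<- FALSE
    infinite_sites <<- FALSE
    place_mutation(cur)
  }

  # clade membership: under pop_clades, alleles private to one population
  # grow on that population's clade; shared or unassigned alleles grow near
  # the common ancestor
  clade_of <- rep("shared", n)
  if (spec$pool_structure == "pop_clades") {
    for (pi in seq_len(spec$n_pops)) {
      for (a in spec$pop_allele_sets[[pi]]) {
        clade_of[a] <- if (clade_of[a] == "shared") paste0("clade", pi) else
          "multi"
      }
    }
    clade_of[clade_of == "multi"] <- "shared"
  }

  seqs <- vector("list", n)
  D <- matrix(0, n, n)
  danc <- numeric(n) # genealogy distance to the common ancestor
  lambda_branch <- if (spec$pool_structure == "mixed")
    max(0, spec$divergence_steps - 1) else max(0, spec$branch_mutations - 1)
  lambda_root <- max(0, spec$divergence_steps / 2 - 1)
  for (i in seq_len(n)) {
    members <- if (i == 1) integer(0) else
      which(clade_of[seq_len(i - 1)] == clade_of[i])
    if (length(members) == 0) {
      # clade founder: descend from the common ancestor
      if (clade_of[i] == "shared" || spec$pool_structure == "mixed") {
        nmut <- if (i == 1) 0L else 1L + stats::rpois(1, lambda_branch)
      } else {
        nmut <- 1L + stats::rpois(1, lambda_root)
      }
      parent <- 0L
      cur <- ancestral
    } else {
      parent <- members[sample.int(length(members), 1)]
      nmut <- 1L + stats::rpois(1, lambda_branch)
      cur <- seqs[[parent]]
    }
    if (nmut > 0) for (m in seq_len(nmut)) cur <- place_mutation(cur)
    seqs[[i]] <- cur
    danc[i] <- (if (parent == 0L) 0 else danc[parent]) + nmut
    if (i > 1) {
      prev <- seq_len(i - 1)
      D[i, prev] <- (if (parent == 0L) danc[prev] else D[parent, prev]) + nmut
      D[prev, i] <- D[i, prev]
    }
  }
  structure(
    list(sequences = vapply(seqs, paste, character(1), collapse = ""),
         tree_distances = D, n_syn = n_syn, n_nonsyn = n_nonsyn,
         syn_by_codon = syn_by_codon, nonsyn_by_codon = nonsyn_by_codon,
         homoplasy_free = homoplasy_free, redraws = redraws,
         spec = spec),
    class = "allele_pool"
  )
}

pop_frequencies <- function(spec, k, pop_index) {
  switch(spec$frequency_model,
    uniform = rep(1 / k, k),
    geometric = {
      f <- spec$q * (1 - spec$q)^(seq_len(k) - 1)
      (f / sum(f))[sample.int(k)]
    },
    explicit = {
      f <- spec$explicit_frequencies[[pop_index]]
      if (length(f) != k) {
        stop("explicit frequencies must match the population's allele set",
             call. = FALSE)
      }
      f / sum(f)
    })
}

#' Assign allele frequencies and sample gene copies per population
#'
#' Each population draws its copies multinomially from frequencies over its
#' allele set (see `pop_allele_sets` in [generator_spec()] for controlling
#' sharing between populations). For nuclear loci, copies are paired into
#' diploid individuals.
#'
#' @param pool An `allele_pool`.
#' @param spec The `generator_spec` used to build the pool.
#' @return A list: `alignment` (`hap_alignment`), `popmap` (data frame),
#'   `allele_of_copy` (integer pool indices), `provenance` (spec echo).
#' @export
assign_frequencies_and_copies <- function(pool, spec = pool$spec) {
  stopifnot(inherits(pool, "allele_pool"))
  nuclear <- spec$locus_type == "nuclear-codon"
  if (nuclear && any(spec$copies_per_pop %% 2 != 0)) {
    stop("pairing error: copies_per_pop must be even for a nuclear locus",
         call. = FALSE)
  }
  ids <- character(0)
  inds <- character(0)
  pops <- character(0)
  allele_of_copy <- integer(0)
  for (pi in seq_len(spec$n_pops)) {
    lab <- spec$pop_labels[pi]
    alleles <- if (is.null(spec$pop_allele_sets)) seq_len(spec$n_alleles) else
      spec$pop_allele_sets[[pi]]
    f <- pop_frequencies(spec, length(alleles), pi)
    ncopy <- spec$copies_per_pop[pi]
    draw <- stats::rmultinom(1, ncopy, f)[, 1]
    copies <- sample(rep(alleles, draw))
    per_ind <- if (nuclear) 2L else 1L
    ind_of_copy <- rep(seq_len(ncopy %/% per_ind), each = per_ind)
    ids <- c(ids, sprintf("%s_i%03d_c%d", lab, ind_of_copy,
                          seq_len(ncopy) - per_ind * (ind_of_copy - 1L)))
    inds <- c(inds, sprintf("%s_i%03d", lab, ind_of_copy))
    pops <- c(pops, rep(lab, ncopy))
    allele_of_copy <- c(allele_of_copy, copies)
  }
  alignment <- hap_alignment(pool$sequences[allele_of_copy], ids,
                             locus_type = spec$locus_type, frame = 0L)
  popmap <- data.frame(copy_id = ids, individual_id = inds,
                       population = pops, stringsAsFactors = FALSE)
  list(alignment = alignment, popmap = popmap,
       allele_of_copy = allele_of_copy,
       provenance = list(spec = unclass(spec)))
}

#' Generate a complete synthetic dataset
#'
#' Seeds the generator, builds the allele pool, samples copies, and returns
#' alignment, population map, haplotype table and provenance in one call.
#'
#' @param spec A `generator_spec`.
#' @return A list: `alignment`, `popmap`, `table` (`haplotype_table`),
#'   `pool`, `provenance`.
#' @export
synthesize_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pool <- generate_allele_pool(spec)
  ds <- assign_frequencies_and_copies(pool, spec)
  ds$pool <- pool
  ds$table <- build_haplotype_table(ds$alignment, ds$popmap)
  ds$provenance$seed <- spec$seed
  ds
}

#' Demonstration dataset imitating a three-population study design
#'
#' A 249 bp nuclear codon locus sampled in three populations -- a large
#' "mainland" source (50 copies), a bottlenecked "island" population (28
#' copies) whose allele pool shares exactly two alleles with the others, and
#' a "captive" population (64 copies) broadly overlapping the mainland pool.
#' Allele numbers are chosen so the pooled sample carries on the order of 74
#' distinct haplotypes among 142 gene copies, with many singletons. A block
#' of codons carries an elevated nonsynonymous rate so the selection scan
#' has a true signal to find.
#'
#' @param seed Integer seed (default 1234).
#' @return See [synthesize_dataset()].
#' @export
demo_dataset <- function(seed = 1234) {
  nc <- 83
  omega <- rep(0.15, nc)
  omega[c(7, 9, 24, 30, 45, 59, 63, 70, 77)] <- 8
  mainland <- 1:64
  captive <- 41:104
  island <- c(1, 41, 105:113)
  geo <- function(k, q) {
    f <- q * (1 - q)^(seq_len(k) - 1)
    f / sum(f)
  }
  spec <- generator_spec(
    n_pops = 3, copies_per_pop = c(50, 28, 64), length = 3 * nc,
    n_alleles = 113, frequency_model = "explicit",
    explicit_frequencies = list(
      geo(length(mainland), 0.02),
      geo(length(island), 0.15),
      geo(length(captive), 0.02)
    ),
    divergence_steps = 1, omega_profile = omega,
    pop_allele_sets = list(mainland, island, captive),
    pop_labels = c("mainland", "island", "captive"),
    infinite_sites = FALSE, # selected codons substitute recurrently
    seed = seed
  )
  synthesize_dataset(spec)
}
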
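# Diversity and differentiation statistics.

as_seq_chr <- function(x) {
  if (inherits(x, "hap_alignment")) x$sequences else as.character(x)
}

seq_matrix <- function(sequences) {
  sequences <- as_seq_chr(sequences)
  do.call(rbind, strsplit(sequences, ""))
}

#' Pairwise nucleotide difference matrix
#'
#' Hamming distances (counts of differing sites) between all sequence pairs.
#'
#' @param x A `hap_alignment` or character vector of equal-length sequences.
#' @return A symmetric integer matrix of pairwise difference counts.
#' @export
pairwise_differences <- function(x) {
  m <- seq_matrix(x)
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    block <- m[(i + 1):n, , drop = FALSE]
    d[i, (i + 1):n] <- as.integer(rowSums(block != matrix(
      m[i, ], nrow = nrow(block), ncol = ncol(m), byrow = TRUE)))
  }
  d + t(d)
}

#' Number of segregating sites
#'
#' @inheritParams pairwise_differences
#' @return Integer count of polymorphic alignment columns.
#' @export
segregating_sites <- function(x) {
  m <- seq_matrix(x)
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing sites,
#' `pi = mean over all C(n,2) pairs of d_ij / L`, with no sample-size
#' correction (the plain pairwise mean; the related haplotype-diversity
#' statistic does use the n/(n-1) correction, see
#' [haplotype_diversity()]).
#'
#' @inheritParams pairwise_differences
#' @return Per-site nucleotide diversity, a single number.
#' @export
nucleotide_diversity <- function(x) {
  seqs <- as_seq_chr(x)
  n <- length(seqs)
  if (n < 2) stop("insufficient data: need at least 2 sequences", call. = FALSE)
  d <- pairwise_differences(seqs)
  mean(d[upper.tri(d)]) / nchar(seqs[1])
}

# Convert sequences to a matrix of codon indices (rows = sequences).
# Errors on internal stop codons, listing 1-based codon positions.
codon_matrix <- function(x, frame = NULL) {
  seqs <- as_seq_chr(x)
  if (is.null(frame)) frame <- if (inherits(x, "hap_alignment")) x$frame else 0L
  L <- nchar(seqs[1])
  usable <- L - frame
  if (usable < 3 || usable %% 3 != 0) {
    stop(sprintf("frame error: length %d minus offset %d is not divisible by 3",
                 L, frame), call. = FALSE)
  }
  nc <- usable %/% 3
  starts <- frame + seq(1, usable, by = 3)
  tabs <- ng_tables()
  m <- matrix(0L, nrow = length(seqs), ncol = nc)
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[i], starts, starts + 2)
    m[i, ] <- codon_index(cods)
  }
  stop_hits <- which(matrix(tabs$stop[m], nrow = nrow(m)), arr.ind = TRUE)
  if (nrow(stop_hits) > 0) {
    pos <- sort(unique(stop_hits[, 2]))
    stop("frame error: stop codon(s) at codon position(s) ",
         paste(pos, collapse = ", "), call. = FALSE)
  }
  m
}

#' Synonymous and nonsynonymous nucleotide diversity (Nei-Gojobori)
#'
#' Per-pair synonymous/nonsynonymous site counts are averaged over the two
#' sequences; difference counts average all minimal mutational pathways
#' between differing codons (pathways through stop codons excluded). Per
#' pair, `p_s = Sd/S` and `p_a = Nd/N` are Jukes-Cantor corrected,
#' `d = -(3/4) log(1 - 4p/3)`, and averaged over all pairs.
#'
#' @param x A `hap_alignment` (codon-framed) or character vector.
#' @param frame Reading-frame offset; defaults to the alignment's.
#' @return List with `pi_s`, `pi_a` (Jukes-Cantor corrected means),
#'   `pi_s_raw`, `pi_a_raw` (uncorrected means of p_s, p_a).
#' @export
syn_nonsyn_diversity <- function(x, frame = NULL) {
  cm <- codon_matrix(x, frame)
  n <- nrow(cm)
  if (n < 2) stop("insufficient data: need at least 2 sequences", call. = FALSE)
  tabs <- ng_tables()
  syn_sites_per_seq <- rowSums(matrix(tabs$syn_sites[cm], nrow = n))
  total_sites <- 3 * ncol(cm)
  ps <- pa <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      ij <- cbind(cm[i, ], cm[j, ])
      sd_ij <- sum(tabs$sd[ij])
      nd_ij <- sum(tabs$nd[ij])
      S <- (syn_sites_per_seq[i] + syn_sites_per_seq[j]) / 2
      N <- total_sites - S
      ps[k] <- if (S > 0) sd_ij / S else 0
      pa[k] <- if (N > 0) nd_ij / N else 0
    }
  }
  jc <- function(p) {
    if (any(p >= 3 / 4)) {
      bad <- which(p >= 3 / 4)[1]
      stop("correction-undefined error: proportion of differences >= 3/4 for pair ",
           bad, call. = FALSE)
    }
    -3 / 4 * log(1 - 4 * p / 3)
  }
  list(pi_s = mean(jc(ps)), pi_a = mean(jc(pa)),
       pi_s_raw = mean(ps), pi_a_raw = mean(pa))
}

#' Haplotype diversity
#'
#' `HD = (n/(n-1)) (1 - sum x_i^2)` over within-population haplotype
#' frequencies `x_i`: the small-sample-corrected probability that two
#' randomly drawn gene copies carry different haplotypes.
#'
#' @param table A `haplotype_table`.
#' @param population Population label, or `NULL` for the pooled sample.
#' @return Haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(table, population = NULL) {
  counts <- pop_counts(table, population)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("insufficient data: need at least 2 gene copies", call. = FALSE)
  x <- counts / n
  (n / (n - 1)) * (1 - sum(x^2))
}

hd_from_counts <- function(counts) {
  n <- sum(counts)
  x <- counts / n
  (n / (n - 1)) * (1 - sum(x^2))
}

# One fixed-S coalescent replicate: simulate a Kingman genealogy for n tips,
# drop S mutations on branches with probability proportional to branch
# length (each at a fresh site), and return the haplotype diversity of the
# induced partition of tips.
coalescent_hd_replicate <- function(n, S) {
  if (S == 0) return(0)
  # active clades as lists of tip indices, with accrued branch lengths
  clades <- as.list(seq_len(n))
  blen <- numeric(n)
  branches <- vector("list", 2 * n - 2)
  lens <- numeric(2 * n - 2)
  nb <- 0L
  k <- n
  while (k > 1) {
    t <- stats::rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + t
    pick <- sample.int(k, 2)
    i <- pick[1]; j <- pick[2]
    nb <- nb + 1L; branches[[nb]] <- clades[[i]]; lens[nb] <- blen[i]
    nb <- nb + 1L; branches[[nb]] <- clades[[j]]; lens[nb] <- blen[j]
    merged <- c(clades[[i]], clades[[j]])
    clades[[min(i, j)]] <- merged
    blen[min(i, j)] <- 0
    clades[[max(i, j)]] <- NULL
    blen <- blen[-max(i, j)]
    k <- k - 1L
  }
  hit <- sample.int(nb, S, replace = TRUE, prob = lens[seq_len(nb)])
  # haplotype of a tip = set of mutations whose branch covers it
  sig <- matrix(FALSE, nrow = n, ncol = S)
  for (s in seq_len(S)) sig[branches[[hit[s]]], s] <- TRUE
  counts <- table(apply(sig, 1, paste, collapse = ""))
  hd_from_counts(as.numeric(counts))
}

#' Coalescent confidence interval for haplotype diversity
#'
#' Simulates neutral Kingman genealogies for `n` tips, conditioning on the
#' observed number of segregating sites `S` (exactly `S` mutations placed
#' uniformly at random on branches, infinite-sites), computes the haplotype
#' diversity of each simulated sample, and returns percentile bounds.
#'
#' @param n Number of gene copies (tips), at least 2.
#' @param S Observed number of segregating sites.
#' @param reps Number of coalescent replicates (default 10000, minimum 1000).
#' @param seed Integer seed for reproducibility (optional).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hd_confidence_interval <- function(n, S, reps = 10000, seed = NULL, level = 0.95) {
  if (n < 2) stop("insufficient data: need n >= 2", call. = FALSE)
  if (S < 0) stop("S must be non-negative", call. = FALSE)
  if (reps < 1000) stop("reps must be at least 1000", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (S == 0) return(c(lower = 0, upper = 0))
  hd <- vapply(seq_len(reps), function(r) coalescent_hd_replicate(n, S),
               numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(hd, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Full diversity summary for one population at one locus
#'
#' @param alignment A `hap_alignment`.
#' @param popmap Population map data frame.
#' @param population Population label; `NULL` pools all copies.
#' @param ci_reps Coalescent replicates for the HD confidence interval.
#' @param seed Seed for the coalescent simulation.
#' @return An object of class `diversity_stats`: list with `pi`, `pi_s`,
#'   `pi_a`, `hd`, `hd_ci`, `n`, `S`, `H`.
#' @export
diversity_stats <- function(alignment, popmap, population = NULL,
                            ci_reps = 10000, seed = NULL) {
  stopifnot(inherits(alignment, "hap_alignment"))
  if (!is.null(population)) {
    by_pop <- split_by_population(alignment, popmap)
    if (!population %in% names(by_pop)) {
      stop("lookup error: unknown population '", population, "'", call. = FALSE)
    }
    seqs <- by_pop[[population]]
    sub <- hap_alignment(seqs, paste0("c", seq_along(seqs)),
                         locus_type = alignment$locus_type, frame = alignment$frame)
  } else {
    sub <- alignment
  }
  tab <- build_haplotype_table(sub, data.frame(
    copy_id = sub$ids, individual_id = sub$ids,
    population = "pooled", stringsAsFactors = FALSE))
  S <- segregating_sites(sub)
  sn <- syn_nonsyn_diversity(sub)
  structure(
    list(pi = nucleotide_diversity(sub), pi_s = sn$pi_s, pi_a = sn$pi_a,
         pi_s_raw = sn$pi_s_raw, pi_a_raw = sn$pi_a_raw,
         hd = haplotype_diversity(tab),
         hd_ci = hd_confidence_interval(length(sub$sequences), S,
                                        reps = ci_reps, seed = seed),
         n = length(sub$sequences), S = S, H = tab$H,
         population = if (is.null(population)) "pooled" else population),
    class = "diversity_stats"
  )
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf(
    "<diversity_stats> %s: n=%d, H=%d, S=%d\n  pi=%.4f  pi_s=%.4f  pi_a=%.4f  HD=%.3f (95%% CI %.3f-%.3f)\n",
    x$population, x$n, x$H, x$S, x$pi, x$pi_s, x$pi_a, x$hd,
    x$hd_ci[1], x$hd_ci[2]))
  invisible(x)
}

kst_statistic <- function(d, labels, weighting = "size") {
  pops <- unique(labels)
  n <- length(labels)
  within_mean <- function(idx) {
    if (length(idx) < 2) return(0)
    sub <- d[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  K_j <- vapply(pops, function(p) within_mean(which(labels == p)), numeric(1))
  n_j <- vapply(pops, function(p) sum(labels == p), numeric(1))
  w <- if (weighting == "size") n_j / n else {
    pc <- n_j * (n_j - 1) / 2
    pc / sum(pc)
  }
  K_S <- sum(w * K_j)
  K_T <- mean(d[upper.tri(d)])
  list(K_S = K_S, K_T = K_T, K_ST = 1 - K_S / K_T)
}

#' Hudson-Boos-Kaplan K_ST with permutation test
#'
#' `K_ST = 1 - K_S/K_T` where `K_S` is the weighted mean of within-population
#' mean pairwise difference counts and `K_T` the pooled mean. Significance is
#' assessed by permuting population labels with population sizes fixed; the
#' observed arrangement is included in both numerator and denominator
#' (add-one convention), so p-values are never exactly zero. With
#' `n_perm = "exhaustive"` all distinct label assignments are enumerated and
#' the p-value is the exact tail proportion.
#'
#' @param alignment A `hap_alignment`.
#' @param popmap Population map data frame.
#' @param pops Character vector of exactly two population labels.
#' @param n_perm Number of random permutations (default 1000), or
#'   `"exhaustive"` for exact enumeration (small samples only).
#' @param seed Integer seed for the permutations.
#' @param weighting `"size"` (`w_j = n_j/n`, default) or `"pairs"`
#'   (within-pair-count proportional).
#' @return An object of class `kst_result`: list with `K_S`, `K_T`, `K_ST`,
#'   `p_value`, `n_perm`.
#' @export
kst <- function(alignment, popmap, pops, n_perm = 1000, seed = NULL,
                weighting = c("size", "pairs")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(alignment, "hap_alignment"))
  if (length(pops) != 2) stop("exactly two populations required", call. = FALSE)
  popmap <- validate_popmap(popmap)
  pop <- popmap$population[match(alignment$ids, popmap$copy_id)]
  keep <- which(pop %in% pops)
  labels <- pop[keep]
  n_j <- table(factor(labels, levels = pops))
  if (any(n_j < 2)) stop("each population needs at least 2 copies", call. = FALSE)
  d <- pairwise_differences(alignment$sequences[keep])
  if (all(d == 0)) {
    stop("undefined statistic: all sequences identical (K_T = 0)", call. = FALSE)
  }
  obs <- kst_statistic(d, labels, weighting)
  n <- length(labels)
  nA <- sum(labels == pops[1])
  if (identical(n_perm, "exhaustive")) {
    combos <- utils::combn(n, nA)
    stat <- apply(combos, 2, function(ia) {
      lab <- rep(pops[2], n)
      lab[ia] <- pops[1]
      kst_statistic(d, lab, weighting)$K_ST
    })
    p <- mean(stat >= obs$K_ST - 1e-12)
    m <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    b <- 0L
    for (r in seq_len(n_perm)) {
      lab <- sample(labels)
      if (kst_statistic(d, lab, weighting)$K_ST >= obs$K_ST - 1e-12) b <- b + 1L
    }
    p <- (b + 1) / (n_perm + 1)
    m <- n_perm
  }
  structure(
    list(K_S = obs$K_S, K_T = obs$K_T, K_ST = obs$K_ST, p_value = p,
         n_perm = m, pops = pops, weighting = weighting),
    class = "kst_result"
  )
}

#' @export
print.kst_result <- function(x, ...) {
  cat(sprintf("<kst_result> %s vs %s: K_ST = %.4f (K_S = %.3f, K_T = %.3f), p = %.4g [%d perms]\n",
              x$pops[1], x$pops[2], x$K_ST, x$K_S, x$K_T, x$p_value, x$n_perm))
  invisible(x)
}
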
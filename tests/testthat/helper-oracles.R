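# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (plain double loops, exhaustive
# enumeration, numeric series) without touching the package's lookup-table
# code paths.

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

oracle_pi <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + oracle_hamming(seqs[i], seqs[j])
      np <- np + 1
    }
  }
  (tot / np) / nchar(seqs[1])
}

oracle_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# fraction of the 9 single-nucleotide changes that are synonymous
# (stop-producing changes counted as nonsynonymous)
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_aa(alt) != "*" && oracle_aa(alt) == oracle_aa(codon)) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# exhaustive enumeration of all minimal mutational pathways between two
# codons (depth-first over orders of applying the differing positions),
# averaging syn/nonsyn step counts over stop-free pathways
oracle_codon_path <- function(c1, c2, allow_stops = FALSE) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  walk <- function(cur, left) {
    if (length(left) == 0) return(list(c(syn = 0, nonsyn = 0)))
    out <- list()
    for (p in left) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && oracle_aa(nxt) == "*" && nxt != c2) next
      step <- if (oracle_aa(nxt) == oracle_aa(cur)) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, setdiff(left, p))) {
        out <- c(out, list(c(syn = step[1] + tail[1],
                             nonsyn = step[2] + tail[2])))
      }
    }
    out
  }
  res <- walk(c1, left = pos)
  if (length(res) == 0) return(oracle_codon_path(c1, c2, allow_stops = TRUE))
  cm <- do.call(rbind, res)
  c(syn = mean(cm[, 1]), nonsyn = mean(cm[, 2]))
}

oracle_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

# per-codon mean Nd/Sd over all sequence pairs
oracle_sitewise <- function(seqs) {
  cods <- lapply(seqs, oracle_codons)
  nc <- length(cods[[1]])
  n <- length(seqs)
  Nd <- Sd <- numeric(nc)
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      np <- np + 1
      for (c in seq_len(nc)) {
        p <- oracle_codon_path(cods[[i]][c], cods[[j]][c])
        Sd[c] <- Sd[c] + p[["syn"]]
        Nd[c] <- Nd[c] + p[["nonsyn"]]
      }
    }
  }
  list(Nd = Nd / np, Sd = Sd / np)
}

oracle_syn_nonsyn_diversity <- function(seqs) {
  cods <- lapply(seqs, oracle_codons)
  site_s <- vapply(cods, function(cs) sum(vapply(cs, oracle_syn_sites,
                                                 numeric(1))), numeric(1))
  L <- nchar(seqs[1])
  n <- length(seqs)
  ds <- da <- c()
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sd_ij <- nd_ij <- 0
      for (c in seq_along(cods[[i]])) {
        p <- oracle_codon_path(cods[[i]][c], cods[[j]][c])
        sd_ij <- sd_ij + p[["syn"]]
        nd_ij <- nd_ij + p[["nonsyn"]]
      }
      S <- (site_s[i] + site_s[j]) / 2
      N <- L - S
      ds <- c(ds, jc(sd_ij / S))
      da <- c(da, jc(nd_ij / N))
    }
  }
  list(pi_s = mean(ds), pi_a = mean(da))
}

oracle_kst_stat <- function(seqs, labels) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- oracle_hamming(seqs[i], seqs[j])
  }
  pops <- unique(labels)
  Kj <- nj <- numeric(length(pops))
  for (k in seq_along(pops)) {
    idx <- which(labels == pops[k])
    nj[k] <- length(idx)
    sub <- d[idx, idx]
    Kj[k] <- mean(sub[upper.tri(sub)])
  }
  KS <- sum((nj / n) * Kj)
  KT <- mean(d[upper.tri(d)])
  1 - KS / KT
}

# exact permutation p-value over all distinct label assignments
oracle_kst_exact_p <- function(seqs, labels) {
  obs <- oracle_kst_stat(seqs, labels)
  pops <- unique(labels)
  nA <- sum(labels == pops[1])
  combos <- combn(length(seqs), nA)
  stats <- apply(combos, 2, function(ia) {
    lab <- rep(pops[2], length(seqs))
    lab[ia] <- pops[1]
    oracle_kst_stat(seqs, lab)
  })
  mean(stats >= obs - 1e-12)
}

# statistical-parsimony probability via numeric series: solve the JC
# saturation relation for the per-site mutation load, then condition a
# Poisson number of hits on the site showing a difference
oracle_prob_parsimony <- function(j, L) {
  if (j == 0) return(1)
  p <- j / L
  if (p >= 3 / 4) return(0)
  D <- uniroot(function(x) 3 / 4 * (1 - exp(-4 * x / 3)) - p,
               c(1e-12, 100), tol = 1e-14)$root
  ks <- 1:300
  p_diff_given_k <- 3 / 4 * (1 - (-1 / 3)^ks)
  denom <- sum(dpois(ks, D) * p_diff_given_k)
  single <- dpois(1, D) * p_diff_given_k[1] / denom
  single^j
}

oracle_parsimony_limit <- function(L, alpha = 0.95) {
  j <- 0
  while (j < L && oracle_prob_parsimony(j + 1, L) >= alpha) j <- j + 1
  j
}

# expected number of distinct alleles among 2*N0 multinomial founder copies
oracle_founder_expectation <- function(p, n0) {
  sum(1 - (1 - p)^(2 * n0))
}

# scalar re-implementation of one overlapping-generations year: ages
# advance, deaths past the lifespan, newborns from two distinct mature
# parents, one random allele from each
oracle_step_year <- function(age, a1, a2, target, lifespan, maturity) {
  age <- age + 1
  keep <- which(age <= lifespan)
  age <- age[keep]; a1 <- a1[keep]; a2 <- a2[keep]
  mature <- which(age >= maturity)
  while (length(age) < target && length(mature) >= 2) {
    pr <- sample(mature, 2, replace = FALSE)
    g1 <- if (runif(1) < 0.5) a1[pr[1]] else a2[pr[1]]
    g2 <- if (runif(1) < 0.5) a1[pr[2]] else a2[pr[2]]
    age <- c(age, 0); a1 <- c(a1, g1); a2 <- c(a2, g2)
  }
  list(age = age, a1 = a1, a2 = a2)
}

# small helpers for building fixtures ---------------------------------------

stopfree_random_seq <- function(ncodon) {
  cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(cods, ncodon, replace = TRUE), collapse = "")
}

# derive k related sequences by sprinkling random stop-free substitutions
mutate_family <- function(ancestor, k, muts_per_seq = 2) {
  bases <- c("A", "C", "G", "T")
  out <- character(k)
  out[1] <- ancestor
  for (i in seq_len(k - 1)) {
    cur <- out[sample.int(i, 1)]
    for (m in seq_len(muts_per_seq)) {
      repeat {
        pos <- sample.int(nchar(cur), 1)
        b <- sample(setdiff(bases, substr(cur, pos, pos)), 1)
        cand <- cur
        substr(cand, pos, pos) <- b
        cod <- ceiling(pos / 3)
        codon <- substr(cand, 3 * cod - 2, 3 * cod)
        if (oracle_aa(codon) != "*") {
          cur <- cand
          break
        }
      }
    }
    out[i + 1] <- cur
  }
  out
}
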
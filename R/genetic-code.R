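# Codon-level machinery shared by the Nei-Gojobori diversity estimators and
# the sitewise omega scan. Everything is precomputed once per session into
# 64 x 64 lookup tables keyed by codon index, so pairwise sweeps over large
# alignments reduce to vectorised table lookups.

.ng_cache <- new.env(parent = emptyenv())

.codon_alphabet <- function() {
  bases <- c("A", "C", "G", "T")
  as.vector(outer(outer(bases, bases, paste0), bases, paste0))
}

codon_index <- function(codons) {
  match(codons, .codon_alphabet())
}

codon_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

is_stop_codon <- function(codons) {
  codon_aa(codons) == "*"
}

# Fraction of the three possible changes at each codon position that are
# synonymous. Changes creating a stop codon count as nonsynonymous, so that
# synonymous + nonsynonymous sites always sum to 3 per codon.
.codon_syn_sites <- function() {
  codons <- .codon_alphabet()
  bases <- c("A", "C", "G", "T")
  syn <- numeric(64)
  for (i in seq_along(codons)) {
    cod <- codons[i]
    if (is_stop_codon(cod)) {
      syn[i] <- NA_real_
      next
    }
    aa0 <- codon_aa(cod)
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        aa1 <- codon_aa(alt)
        if (!is.na(aa1) && aa1 != "*" && aa1 == aa0) s <- s + 1 / 3
      }
    }
    syn[i] <- s
  }
  names(syn) <- codons
  syn
}

# Average synonymous/nonsynonymous step counts over all minimal mutational
# pathways between two codons. Pathways passing through a stop codon are
# excluded; if every pathway is blocked the average is taken over all of
# them (a rare corner at three-fold differences involving stop neighbours).
.codon_path_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) {
    return(c(syn = 0, nonsyn = 0))
  }
  perms <- if (k == 1L) list(pos) else {
    idx <- .permutations(k)
    lapply(seq_len(nrow(idx)), function(r) pos[idx[r, ]])
  }
  walk <- function(order) {
    cur <- c1
    syn <- 0
    nonsyn <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt != c2 && is_stop_codon(nxt)) {
        return(NULL)
      }
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, logical(1))
  if (any(ok)) res <- res[ok] else res <- lapply(perms, function(o) {
    # all pathways blocked: count steps ignoring the stop constraint
    cur <- c1
    syn <- 0
    nonsyn <- 0
    for (p in o) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  })
  m <- do.call(rbind, res)
  colMeans(m)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  row <- 1L
  for (i in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(k)[-i]
      out[row, ] <- c(i, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# Lazily build and cache the lookup tables.
ng_tables <- function() {
  if (!is.null(.ng_cache$tables)) {
    return(.ng_cache$tables)
  }
  codons <- .codon_alphabet()
  syn_sites <- .codon_syn_sites()
  sd_mat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  stop_mask <- is_stop_codon(codons)
  for (i in 1:64) {
    if (stop_mask[i]) next
    for (j in 1:64) {
      if (stop_mask[j]) next
      if (i == j) {
        sd_mat[i, j] <- 0
        nd_mat[i, j] <- 0
      } else {
        cnt <- .codon_path_counts(codons[i], codons[j])
        sd_mat[i, j] <- cnt[["syn"]]
        nd_mat[i, j] <- cnt[["nonsyn"]]
      }
    }
  }
  .ng_cache$tables <- list(
    codons = codons,
    syn_sites = syn_sites,
    nonsyn_sites = ifelse(is.na(syn_sites), NA_real_, 3 - syn_sites),
    sd = sd_mat,
    nd = nd_mat,
    stop = stop_mask
  )
  .ng_cache$tables
}
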
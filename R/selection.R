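# Counting-based sitewise dN/dS (omega) scan and peptide-binding-region
# mapping. This is a transparent Nei-Gojobori-style surrogate for full
# Bayesian sitewise codon models: it recovers the location of codons with an
# excess of nonsynonymous variation, not posterior omega magnitudes.

#' Sitewise omega scan (counting-based)
#'
#' For every codon, pathway-averaged nonsynonymous (`Nd`) and synonymous
#' (`Sd`) difference counts are accumulated over all sequence pairs, along
#' with mean nonsynonymous/synonymous site counts. `omega` is
#' `(Nd/N_sites)/(Sd/S_sites)`. Codons with `Sd = 0` but `Nd > 0` get
#' `omega = Inf` (and a finite ranking value with `Sd` replaced by 0.5 in
#' `omega_ranking`); codons with no differences have `omega = NA`.
#'
#' @param x A `hap_alignment` (codon-framed) or character vector.
#' @param frame Reading-frame offset; defaults to the alignment's.
#' @return A data frame of class `omega_scan` with columns `codon`
#'   (1-based), `Nd`, `Sd`, `N_sites`, `S_sites`, `omega`, `omega_ranking`,
#'   `positive`, `is_pbr`.
#' @export
sitewise_omega <- function(x, frame = NULL) {
  cm <- codon_matrix(x, frame)
  n <- nrow(cm)
  if (n < 2) stop("insufficient data: need at least 2 sequences", call. = FALSE)
  tabs <- ng_tables()
  nc <- ncol(cm)
  npair <- n * (n - 1) / 2
  Nd <- Sd <- numeric(nc)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ij <- cbind(cm[i, ], cm[j, ])
      Sd <- Sd + tabs$sd[ij]
      Nd <- Nd + tabs$nd[ij]
    }
  }
  Nd <- Nd / npair
  Sd <- Sd / npair
  S_sites <- colMeans(matrix(tabs$syn_sites[cm], nrow = n))
  N_sites <- 3 - S_sites
  pn <- Nd / N_sites
  ps <- Sd / S_sites
  omega <- ifelse(Nd + Sd == 0, NA_real_,
                  ifelse(Sd == 0, Inf, pn / ps))
  omega_ranking <- ifelse(Nd + Sd == 0, NA_real_,
                          (Nd / N_sites) / (ifelse(Sd == 0, 0.5, Sd) / S_sites))
  out <- data.frame(
    codon = seq_len(nc), Nd = Nd, Sd = Sd,
    N_sites = N_sites, S_sites = S_sites,
    omega = omega, omega_ranking = omega_ranking,
    positive = FALSE, is_pbr = NA
  )
  class(out) <- c("omega_scan", "data.frame")
  out
}

#' Mean omega over defined codons
#'
#' @param sites An `omega_scan` data frame from [sitewise_omega()].
#' @param finite_only Drop infinite-omega codons from the mean (default
#'   `FALSE`: infinite values are replaced by their `omega_ranking`
#'   pseudocount value so the mean stays finite).
#' @return Mean omega across codons where omega is defined.
#' @export
mean_omega <- function(sites, finite_only = FALSE) {
  stopifnot(inherits(sites, "omega_scan"))
  om <- sites$omega
  defined <- !is.na(om)
  if (!any(defined)) {
    stop("insufficient data: no codon has a defined omega", call. = FALSE)
  }
  om[defined & !is.finite(om)] <- if (finite_only) NA_real_ else
    sites$omega_ranking[defined & !is.finite(om)]
  mean(om[defined], na.rm = TRUE)
}

#' Flag codons with an excess of nonsynonymous differences
#'
#' Each codon is tested against a permutation null built from the
#' synonymous/nonsynonymous labels of mutation events at all other codons:
#' the codon's event count is held fixed and its labels are redrawn without
#' replacement from the leave-one-out label pool (so a handful of strongly
#' selected codons cannot contaminate their own null). Events per codon are
#' counted as the number of distinct codon states minus one (the
#' parsimony-minimal mutation count), so tightly linked pairwise
#' differences are not double counted; a codon's own labels are its
#' pairwise nonsynonymous fraction applied to that count. A codon is
#' flagged positive when its observed nonsynonymous fraction `Nd/(Nd+Sd)`
#' exceeds the 95th percentile of its null and its omega exceeds 1.
#'
#' @inheritParams sitewise_omega
#' @param n_perm Number of label shuffles (minimum 100).
#' @param seed Integer seed.
#' @return The `omega_scan` data frame with the `positive` column filled in.
#' @export
flag_positive_sites <- function(x, n_perm = 1000, seed = NULL, frame = NULL) {
  if (n_perm < 100) {
    stop("configuration error: n_perm must be at least 100", call. = FALSE)
  }
  scan <- sitewise_omega(x, frame)
  cm <- codon_matrix(x, frame)
  # parsimony-minimal event count per codon
  units <- apply(cm, 2, function(col) length(unique(col)) - 1L)
  n_units <- sum(units)
  if (n_units == 0) {
    return(scan)
  }
  f_codon <- ifelse(scan$Nd + scan$Sd > 0,
                    scan$Nd / (scan$Nd + scan$Sd), 0)
  ones <- units * f_codon
  total_ones <- sum(ones)
  if (!is.null(seed)) set.seed(seed)
  has_diff <- units > 0
  q95 <- rep(NA_real_, nrow(scan))
  for (c in which(has_diff)) {
    ones_out <- round(total_ones - ones[c])
    zeros_out <- round(n_units - units[c] - ones_out)
    if (ones_out + zeros_out < units[c]) next
    draw <- stats::rhyper(n_perm, ones_out, zeros_out, units[c]) / units[c]
    q95[c] <- stats::quantile(draw, 0.95, names = FALSE)
  }
  f_obs <- ifelse(has_diff, scan$Nd / (scan$Nd + scan$Sd), NA_real_)
  scan$positive <- !is.na(scan$omega) & scan$omega > 1 &
    !is.na(f_obs) & !is.na(q95) & f_obs > q95
  scan
}

#' Construct a peptide-binding-region annotation
#'
#' @param reference_id Identifier of the annotated reference protein.
#' @param reference_sequence Amino-acid sequence of the reference (string).
#' @param pbr_positions Integer vector of 1-based residue indices forming
#'   the peptide-binding region on the reference.
#' @return An object of class `pbr_annotation`.
#' @export
pbr_annotation <- function(reference_id, reference_sequence, pbr_positions) {
  reference_sequence <- toupper(as.character(reference_sequence))
  pbr_positions <- sort(unique(as.integer(pbr_positions)))
  if (any(pbr_positions < 1 | pbr_positions > nchar(reference_sequence))) {
    stop("pbr_positions out of range for the reference sequence", call. = FALSE)
  }
  structure(
    list(reference_id = reference_id,
         reference_sequence = reference_sequence,
         pbr_positions = pbr_positions),
    class = "pbr_annotation"
  )
}

#' Read a PBR annotation from a reference FASTA and positions TSV
#'
#' @param fasta_path Amino-acid FASTA with one reference record.
#' @param positions_path TSV with columns `reference_id`, `residue_index`.
#' @return A `pbr_annotation`.
#' @export
read_pbr_annotation <- function(fasta_path, positions_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  if (length(aa) != 1) stop("reference FASTA must contain exactly one record",
                            call. = FALSE)
  pos <- utils::read.delim(positions_path, stringsAsFactors = FALSE)
  if (!all(c("reference_id", "residue_index") %in% names(pos))) {
    stop("positions TSV needs columns reference_id, residue_index", call. = FALSE)
  }
  id <- vapply(strsplit(names(aa), "[ \t]"), `[`, character(1), 1L)
  pbr_annotation(id, as.character(aa[[1]]), pos$residue_index)
}

# Modal (consensus) translation of a codon alignment, as an AA string.
consensus_translation <- function(x, frame = NULL) {
  cm <- codon_matrix(x, frame)
  codons <- .codon_alphabet()
  cons <- apply(cm, 2, function(col) {
    tb <- table(col)
    as.integer(names(tb)[which.max(tb)])
  })
  paste(codon_aa(codons[cons]), collapse = "")
}

#' Map PBR residues from an annotated reference onto query codons
#'
#' The consensus translation of the query codon alignment is globally
#' aligned to the reference protein (match +1, mismatch 0, gap -1), and the
#' reference's PBR residue indices are projected through the alignment onto
#' 1-based query codon indices. PBR positions falling on alignment gaps are
#' reported in the `unmapped` attribute.
#'
#' @param x A `hap_alignment` (codon-framed) or character vector.
#' @param annotation A `pbr_annotation`.
#' @param frame Reading-frame offset; defaults to the alignment's.
#' @param max_gap_fraction Maximum tolerated fraction of reference residues
#'   aligned to gaps before a homology error is raised (default 0.2).
#' @return Logical vector over query codons (`TRUE` = PBR), with attributes
#'   `unmapped` (reference PBR residues with no query partner) and
#'   `alignment_score`.
#' @export
map_pbr <- function(x, annotation, frame = NULL, max_gap_fraction = 0.2) {
  stopifnot(inherits(annotation, "pbr_annotation"))
  query <- consensus_translation(x, frame)
  alphabet <- unique(c(strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]],
                       strsplit(paste0(query, annotation$reference_sequence), "")[[1]]))
  sm <- matrix(0, length(alphabet), length(alphabet),
               dimnames = list(alphabet, alphabet))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(annotation$reference_sequence),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qi <- ri <- 0L
  ref_to_query <- rep(NA_integer_, nchar(annotation$reference_sequence))
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qi <- qi + 1L
    if (ra[k] != "-") {
      ri <- ri + 1L
      if (qa[k] != "-") ref_to_query[ri] <- qi
    }
  }
  gap_frac <- mean(is.na(ref_to_query))
  if (gap_frac > max_gap_fraction) {
    stop(sprintf("homology error: %.0f%% of reference residues align to gaps",
                 100 * gap_frac), call. = FALSE)
  }
  mapped <- ref_to_query[annotation$pbr_positions]
  is_pbr <- rep(FALSE, nchar(query))
  is_pbr[mapped[!is.na(mapped)]] <- TRUE
  attr(is_pbr, "unmapped") <- annotation$pbr_positions[is.na(mapped)]
  attr(is_pbr, "alignment_score") <- Biostrings::score(aln)
  is_pbr
}

#' Attach PBR flags to an omega scan
#'
#' @param scan An `omega_scan` data frame.
#' @param is_pbr Logical vector from [map_pbr()] (same codon count).
#' @return The scan with `is_pbr` filled in.
#' @export
annotate_pbr <- function(scan, is_pbr) {
  stopifnot(inherits(scan, "omega_scan"), length(is_pbr) == nrow(scan))
  scan$is_pbr <- as.logical(is_pbr)
  scan
}
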
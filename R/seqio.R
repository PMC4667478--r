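# Sequence input/output, validation and haplotype tables.

#' Construct a haplotype alignment
#'
#' An alignment here is a set of equal-length, ungapped, phased haplotype
#' sequences (one record per gene copy), optionally with a reading-frame
#' offset for codon-based analyses.
#'
#' @param sequences Character vector of DNA sequences (A/C/G/T only).
#' @param ids Character vector of unique record identifiers.
#' @param locus_type Either `"nuclear-codon"` (two copies per diploid
#'   individual) or `"mitochondrial-codon"` (one copy per individual).
#' @param frame Reading-frame offset in `{0, 1, 2}`: number of leading bases
#'   to skip before the first complete codon.
#' @return An object of class `hap_alignment`.
#' @export
hap_alignment <- function(sequences, ids = NULL,
                          locus_type = c("nuclear-codon", "mitochondrial-codon"),
                          frame = 0L) {
  locus_type <- match.arg(locus_type)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) {
    stop("empty input: alignment contains no sequences", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("alignment-length error: records have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  if (lens[1] == 0L) stop("empty input: zero-length sequences", call. = FALSE)
  bad <- regexpr("[^ACGT]", sequences)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf(
      "validation error: record '%s' contains non-ACGT symbol '%s' at position %d",
      ids[i], substr(sequences[i], bad[i], bad[i]), bad[i]
    ), call. = FALSE)
  }
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  structure(
    list(sequences = sequences, ids = ids, length = lens[1],
         locus_type = locus_type, frame = as.integer(frame)),
    class = "hap_alignment"
  )
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d sequences x %d bp (%s, frame %d)\n",
              length(x$sequences), x$length, x$locus_type, x$frame))
  invisible(x)
}

#' Read an ungapped haplotype FASTA file
#'
#' @param path Path to a FASTA file of equal-length, gap-free sequences.
#' @inheritParams hap_alignment
#' @return A `hap_alignment`.
#' @export
read_fasta <- function(path, locus_type = c("nuclear-codon", "mitochondrial-codon"),
                       frame = 0L) {
  locus_type <- match.arg(locus_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty input: no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  hap_alignment(as.character(set), ids, locus_type = locus_type, frame = frame)
}

#' Write an alignment to FASTA
#'
#' @param alignment A `hap_alignment`.
#' @param path Output file path.
#' @export
write_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "hap_alignment"))
  set <- Biostrings::DNAStringSet(alignment$sequences)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a population map
#'
#' A population map is a 3-column TSV (`copy_id`, `individual_id`,
#' `population`) assigning each gene copy to an individual and a population.
#'
#' @param path Path to a TSV file with a header line.
#' @return A data frame with columns `copy_id`, `individual_id`, `population`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pm <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("copy_id", "individual_id", "population")
  if (!all(need %in% names(pm))) {
    stop("population map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_popmap(pm[, need])
}

validate_popmap <- function(popmap) {
  popmap <- as.data.frame(popmap, stringsAsFactors = FALSE)
  if (anyDuplicated(popmap$copy_id)) {
    stop("population map assigns some copy_id more than once", call. = FALSE)
  }
  popmap
}

#' Write a population map to TSV
#' @param popmap A population-map data frame.
#' @param path Output file path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a haplotype table from an alignment and population map
#'
#' Collapses gene copies into unique haplotypes (exact string identity) and
#' tabulates per-population copy counts and frequencies.
#'
#' @param alignment A `hap_alignment`.
#' @param popmap A population-map data frame (see [read_popmap()]).
#' @return An object of class `haplotype_table` with elements `haplotypes`
#'   (data frame: `hap_id`, `sequence`, one count column per population,
#'   `total`), `counts` (matrix haplotypes x populations), `H` (number of
#'   unique haplotypes), `N` (total gene copies), `populations`.
#' @export
build_haplotype_table <- function(alignment, popmap) {
  stopifnot(inherits(alignment, "hap_alignment"))
  popmap <- validate_popmap(popmap)
  missing <- setdiff(alignment$ids, popmap$copy_id)
  if (length(missing) > 0) {
    stop("mapping error: records missing from population map: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  pop <- popmap$population[match(alignment$ids, popmap$copy_id)]
  pops <- sort(unique(pop))
  uniq <- sort(unique(alignment$sequences))
  hap_id <- sprintf("H%02d", seq_along(uniq))
  counts <- matrix(0L, nrow = length(uniq), ncol = length(pops),
                   dimnames = list(hap_id, pops))
  idx <- match(alignment$sequences, uniq)
  for (k in seq_along(idx)) {
    counts[idx[k], pop[k]] <- counts[idx[k], pop[k]] + 1L
  }
  total <- rowSums(counts)
  haps <- data.frame(hap_id = hap_id, sequence = uniq,
                     stringsAsFactors = FALSE)
  for (p in pops) haps[[p]] <- counts[, p]
  haps$total <- total
  structure(
    list(haplotypes = haps, counts = counts, H = length(uniq),
         N = length(alignment$sequences), populations = pops,
         length = alignment$length, popmap = popmap),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> H = %d haplotypes among N = %d gene copies\n",
              x$H, x$N))
  cat("  per population:",
      paste(sprintf("%s n=%d", x$populations, colSums(x$counts)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Haplotype frequencies for one population (or pooled)
#'
#' @param table A `haplotype_table`.
#' @param population A population label, or `NULL` for the pooled sample.
#' @return Named numeric vector of frequencies over haplotypes with at least
#'   one copy in the chosen population (sums to 1).
#' @export
allele_frequencies <- function(table, population = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  counts <- pop_counts(table, population)
  counts <- counts[counts > 0]
  counts / sum(counts)
}

pop_counts <- function(table, population = NULL) {
  if (is.null(population)) {
    return(rowSums(table$counts))
  }
  if (!population %in% table$populations) {
    stop("lookup error: unknown population '", population, "'", call. = FALSE)
  }
  table$counts[, population]
}

#' Number of haplotypes shared between two populations
#'
#' @param table A `haplotype_table`.
#' @param popA,popB Population labels present in the table.
#' @return Integer count of haplotypes with at least one copy in each.
#' @export
shared_haplotypes <- function(table, popA, popB) {
  a <- pop_counts(table, popA)
  b <- pop_counts(table, popB)
  sum(a > 0 & b > 0)
}

#' Unique haplotypes per gene copy
#'
#' The ratio H/N: a high value means most haplotypes are carried by only a
#' few copies, a hallmark of hyper-polymorphic loci.
#'
#' @param table A `haplotype_table`.
#' @return H / N as a single number.
#' @export
haplotypes_per_copy <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  table$H / table$N
}

#' Export a haplotype table as TSV
#' @param table A `haplotype_table`.
#' @param path Output file path.
#' @export
write_haplotype_table <- function(table, path) {
  utils::write.table(table$haplotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Expand a haplotype table back into the multiset of copy sequences.
expand_haplotypes <- function(table, population = NULL) {
  counts <- pop_counts(table, population)
  rep(table$haplotypes$sequence, counts)
}

# Split an alignment into per-population sub-alignments of sequence strings.
split_by_population <- function(alignment, popmap) {
  popmap <- validate_popmap(popmap)
  pop <- popmap$population[match(alignment$ids, popmap$copy_id)]
  if (anyNA(pop)) {
    stop("mapping error: records missing from population map", call. = FALSE)
  }
  split(alignment$sequences, pop)
}
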
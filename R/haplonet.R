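# Statistical-parsimony (TCS-style) haplotype networks.

#' Probability of a parsimonious connection
#'
#' Probability that `j` observed differences between two sequences of length
#' `L` arose without superimposed changes (each differing site mutated
#' exactly once), so that the `j`-step connection is the true mutational
#' path. Computed under a Jukes-Cantor multiple-hit model: the per-site
#' expected number of mutations `D` is estimated from the observed
#' proportion of differences `p = j/L` by `D = -(3/4) log(1 - 4p/3)`;
#' mutations per site are Poisson(`D`), and a site showing a difference is a
#' single hit with probability `D e^-D / ((3/4)(1 - e^{-4D/3}))`. The
#' parsimony probability is that quantity to the power `j`.
#'
#' @param j Number of observed differences (non-negative integer).
#' @param L Sequence length in sites.
#' @return Probability in `[0, 1]`, decreasing in `j`.
#' @export
prob_parsimony <- function(j, L) {
  if (L < 1) stop("input error: L must be at least 1", call. = FALSE)
  vapply(j, function(jj) {
    if (jj == 0) return(1)
    p <- jj / L
    if (p >= 3 / 4) return(0)
    D <- -3 / 4 * log(1 - 4 * p / 3)
    p_single <- (D * exp(-D)) / ((3 / 4) * (1 - exp(-4 * D / 3)))
    p_single^jj
  }, numeric(1))
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` for which the probability of a
#' parsimonious connection (see [prob_parsimony()]) is at least `alpha`.
#' Pairs of haplotypes further apart than this limit are not connected in
#' the network at the chosen confidence level.
#'
#' @param L Sequence length in sites.
#' @param alpha Connection confidence (default 0.95).
#' @return Integer step limit (possibly 0).
#' @export
parsimony_limit <- function(L, alpha = 0.95) {
  if (L < 1) stop("input error: L must be at least 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  j <- 0L
  while (j < L && prob_parsimony(j + 1L, L) >= alpha) j <- j + 1L
  j
}

#' Network construction settings
#'
#' @param alpha Connection confidence in (0, 1); default 0.95.
#' @param tie_break Tie-break rule identifier (only `"frequency"` is
#'   implemented: among equal-distance candidate connections, the pair whose
#'   more frequent member is larger connects first, remaining ties broken
#'   lexicographically by haplotype id).
#' @return A list of class `network_config`.
#' @export
network_config <- function(alpha = 0.95, tie_break = "frequency") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(alpha = alpha, tie_break = tie_break),
            class = "network_config")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Minimal mutational path between two sequences: mutate differing sites in
# ascending position order. Returns the d-1 intermediate sequences.
intermediate_path <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  pos <- which(av != bv)
  if (length(pos) <= 1) return(character(0))
  out <- character(length(pos) - 1)
  cur <- av
  for (k in seq_len(length(pos) - 1)) {
    cur[pos[k]] <- bv[pos[k]]
    out[k] <- paste(cur, collapse = "")
  }
  out
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are considered in order of increasing mutational
#' distance; a pair is connected while its distance does not exceed the
#' parsimony limit, unless the two haplotypes are already joined through the
#' graph by a path no longer than that distance. Connections at distance
#' `d > 1` insert `d - 1` inferred intermediate haplotypes (count zero)
#' along the minimal path mutating differing sites in ascending position
#' order; inferred intermediates whose sequence matches an existing node
#' are reused. Every edge in the result spans exactly one mutation.
#'
#' @param table A `haplotype_table` with at least 2 haplotypes.
#' @param config A `network_config`.
#' @return An object of class `haplo_network`: list with `graph` (igraph),
#'   `nodes` (data frame: `id`, `sequence`, `inferred`, per-population
#'   counts, `total`), `parsimony_limit`, `alpha`, `components`.
#' @export
build_network <- function(table, config = network_config()) {
  stopifnot(inherits(table, "haplotype_table"), inherits(config, "network_config"))
  if (table$H < 2) stop("need at least 2 haplotypes", call. = FALSE)
  limit <- parsimony_limit(table$length, config$alpha)
  haps <- table$haplotypes
  node_seq <- haps$sequence
  node_id <- haps$hap_id
  node_inferred <- rep(FALSE, length(node_id))
  edges <- matrix(character(0), ncol = 2)
  n_inferred <- 0L

  find_or_add <- function(sq) {
    hit <- match(sq, node_seq)
    if (!is.na(hit)) return(hit)
    n_inferred <<- n_inferred + 1L
    node_seq <<- c(node_seq, sq)
    node_id <<- c(node_id, sprintf("I%02d", n_inferred))
    node_inferred <<- c(node_inferred, TRUE)
    length(node_seq)
  }
  add_edge <- function(i, j) {
    a <- node_id[i]; b <- node_id[j]
    e <- sort(c(a, b))
    if (nrow(edges) == 0 || !any(edges[, 1] == e[1] & edges[, 2] == e[2])) {
      edges <<- rbind(edges, e)
    }
  }
  graph_now <- function() {
    igraph::graph_from_data_frame(
      as.data.frame(edges, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = node_id, stringsAsFactors = FALSE))
  }

  # candidate pairs among observed haplotypes, ordered by distance then
  # tie-break (higher max frequency first, then lexicographic ids)
  H <- table$H
  pr <- t(utils::combn(H, 2))
  d <- apply(pr, 1, function(r) hamming(haps$sequence[r[1]], haps$sequence[r[2]]))
  maxfreq <- pmax(haps$total[pr[, 1]], haps$total[pr[, 2]])
  ord <- order(d, -maxfreq, haps$hap_id[pr[, 1]], haps$hap_id[pr[, 2]])
  for (k in ord) {
    dk <- d[k]
    if (dk == 0 || dk > limit) next
    i <- pr[k, 1]; j <- pr[k, 2]
    g <- graph_now()
    cur <- suppressWarnings(igraph::distances(g, v = node_id[i], to = node_id[j]))
    if (is.finite(cur[1, 1]) && cur[1, 1] <= dk) next
    mids <- intermediate_path(haps$sequence[i], haps$sequence[j])
    chain <- c(i, vapply(mids, find_or_add, integer(1), USE.NAMES = FALSE), j)
    for (s in seq_len(length(chain) - 1)) add_edge(chain[s], chain[s + 1])
  }

  counts <- matrix(0L, nrow = length(node_id), ncol = length(table$populations),
                   dimnames = list(node_id, table$populations))
  counts[seq_len(H), ] <- table$counts
  nodes <- data.frame(id = node_id, sequence = node_seq,
                      inferred = node_inferred, stringsAsFactors = FALSE)
  for (p in table$populations) nodes[[p]] <- counts[, p]
  nodes$total <- rowSums(counts)
  g <- graph_now()
  for (p in table$populations) {
    g <- igraph::set_vertex_attr(g, p, value = counts[, p])
  }
  g <- igraph::set_vertex_attr(g, "inferred", value = node_inferred)
  g <- igraph::set_vertex_attr(g, "sequence", value = node_seq)
  structure(
    list(graph = g, nodes = nodes, parsimony_limit = limit,
         alpha = config$alpha,
         components = igraph::components(g)$no),
    class = "haplo_network"
  )
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf(
    "<haplo_network> %d nodes (%d inferred), %d edges, %d component(s); parsimony limit %d steps at %.0f%%\n",
    nrow(x$nodes), sum(x$nodes$inferred), igraph::ecount(x$graph),
    x$components, x$parsimony_limit, 100 * x$alpha))
  invisible(x)
}

resolve_group <- function(network, group) {
  nodes <- network$nodes
  if (length(group) == 1 && group %in% setdiff(names(nodes),
      c("id", "sequence", "inferred", "total"))) {
    ids <- nodes$id[nodes[[group]] > 0]
  } else {
    ids <- intersect(group, nodes$id)
  }
  if (length(ids) == 0) {
    stop("group resolves to no nodes in the network", call. = FALSE)
  }
  ids
}

#' Minimum mutational separation between two groups of haplotypes
#'
#' Shortest-path distance in mutational steps (unit edges, counting through
#' inferred intermediates) minimised over all cross-group node pairs.
#'
#' @param network A `haplo_network`.
#' @param groupA,groupB Population labels, or character vectors of node ids.
#' @return Integer number of mutational steps (0 if the groups overlap).
#' @export
group_separation <- function(network, groupA, groupB) {
  a <- resolve_group(network, groupA)
  b <- resolve_group(network, groupB)
  if (length(intersect(a, b)) > 0) return(0L)
  d <- suppressWarnings(igraph::distances(network$graph, v = a, to = b))
  md <- min(d)
  if (!is.finite(md)) {
    stop(sprintf(
      "disconnected error: groups lie in different components (parsimony limit %d steps)",
      network$parsimony_limit), call. = FALSE)
  }
  as.integer(md)
}

#' Export a haplotype network to GraphML
#'
#' Node attributes carry per-population counts and the inferred flag so the
#' network can be drawn downstream.
#'
#' @param network A `haplo_network`.
#' @param path Output file path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Node and edge tables of a haplotype network
#'
#' @param network A `haplo_network`.
#' @return List with `nodes` and `edges` data frames.
#' @export
network_tables <- function(network) {
  el <- igraph::as_edgelist(network$graph)
  list(nodes = network$nodes,
       edges = data.frame(from = el[, 1], to = el[, 2],
                          stringsAsFactors = FALSE))
}
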
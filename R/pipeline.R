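# End-to-end orchestration: stats -> kst -> scan -> network -> bottleneck,
# with a run manifest recording seeds and a config hash so runs are
# reproducible and distinguishable.

#' Pipeline run configuration
#'
#' @param fasta Path to the haplotype FASTA (or `NULL` when `alignment` is
#'   given directly).
#' @param popmap Path to the population-map TSV (or a data frame).
#' @param locus_type,frame Locus definition (see [hap_alignment()]).
#' @param alignment Optional in-memory `hap_alignment` (overrides `fasta`).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed for all stochastic stages.
#' @param n_perm Permutations for K_ST and the positive-site scan.
#' @param ci_reps Coalescent replicates for HD confidence intervals.
#' @param pbr Optional `pbr_annotation` for the selection scan.
#' @param bottleneck_population Population whose allele frequencies seed the
#'   bottleneck stage (default: the first population).
#' @param bottleneck_founders,bottleneck_growth_rates,bottleneck_years
#'   Scenario grid for the bottleneck stage (vectors; `bottleneck_years`
#'   aligned with the growth rates).
#' @param bottleneck_iterations Iterations per bottleneck scenario.
#' @param census_cap Census cap for the bottleneck simulator.
#' @param network_alpha Connection confidence for the haplotype network.
#' @param stages Character vector of stages to run, a subset of
#'   `c("stats", "kst", "scan", "network", "bottleneck")`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fasta = NULL, popmap = NULL,
                       locus_type = "nuclear-codon", frame = 0L,
                       alignment = NULL, out_dir = tempfile("mhcdrift_run_"),
                       seed = 1L, n_perm = 1000L, ci_reps = 2000L,
                       pbr = NULL, bottleneck_population = NULL,
                       bottleneck_founders = c(10L, 100L),
                       bottleneck_growth_rates = c(0.10, 0.20, 0.50),
                       bottleneck_years = c(100L, 60L, 34L),
                       bottleneck_iterations = 1000L,
                       census_cap = 50000L, network_alpha = 0.95,
                       stages = c("stats", "kst", "scan", "network", "bottleneck")) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dump <- utils::capture.output(utils::str(
    config[setdiff(names(config), "alignment")], give.attr = FALSE))
  writeLines(dump, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: per-population diversity statistics, pairwise K_ST
#' permutation tests over all population pairs, the sitewise omega scan
#' (with optional PBR annotation), haplotype-network construction, and the
#' bottleneck simulation seeded with one population's observed allele
#' frequencies. Each stage writes a TSV summary into `config$out_dir`; a
#' `manifest.json` records package version, seeds and a config hash. A stage
#' failure aborts with the stage name; outputs of earlier stages remain.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list of in-memory stage results (`stats`, `kst`,
#'   `scan`, `network`, `bottleneck`, `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  aln <- stage("input", {
    if (!is.null(config$alignment)) config$alignment else
      read_fasta(config$fasta, locus_type = config$locus_type,
                 frame = config$frame)
  })
  pm <- stage("input", {
    if (is.data.frame(config$popmap)) validate_popmap(config$popmap) else
      read_popmap(config$popmap)
  })
  tab <- build_haplotype_table(aln, pm)
  out <- list()

  if ("stats" %in% config$stages) {
    out$stats <- stage("stats", {
      rows <- lapply(c(as.list(tab$populations), list(NULL)), function(p) {
        st <- diversity_stats(aln, pm, p, ci_reps = config$ci_reps,
                              seed = config$seed)
        data.frame(population = st$population, n = st$n, H = st$H, S = st$S,
                   pi = st$pi, pi_s = st$pi_s, pi_a = st$pi_a, hd = st$hd,
                   hd_lower = st$hd_ci[1], hd_upper = st$hd_ci[2])
      })
      df <- do.call(rbind, rows)
      utils::write.table(df, file.path(config$out_dir, "stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      df
    })
  }

  if ("kst" %in% config$stages) {
    out$kst <- stage("kst", {
      pairs <- utils::combn(tab$populations, 2)
      rows <- lapply(seq_len(ncol(pairs)), function(k) {
        r <- kst(aln, pm, pairs[, k], n_perm = config$n_perm,
                 seed = config$seed + k)
        data.frame(popA = pairs[1, k], popB = pairs[2, k], K_S = r$K_S,
                   K_T = r$K_T, K_ST = r$K_ST, p_value = r$p_value,
                   n_perm = r$n_perm)
      })
      df <- do.call(rbind, rows)
      utils::write.table(df, file.path(config$out_dir, "kst.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      df
    })
  }

  if ("scan" %in% config$stages) {
    out$scan <- stage("scan", {
      sc <- flag_positive_sites(aln, n_perm = config$n_perm,
                                seed = config$seed)
      if (!is.null(config$pbr)) {
        sc <- annotate_pbr(sc, map_pbr(aln, config$pbr))
      }
      utils::write.table(sc, file.path(config$out_dir, "scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sc
    })
  }

  if ("network" %in% config$stages) {
    out$network <- stage("network", {
      net <- build_network(tab, network_config(alpha = config$network_alpha))
      write_graphml(net, file.path(config$out_dir, "network.graphml"))
      tabs <- network_tables(net)
      utils::write.table(tabs$nodes, file.path(config$out_dir, "network_nodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(tabs$edges, file.path(config$out_dir, "network_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      net
    })
  }

  if ("bottleneck" %in% config$stages) {
    out$bottleneck <- stage("bottleneck", {
      popn <- if (is.null(config$bottleneck_population))
        tab$populations[1] else config$bottleneck_population
      freqs <- allele_frequencies(tab, popn)
      rows <- list()
      k <- 0L
      for (n0 in config$bottleneck_founders) {
        for (gi in seq_along(config$bottleneck_growth_rates)) {
          k <- k + 1L
          res <- run_scenario(bottleneck_config(
            freqs, founders = n0,
            growth_rate = config$bottleneck_growth_rates[gi],
            years = config$bottleneck_years[gi],
            iterations = config$bottleneck_iterations,
            census_cap = config$census_cap,
            seed = config$seed + 100L + k))
          rows[[k]] <- data.frame(
            population = popn, founders = n0,
            growth_rate = config$bottleneck_growth_rates[gi],
            years = config$bottleneck_years[gi],
            source_alleles = length(freqs),
            mean_alleles = res$mean_alleles, se = res$se,
            extinct = res$extinct)
        }
      }
      df <- do.call(rbind, rows)
      utils::write.table(df, file.path(config$out_dir, "bottleneck.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      df
    })
  }

  manifest <- list(
    package = "mhcdrift",
    version = as.character(utils::packageVersion("mhcdrift")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = config$stages,
    n_sequences = length(aln$sequences),
    alignment_length = aln$length,
    populations = tab$populations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
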
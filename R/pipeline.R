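# End-to-end pipeline runners. These compose the reading, graph, clustering
# and rhythm operations into file-in/file-out workflows; the shell wrapper in
# inst/cli/circanet.R only parses arguments and calls these functions.
# Progress and summaries go to message() (stderr); reports go to files.

#' Build and report phase-coherent clusters from files
#'
#' Reads a reaction table and a phase table, builds the reaction graph,
#' clusters the phased gene-reaction nodes at the given `lambda` and cut
#' height `h`, and writes the report files into `out_dir`:
#' `network_summary.tsv` (component sizes), `clusters.tsv` (membership),
#' `cluster_summary.tsv` (ranked cluster statistics), `enrichment.tsv`
#' (per-cluster pathway enrichment), one Newick tree per multi-node
#' component and `itol_phases.txt` (leaf colour-strip annotation on the 24 h
#' colour wheel).
#'
#' @param reaction_file,phase_file Input TSV paths.
#' @param out_dir Output directory (created if needed).
#' @param lambda Phase-penalty weight (default 1).
#' @param h Tree-cut height (default 12).
#' @param currency Currency metabolites excluded from connectivity.
#' @param min_report_size Reporting threshold for printed summaries.
#' @return The `phase_clusters` object, invisibly.
#' @export
run_build_cluster <- function(reaction_file, phase_file, out_dir,
                              lambda = 1, h = 12,
                              currency = default_currency_metabolites(),
                              min_report_size = 10) {
  records <- read_reaction_table(reaction_file)
  phases <- read_phase_table(phase_file)
  network <- build_reaction_graph(records, currency = currency)
  nodes <- gene_reaction_nodes(records, phases)
  if (nrow(nodes) == 0) {
    stop("no gene-reaction node carries a phase; nothing to cluster",
         call. = FALSE)
  }
  fit <- cluster_phase_coherent(nodes, network, lambda = lambda, h = h,
                                records = records,
                                min_report_size = min_report_size)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- component_sizes(network)
  readr::write_tsv(sizes, file.path(out_dir, "network_summary.tsv"),
                   progress = FALSE)
  write_cluster_table(fit, file.path(out_dir, "clusters.tsv"))
  readr::write_tsv(fit$clusters, file.path(out_dir, "cluster_summary.tsv"),
                   progress = FALSE)
  if (!is.null(fit$enrichment)) {
    readr::write_tsv(fit$enrichment, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }
  export_newick(fit, out_dir)
  write_itol_phase_annotation(fit, file.path(out_dir, "itol_phases.txt"))

  dropped <- attr(nodes, "dropped_genes")
  message("components: ", nrow(sizes), " (sizes ",
          paste(utils::head(sizes$size, 5), collapse = ", "),
          if (nrow(sizes) > 5) ", ..." else "", ")")
  message("dropped unphased genes: ", length(dropped))
  message("clusters: ", nrow(fit$clusters), "; largest ",
          max(fit$clusters$n_members), " members")
  invisible(fit)
}

#' Detect rhythmic features from files
#'
#' Reads an expression/intensity matrix and its sample sheet, runs the
#' per-condition g-test with dual-condition selection, estimates the overall
#' FDR by permutation, and writes `rhythm_calls.tsv` into `out_dir`.
#'
#' @param expr_file,samples_file Input TSV paths.
#' @param out_dir Output directory (created if needed).
#' @param dominant_period Period of interest in hours (default 24).
#' @param cutoff Strict g-test p-value cutoff (default 0.3).
#' @param n_perm Permutations for the FDR estimate (default 1000).
#' @param seed Integer seed for the permutations.
#' @return A list with `calls` (per-feature tibble) and `fdr` (one-row
#'   tibble), invisibly.
#' @export
run_detect_rhythms <- function(expr_file, samples_file, out_dir,
                               dominant_period = 24, cutoff = 0.3,
                               n_perm = 1000, seed = 1L) {
  expr <- read_expression_matrix(expr_file)
  samples <- read_sample_sheet(samples_file)
  calls <- detect_rhythms(expr, samples, dominant_period = dominant_period,
                          cutoff = cutoff)
  fdr <- permutation_fdr(expr, samples, dominant_period = dominant_period,
                         cutoff = cutoff, n_perm = n_perm, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(calls, file.path(out_dir, "rhythm_calls.tsv"),
                   progress = FALSE)
  message(fdr$n_observed, " feature(s) called circadian; permutation FDR = ",
          signif(fdr$fdr, 3))
  invisible(list(calls = calls, fdr = fdr))
}

#' Write a simulated reaction network to files
#'
#' @param out_dir Output directory; writes `reactions.tsv`, `phases.tsv`
#'   and `truth.tsv` in the dialects read back by [read_reaction_table()]
#'   and [read_phase_table()].
#' @param ... Passed to [simulate_reaction_network()].
#' @return The simulation list, invisibly.
#' @export
run_simulate_network <- function(out_dir, ...) {
  sim <- simulate_reaction_network(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_reaction_table(sim$reactions, file.path(out_dir, "reactions.tsv"))
  readr::write_tsv(sim$phases, file.path(out_dir, "phases.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  invisible(sim)
}

#' Write a simulated time-series experiment to files
#'
#' @param out_dir Output directory; writes `expr.tsv`, `samples.tsv` and
#'   `truth.tsv` in the dialects read back by [read_expression_matrix()] and
#'   [read_sample_sheet()].
#' @param ... Passed to [simulate_timeseries()].
#' @return The simulation list, invisibly.
#' @export
run_simulate_series <- function(out_dir, ...) {
  sim <- simulate_timeseries(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$expr, file.path(out_dir, "expr.tsv"), progress = FALSE)
  readr::write_tsv(sim$samples, file.path(out_dir, "samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  invisible(sim)
}
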
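# Pathway over-representation: one-sided Fisher's exact test (hypergeometric
# upper tail) per pathway, with Benjamini-Hochberg adjustment reported next to
# the raw p-values, and metabolite -> circadian-enzyme linkage queries.

#' One-sided Fisher's exact enrichment test
#'
#' Hypergeometric upper-tail probability of observing at least
#' `in_cluster_in_pathway` pathway members in a cluster of size
#' `in_cluster_total` drawn from a background of `background_total` genes of
#' which `background_in_pathway` are in the pathway.
#'
#' @param in_cluster_in_pathway,in_cluster_total Counts inside the cluster.
#' @param background_in_pathway,background_total Counts in the background
#'   (which includes the cluster).
#' @return The one-sided p-value.
#' @export
fisher_enrichment <- function(in_cluster_in_pathway, in_cluster_total,
                              background_in_pathway, background_total) {
  counts <- c(in_cluster_in_pathway, in_cluster_total,
              background_in_pathway, background_total)
  if (!all(is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (in_cluster_total > background_total ||
      background_in_pathway > background_total ||
      in_cluster_in_pathway > min(in_cluster_total, background_in_pathway)) {
    stop("inconsistent 2x2 margins", call. = FALSE)
  }
  stats::phyper(in_cluster_in_pathway - 1, background_in_pathway,
                background_total - background_in_pathway, in_cluster_total,
                lower.tail = FALSE)
}

#' Gene-to-pathway map from a reaction table
#'
#' Associates every gene with the pathway annotations of the reactions it
#' catalyses.
#'
#' @param records Reaction tibble.
#' @return A tibble (`gene`, `pathway`), one row per distinct pair.
#' @export
gene_pathway_map <- function(records) {
  tibble::tibble(gene = records$genes, pathway = records$pathways) |>
    tidyr::unnest_longer("gene") |>
    tidyr::unnest_longer("pathway") |>
    dplyr::distinct(.data$gene, .data$pathway) |>
    dplyr::arrange(.data$gene, .data$pathway)
}

#' Pathway enrichment of a gene set
#'
#' One [fisher_enrichment()] test per pathway that intersects `genes`, with
#' Benjamini-Hochberg adjusted p-values reported alongside the raw ones.
#' Results are sorted by raw p-value, ties broken by pathway identifier.
#'
#' @param genes Character vector of cluster genes (subset of `background`).
#' @param background Character vector of background genes.
#' @param pathway_map Tibble (`gene`, `pathway`) such as from
#'   [gene_pathway_map()].
#' @return A tibble (`pathway`, `in_cluster_in_pathway`, `in_cluster_total`,
#'   `background_in_pathway`, `background_total`, `p_value`, `p_adjust`);
#'   zero rows if no pathway intersects the gene set.
#' @export
pathway_enrichment <- function(genes, background, pathway_map) {
  genes <- unique(genes)
  background <- unique(background)
  if (length(background) == 0) {
    stop("background gene set is empty", call. = FALSE)
  }
  outside <- setdiff(genes, background)
  if (length(outside) > 0) {
    stop("cluster gene(s) absent from background: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  map <- pathway_map |>
    dplyr::filter(.data$gene %in% background) |>
    dplyr::distinct(.data$gene, .data$pathway)
  hit <- map |> dplyr::filter(.data$gene %in% genes)
  if (nrow(hit) == 0) {
    return(tibble::tibble(
      pathway = character(0), in_cluster_in_pathway = integer(0),
      in_cluster_total = integer(0), background_in_pathway = integer(0),
      background_total = integer(0), p_value = double(0), p_adjust = double(0)
    ))
  }
  res <- hit |>
    dplyr::count(.data$pathway, name = "in_cluster_in_pathway") |>
    dplyr::left_join(
      map |> dplyr::count(.data$pathway, name = "background_in_pathway"),
      by = "pathway"
    ) |>
    dplyr::mutate(
      in_cluster_total = length(genes),
      background_total = length(background),
      p_value = purrr::pmap_dbl(
        list(.data$in_cluster_in_pathway, .data$in_cluster_total,
             .data$background_in_pathway, .data$background_total),
        fisher_enrichment
      ),
      p_adjust = stats::p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::arrange(.data$p_value, .data$pathway) |>
    dplyr::select("pathway", "in_cluster_in_pathway", "in_cluster_total",
                  "background_in_pathway", "background_total",
                  "p_value", "p_adjust")
  res
}

#' Circadian enzymes directly connected to a metabolite
#'
#' Returns the phased gene-reaction nodes whose reaction has the metabolite
#' as a substrate or product, deduplicated by (gene, reaction).
#'
#' @param records Reaction tibble.
#' @param metabolite A metabolite identifier.
#' @param nodes Phased node tibble from [gene_reaction_nodes()].
#' @return A tibble (`metabolite`, `gene`, `reaction_id`, `phase`); empty
#'   (with a warning) if the metabolite is unknown.
#' @export
link_metabolite_to_enzymes <- function(records, metabolite, nodes) {
  touches <- purrr::map2_lgl(records$substrates, records$products,
                             function(s, p) metabolite %in% c(s, p))
  if (!any(touches)) {
    warning("metabolite not found in any reaction: ", metabolite,
            call. = FALSE)
  }
  nodes |>
    dplyr::filter(.data$reaction_id %in% records$reaction_id[touches]) |>
    dplyr::distinct(.data$gene, .data$reaction_id, .keep_all = TRUE) |>
    dplyr::transmute(
      metabolite = metabolite,
      gene = .data$gene,
      reaction_id = .data$reaction_id,
      phase = .data$phase
    )
}
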
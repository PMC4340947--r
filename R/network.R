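# Reaction graph construction. Reactions are nodes; two reactions are joined
# by an (undirected) edge when they share at least one metabolite — substrate
# or product, on either side — that is not on the currency exclusion list.
# Reaction direction is stored but deliberately ignored for connectivity.

#' Default currency metabolites
#'
#' Ubiquitous cofactors whose sharing between two reactions says nothing about
#' pathway proximity: water, proton, the adenosine phosphates, the
#' nicotinamide cofactors, coenzyme A, ortho-/diphosphate, CO2 and O2. Both
#' common names and KEGG compound identifiers are listed, so tables using
#' either vocabulary are covered. Pass `currency = character(0)` to
#' [build_reaction_graph()] to reproduce raw connectivity.
#'
#' @return A character vector of metabolite identifiers.
#' @export
default_currency_metabolites <- function() {
  c(
    "H2O", "C00001", "H+", "C00080",
    "ATP", "C00002", "ADP", "C00008", "AMP", "C00020",
    "NAD+", "C00003", "NADH", "C00004", "NADP+", "C00006", "NADPH", "C00005",
    "CoA", "C00010", "Orthophosphate", "C00009", "Diphosphate", "C00013",
    "CO2", "C00011", "O2", "C00007"
  )
}

#' Build the undirected reaction graph
#'
#' Two reactions are connected if and only if they share a metabolite
#' (substrate or product on either reaction; the union of both sides is used)
#' that is not in `currency`. The result is an undirected graph with reactions
#' as nodes, labelled with its connected components.
#'
#' @param records Reaction tibble from [read_reaction_table()] or
#'   [simulate_reaction_network()].
#' @param currency Metabolite identifiers excluded from connectivity; default
#'   [default_currency_metabolites()].
#' @return A `reaction_graph` object: list with the igraph `graph`, a
#'   `membership` tibble (`reaction_id`, `component`) and the `currency`
#'   vector used.
#' @examples
#' rec <- tibble::tibble(
#'   reaction_id = c("R1", "R2", "R3"),
#'   genes = list("gA", "gB", "gC"),
#'   substrates = list("A", "B", "D"),
#'   products = list("B", "C", "E"),
#'   reversible = FALSE,
#'   pathways = list(character(0), character(0), character(0))
#' )
#' g <- build_reaction_graph(rec, currency = character(0))
#' glance(g)
#' @export
build_reaction_graph <- function(records, currency = default_currency_metabolites()) {
  if (nrow(records) == 0) {
    stop("cannot build a reaction graph from an empty record list",
         call. = FALSE)
  }
  validate_reaction_records(records)
  mets <- purrr::map2(records$substrates, records$products,
                      function(s, p) setdiff(union(s, p), currency))
  incidence <- tibble::tibble(
    reaction_id = rep(records$reaction_id, lengths(mets)),
    metabolite = unlist(mets, use.names = FALSE)
  )
  if (nrow(incidence) > 0) {
    edges <- dplyr::inner_join(incidence, incidence, by = "metabolite",
                               relationship = "many-to-many",
                               suffix = c("_a", "_b")) |>
      dplyr::filter(.data$reaction_id_a < .data$reaction_id_b) |>
      dplyr::distinct(.data$reaction_id_a, .data$reaction_id_b)
  } else {
    edges <- tibble::tibble(reaction_id_a = character(0),
                            reaction_id_b = character(0))
  }
  graph <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = records$reaction_id)
  )
  comp <- igraph::components(graph)
  membership <- tibble::tibble(
    reaction_id = names(comp$membership),
    component = as.integer(comp$membership)
  )
  structure(
    list(graph = graph, membership = membership, currency = currency),
    class = "reaction_graph"
  )
}

#' @export
print.reaction_graph <- function(x, ...) {
  gl <- glance(x)
  cat("<reaction_graph>\n")
  cat("  reactions:  ", gl$n_reactions, "\n", sep = "")
  cat("  edges:      ", gl$n_edges, "\n", sep = "")
  cat("  components: ", gl$n_components,
      " (largest: ", gl$largest_component, ")\n", sep = "")
  cat("  currency metabolites excluded: ", length(x$currency), "\n", sep = "")
  invisible(x)
}

#' @describeIn build_reaction_graph Edge list as a tibble (`from`, `to`).
#' @param x A `reaction_graph`.
#' @param ... Unused.
#' @method tidy reaction_graph
#' @export
tidy.reaction_graph <- function(x, ...) {
  e <- igraph::as_data_frame(x$graph, what = "edges")
  tibble::tibble(from = e$from, to = e$to)
}

#' @describeIn build_reaction_graph One-row summary (reaction, edge and
#'   component counts).
#' @method glance reaction_graph
#' @export
glance.reaction_graph <- function(x, ...) {
  sizes <- component_sizes(x)$size
  tibble::tibble(
    n_reactions = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_components = length(sizes),
    largest_component = max(sizes)
  )
}

#' Connected component sizes
#'
#' @param network A `reaction_graph`.
#' @return A tibble (`component`, `size`), ordered by decreasing size.
#' @export
component_sizes <- function(network) {
  stopifnot(inherits(network, "reaction_graph"))
  network$membership |>
    dplyr::count(.data$component, name = "size") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$component)
}

#' Expand reactions into phased gene-reaction nodes
#'
#' Genes and reactions are many-to-many, so the clustering unit is the
#' (gene, reaction) pair. Each pair inherits the circadian phase of its gene;
#' genes absent from the phase table are dropped (their count is reported via
#' a message and the `dropped_genes` attribute).
#'
#' @param records Reaction tibble.
#' @param phases Phase tibble (`gene`, `phase_h`) from [read_phase_table()].
#' @return A tibble (`node`, `gene`, `reaction_id`, `phase`) with one row per
#'   phased (gene, reaction) pair. `node` is `"gene|reaction_id"`.
#' @export
gene_reaction_nodes <- function(records, phases) {
  validate_reaction_records(records)
  if (any(phases$phase_h < 0 | phases$phase_h >= 24)) {
    stop("phase_h values must lie in [0, 24)", call. = FALSE)
  }
  pairs <- tibble::tibble(
    reaction_id = rep(records$reaction_id, lengths(records$genes)),
    gene = unlist(records$genes, use.names = FALSE)
  ) |>
    dplyr::distinct()
  dropped <- sort(setdiff(unique(pairs$gene), phases$gene))
  nodes <- pairs |>
    dplyr::inner_join(phases, by = "gene") |>
    dplyr::transmute(
      node = paste(.data$gene, .data$reaction_id, sep = "|"),
      gene = .data$gene,
      reaction_id = .data$reaction_id,
      phase = .data$phase_h
    ) |>
    dplyr::arrange(.data$node)
  if (length(dropped) > 0) {
    message(length(dropped), " gene(s) without a circadian phase dropped")
  }
  attr(nodes, "dropped_genes") <- dropped
  nodes
}
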
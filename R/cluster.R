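# Complete-linkage hierarchical clustering of gene-reaction nodes on the
# combined distance, one dendrogram per connected component, with a strict
# fixed-height tree cut. A merge at exactly the cut height is split: clusters
# are the maximal subtrees whose internal merge heights are all < h.

#' Complete-linkage dendrogram with a deterministic input order
#'
#' Thin wrapper around [stats::hclust()] (`method = "complete"`) that first
#' orders the rows/columns of `D` lexicographically by label, so that repeated
#' runs — and runs after node relabelling — give the same tree even in the
#' presence of tied distances.
#'
#' @param D A symmetric finite dissimilarity matrix with unique dimnames.
#' @return An `hclust` object.
#' @export
complete_linkage <- function(D) {
  if (!is.matrix(D) || nrow(D) < 2) {
    stop("D must be a matrix with at least two rows", call. = FALSE)
  }
  labs <- rownames(D)
  if (is.null(labs) || anyDuplicated(labs)) {
    stop("D must have unique row labels", call. = FALSE)
  }
  if (!all(is.finite(D))) {
    stop("D must be finite within a component", call. = FALSE)
  }
  ord <- order(labs)
  stats::hclust(stats::as.dist(D[ord, ord, drop = FALSE]),
                method = "complete")
}

#' Cut a dendrogram strictly below a height
#'
#' Clusters are the maximal subtrees all of whose internal merge heights are
#' strictly less than `h`; a merge at exactly `h` is split. This differs from
#' [stats::cutree()], which keeps merges at exactly the cut height together.
#'
#' @param tree An `hclust` object.
#' @param h Positive cut height.
#' @return Integer cluster memberships named by leaf label, numbered in order
#'   of first appearance.
#' @export
cut_phase_tree <- function(tree, h) {
  stopifnot(inherits(tree, "hclust"), is.numeric(h), length(h) == 1, h > 0)
  n <- length(tree$labels)
  grp <- seq_len(n)
  rep_leaf <- integer(nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    child <- tree$merge[i, ]
    a <- if (child[1] < 0) -child[1] else rep_leaf[child[1]]
    b <- if (child[2] < 0) -child[2] else rep_leaf[child[2]]
    if (tree$height[i] < h) {
      grp[grp == grp[b]] <- grp[a]
    }
    rep_leaf[i] <- a
  }
  memb <- match(grp, unique(grp[tree$order]))
  names(memb) <- tree$labels
  memb
}

#' Phase-coherent clustering of gene-reaction nodes
#'
#' The package's main operation. Computes the combined network + phase
#' distance at weight `lambda`, builds one complete-linkage dendrogram per
#' connected component, cuts every tree strictly below height `h`, and
#' summarises each resulting cluster with its size (gene-reaction pairs and
#' unique genes), circular mean phase, Rayleigh coherency p-value and — when
#' `records` is supplied — its enriched pathways. Clusters are ranked by size
#' (descending), ties broken by smaller coherency p-value.
#'
#' @param nodes Phased node tibble from [gene_reaction_nodes()].
#' @param network A `reaction_graph` from [build_reaction_graph()].
#' @param lambda Phase-penalty weight (default 1).
#' @param h Cut height (default 12). A cluster's internal merges all sit
#'   strictly below `h`.
#' @param records Optional reaction tibble; if given, per-cluster pathway
#'   enrichment is computed against all clustered genes as background.
#' @param min_report_size Minimum cluster size used by `print()` for
#'   reporting; never applied before statistics are computed.
#' @return A `phase_clusters` object: list with `members` (node-level tibble
#'   including the `cluster` assignment), `clusters` (ranked summary tibble),
#'   `trees` (named list of `hclust` objects per multi-node component),
#'   `enrichment` (tibble or `NULL`) and `params`.
#' @export
cluster_phase_coherent <- function(nodes, network, lambda = 1, h = 12,
                                   records = NULL, min_report_size = 10) {
  stopifnot(h > 0)
  D <- combined_distance(nodes, network, lambda = lambda)
  comp_of <- network$membership$component[
    match(nodes$reaction_id, network$membership$reaction_id)]
  members <- nodes |> dplyr::mutate(component = comp_of, cluster = NA_integer_)
  trees <- list()
  next_id <- 0L
  for (comp in sort(unique(comp_of))) {
    idx <- which(comp_of == comp)
    if (length(idx) == 1) {
      members$cluster[idx] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    tree <- complete_linkage(D[idx, idx, drop = FALSE])
    trees[[as.character(comp)]] <- tree
    memb <- cut_phase_tree(tree, h)
    members$cluster[idx] <- next_id + memb[members$node[idx]]
    next_id <- next_id + max(memb)
  }
  summary <- summarise_clusters(members)
  ranked <- summary |>
    dplyr::arrange(dplyr::desc(.data$n_members), .data$coherency_p,
                   .data$cluster) |>
    dplyr::mutate(rank_id = dplyr::row_number())
  relabel <- ranked$rank_id[match(members$cluster, ranked$cluster)]
  members$cluster <- relabel
  clusters <- ranked |>
    dplyr::mutate(cluster = .data$rank_id) |>
    dplyr::select(-"rank_id")

  enrichment <- NULL
  if (!is.null(records)) {
    map <- gene_pathway_map(records)
    background <- unique(members$gene)
    enrichment <- purrr::map_dfr(clusters$cluster, function(cl) {
      genes <- unique(members$gene[members$cluster == cl])
      res <- pathway_enrichment(genes, background, map)
      if (nrow(res) == 0) return(res)
      dplyr::mutate(res, cluster = cl, .before = 1)
    })
    top <- enrichment |>
      dplyr::group_by(.data$cluster) |>
      dplyr::slice_min(order_by = .data$p_value, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("cluster", top_pathway = "pathway",
                    top_pathway_p = "p_value")
    clusters <- dplyr::left_join(clusters, top, by = "cluster")
  }

  structure(
    list(
      members = members,
      clusters = clusters,
      trees = trees,
      enrichment = enrichment,
      params = list(lambda = lambda, h = h,
                    min_report_size = min_report_size)
    ),
    class = "phase_clusters"
  )
}

summarise_clusters <- function(members) {
  members |>
    dplyr::group_by(.data$cluster, .data$component) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_genes = dplyr::n_distinct(.data$gene),
      mean_phase = circular_mean_phase(.data$phase),
      coherency_p = if (dplyr::n() >= 2) {
        rayleigh_test(.data$phase)$p_value
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' @export
print.phase_clusters <- function(x, ...) {
  gl <- glance(x)
  cat("<phase_clusters> lambda = ", x$params$lambda,
      ", cut height h = ", x$params$h, "\n", sep = "")
  cat("  ", gl$n_nodes, " gene-reaction nodes in ", gl$n_components,
      " component(s) -> ", gl$n_clusters, " cluster(s)\n", sep = "")
  big <- x$clusters |>
    dplyr::filter(.data$n_members >= x$params$min_report_size)
  if (nrow(big) > 0) {
    cat("  clusters with >= ", x$params$min_report_size, " members:\n",
        sep = "")
    print(as.data.frame(utils::head(big, 10)), row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn cluster_phase_coherent Node-level tibble with per-cluster
#'   summary columns joined on.
#' @param x A `phase_clusters` object.
#' @param ... Unused.
#' @method tidy phase_clusters
#' @export
tidy.phase_clusters <- function(x, ...) {
  dplyr::left_join(
    x$members,
    x$clusters |>
      dplyr::select("cluster", "n_members", "mean_phase", "coherency_p"),
    by = "cluster"
  )
}

#' @describeIn cluster_phase_coherent One-row summary of the fit.
#' @method glance phase_clusters
#' @export
glance.phase_clusters <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$members),
    n_components = dplyr::n_distinct(x$members$component),
    n_clusters = dplyr::n_distinct(x$members$cluster),
    largest_cluster = max(x$clusters$n_members),
    lambda = x$params$lambda,
    h = x$params$h
  )
}

#' Export dendrograms as Newick trees
#'
#' Writes one Newick file per multi-node component, with branch lengths
#' derived from the complete-linkage merge heights (via
#' [ape::as.phylo()]). Single-node components have no tree and are skipped.
#'
#' @param x A `phase_clusters` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
export_newick <- function(x, dir, prefix = "tree_component") {
  stopifnot(inherits(x, "phase_clusters"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (comp in names(x$trees)) {
    phy <- ape::as.phylo(x$trees[[comp]])
    path <- file.path(dir, paste0(prefix, comp, ".nwk"))
    ape::write.tree(phy, file = path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write an iTOL color-strip annotation of node phases
#'
#' Maps each leaf's circadian phase onto a 24 h circular colour wheel (HSV
#' hue = phase / 24) and writes an iTOL `DATASET_COLORSTRIP` annotation file,
#' so dendrogram leaves can be ringed by peak time.
#'
#' @param x A `phase_clusters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_itol_phase_annotation <- function(x, path) {
  stopifnot(inherits(x, "phase_clusters"))
  colors <- grDevices::hsv(h = x$members$phase / 24, s = 0.85, v = 0.9)
  lines <- c(
    "DATASET_COLORSTRIP",
    "SEPARATOR TAB",
    "DATASET_LABEL\tcircadian phase",
    "COLOR\t#444444",
    "DATA",
    paste(x$members$node, colors, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write the cluster membership table
#'
#' @param x A `phase_clusters` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}
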
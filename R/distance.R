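# The combined dissimilarity: network hop distance plus a sinusoidal phase
# penalty, D_ij = d_ij + 4*lambda*sin^2(pi*(p_i - p_j)/24). The penalty is the
# squared chord distance between unit vectors at the two phase angles, scaled
# by lambda; with lambda = 1 it calibrates to 0, 1, 2, 3, 4 for phase
# differences of 0, 4, 6, 8, 12 hours.

#' Sinusoidal phase penalty
#'
#' Computes `4 * lambda * sin^2(pi * (p_i - p_j) / period_hours)`, the squared
#' distance between two unit vectors on the circle whose angles encode the
#' circadian peak times, weighted by `lambda`. The raw difference is used
#' inside `sin^2`, which is periodic with period `period_hours`, so this
#' equals the penalty on the circular phase difference.
#'
#' @param p_i,p_j Peak times in hours; vectors are recycled.
#' @param lambda Nonnegative weight of the phase term; `lambda = 0`
#'   degenerates to pure network distance.
#' @param period_hours Oscillation period (24 for circadian rhythms).
#' @return Nonnegative penalties in `[0, 4 * lambda]`.
#' @examples
#' phase_penalty(0, c(0, 4, 6, 8, 12)) # 0 1 2 3 4
#' @export
phase_penalty <- function(p_i, p_j, lambda = 1, period_hours = 24) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0) {
    stop("lambda must be a single finite nonnegative number", call. = FALSE)
  }
  if (!all(is.finite(p_i)) || !all(is.finite(p_j))) {
    stop("phases must be finite", call. = FALSE)
  }
  4 * lambda * sin(pi * (p_i - p_j) / period_hours)^2
}

#' All-pairs shortest-path hop distances between reactions
#'
#' Unit edge weights; pairs in different connected components get `Inf`.
#'
#' @param network A `reaction_graph` from [build_reaction_graph()].
#' @return A symmetric numeric matrix with reaction ids as dimnames.
#' @export
network_distances <- function(network) {
  stopifnot(inherits(network, "reaction_graph"))
  if (igraph::vcount(network$graph) == 0) {
    stop("network is empty", call. = FALSE)
  }
  igraph::distances(network$graph, algorithm = "unweighted")
}

#' Combined network + phase distance matrix
#'
#' `D_ij = d(r_i, r_j) + phase_penalty(p_i, p_j, lambda)` over gene-reaction
#' nodes. Two nodes attached to the same reaction have `d = 0`, so their
#' dissimilarity reduces to the pure phase penalty; node pairs whose reactions
#' lie in different components keep the `Inf` sentinel and are clustered
#' separately downstream.
#'
#' @param nodes Node tibble from [gene_reaction_nodes()].
#' @param network A `reaction_graph`; every node's reaction must be a vertex.
#' @param lambda Phase-penalty weight (default 1).
#' @return A symmetric matrix with node labels as dimnames and attributes
#'   `lambda` and `nodes` (the input tibble).
#' @export
combined_distance <- function(nodes, network, lambda = 1) {
  stopifnot(inherits(network, "reaction_graph"))
  if (nrow(nodes) == 0) {
    stop("no gene-reaction nodes supplied", call. = FALSE)
  }
  known <- igraph::V(network$graph)$name
  unknown <- setdiff(unique(nodes$reaction_id), known)
  if (length(unknown) > 0) {
    stop("node(s) reference reaction(s) absent from the network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  d_rxn <- network_distances(network)
  d <- d_rxn[nodes$reaction_id, nodes$reaction_id, drop = FALSE]
  pen <- outer(nodes$phase, nodes$phase,
               function(a, b) phase_penalty(a, b, lambda = lambda))
  D <- d + pen
  dimnames(D) <- list(nodes$node, nodes$node)
  attr(D, "lambda") <- lambda
  attr(D, "nodes") <- nodes
  D
}

#' Long-format view of a combined distance matrix
#'
#' One row per unordered node pair, decomposed into the hop distance `d`, the
#' phase `penalty` and their sum `D`. Suited for TSV export and inspection.
#'
#' @param D Matrix from [combined_distance()].
#' @return A tibble (`node_i`, `node_j`, `d`, `penalty`, `D`).
#' @export
distance_long <- function(D) {
  nodes <- attr(D, "nodes")
  lambda <- attr(D, "lambda")
  if (is.null(nodes) || is.null(lambda)) {
    stop("D must come from combined_distance()", call. = FALSE)
  }
  idx <- which(upper.tri(D), arr.ind = TRUE)
  pen <- phase_penalty(nodes$phase[idx[, 1]], nodes$phase[idx[, 2]],
                       lambda = lambda)
  tibble::tibble(
    node_i = nodes$node[idx[, 1]],
    node_j = nodes$node[idx[, 2]],
    d = D[idx] - pen,
    penalty = pen,
    D = D[idx]
  )
}
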
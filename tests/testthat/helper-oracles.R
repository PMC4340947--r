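# Independent oracles and small fixture builders shared across tests.

# Construct a reaction tibble from parallel lists.
make_records <- function(ids, genes, substrates, products,
                         reversible = FALSE, pathways = NULL) {
  n <- length(ids)
  if (is.null(pathways)) pathways <- rep(list(character(0)), n)
  tibble::tibble(
    reaction_id = ids,
    genes = lapply(genes, as.character),
    substrates = lapply(substrates, as.character),
    products = lapply(products, as.character),
    reversible = rep_len(reversible, n),
    pathways = lapply(pathways, as.character)
  )
}

# Random sparse reaction table over a shared metabolite alphabet.
random_records <- function(n_reactions, n_metabolites, seed) {
  withr::with_seed(seed, {
    mets <- sprintf("met%02d", seq_len(n_metabolites))
    make_records(
      ids = sprintf("R%02d", seq_len(n_reactions)),
      genes = as.list(sprintf("g%02d", seq_len(n_reactions))),
      substrates = replicate(n_reactions, sample(mets, sample(1:2, 1)),
                             simplify = FALSE),
      products = replicate(n_reactions, sample(mets, sample(1:2, 1)),
                           simplify = FALSE)
    )
  })
}

# Brute-force edge set: every unordered reaction pair sharing a non-currency
# metabolite (union of substrates and products on both sides).
brute_force_edges <- function(records, currency = character(0)) {
  mets <- purrr::map2(records$substrates, records$products,
                      function(s, p) setdiff(union(s, p), currency))
  ids <- records$reaction_id
  out <- character(0)
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(mets[[i]], mets[[j]])) > 0) {
        pair <- sort(c(ids[i], ids[j]))
        out <- c(out, paste(pair[1], pair[2]))
      }
    }
  }
  sort(out)
}

edge_key <- function(network) {
  e <- tidy(network)
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
}

# Per-source breadth-first search over an edge list; returns the full
# hop-count matrix with Inf for unreachable pairs.
bfs_distances <- function(vertices, edges) {
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  d <- matrix(Inf, length(vertices), length(vertices),
              dimnames = list(vertices, vertices))
  for (src in vertices) {
    d[src, src] <- 0
    frontier <- src
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- setdiff(unique(unlist(adj[frontier])),
                     vertices[is.finite(d[src, ])])
      d[src, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Naive agglomerative complete linkage: recompute the max pairwise distance
# between every cluster pair at every step.
naive_complete_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

random_dist_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.1, 10)
    m <- m + t(m)
    dimnames(m) <- list(sprintf("n%02d", seq_len(n)),
                        sprintf("n%02d", seq_len(n)))
    m
  })
}

# Exhaustive hypergeometric upper tail from binomial coefficients only.
hyper_tail_oracle <- function(a, K, N, k) {
  js <- seq(a, min(K, k))
  if (length(js) == 0 || a > min(K, k)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, k - js) - lchoose(N, k)))
}

circ_diff_h <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Adjusted Rand index between the planted module labels and the recovered
# cluster assignment, restricted to truth-labelled (module) nodes.
module_recovery_ari <- function(fit, truth) {
  joined <- dplyr::inner_join(fit$members, truth,
                              by = c("gene", "reaction_id"))
  joined <- joined[!is.na(joined$module), ]
  mclust::adjustedRandIndex(joined$module, joined$cluster)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
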
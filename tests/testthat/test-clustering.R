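test_that("complete linkage merges at the maximum pairwise distance", {
  D <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- complete_linkage(D)
  expect_equal(hc$height, c(1, 4))

  for (seed in 1:20) {
    n <- sample(3:12, 1)
    D <- random_dist_matrix(n, seed = seed + 100)
    hc <- complete_linkage(D)
    expect_equal(sort(hc$height), naive_complete_heights(D),
                 tolerance = 1e-10)
  }
  expect_error(complete_linkage(matrix(0, 1, 1)), "two rows")
  expect_error(complete_linkage(matrix(c(0, Inf, Inf, 0), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "finite")
})

test_that("the tree cut is strict: merges at exactly h are split", {
  D <- matrix(c(0, 5, 13, 13,
                5, 0, 13, 13,
                13, 13, 0, 5,
                13, 13, 5, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hc <- complete_linkage(D)
  expect_equal(max(table(cut_phase_tree(hc, 12))), 2) # 2 clusters of 2
  expect_equal(length(unique(cut_phase_tree(hc, 12))), 2)
  # boundary: a merge at exactly the cut height is split
  expect_equal(length(unique(cut_phase_tree(hc, 5))), 4)
  expect_equal(length(unique(cut_phase_tree(hc, 5 + 1e-9))), 2)
  # below all heights -> singletons; above all -> one cluster
  expect_equal(length(unique(cut_phase_tree(hc, 1))), 4)
  expect_equal(length(unique(cut_phase_tree(hc, 14))), 1)
})

test_that("clusters are ranked by size then coherency and relabeling-proof", {
  sim <- simulate_reaction_network(n_modules = 2, module_size = 5,
                                   module_phase_centers = c(2, 14),
                                   phase_spread_h = 0.5, n_background = 8,
                                   n_bridges = 1, seed = 5)
  net <- build_reaction_graph(sim$reactions)
  nodes <- suppressMessages(gene_reaction_nodes(sim$reactions, sim$phases))
  fit <- cluster_phase_coherent(nodes, net, records = sim$reactions)

  expect_true(all(diff(fit$clusters$n_members) <= 0))
  ties <- split(fit$clusters, fit$clusters$n_members)
  for (tie in ties) {
    if (nrow(tie) > 1) {
      expect_true(all(diff(order(tie$cluster)) > 0))
      p <- tie$coherency_p
      expect_true(all(diff(p[!is.na(p)]) >= 0))
    }
  }
  # partition: every node in exactly one cluster
  expect_false(anyNA(fit$members$cluster))
  expect_equal(sum(fit$clusters$n_members), nrow(nodes))

  # relabeling the nodes leaves the cluster composition unchanged
  relabel <- function(x) paste0("zz_", x)
  rec2 <- sim$reactions
  rec2$genes <- lapply(rec2$genes, relabel)
  ph2 <- sim$phases
  ph2$gene <- relabel(ph2$gene)
  nodes2 <- suppressMessages(gene_reaction_nodes(rec2, ph2))
  net2 <- build_reaction_graph(rec2)
  fit2 <- cluster_phase_coherent(nodes2, net2)
  sets1 <- sort(sapply(split(fit$members$gene, fit$members$cluster),
                       function(g) paste(sort(relabel(g)), collapse = ",")))
  sets2 <- sort(sapply(split(fit2$members$gene, fit2$members$cluster),
                       function(g) paste(sort(g), collapse = ",")))
  expect_equal(unname(sets1), unname(sets2))
})

test_that("planted phase-coherent modules are recovered through the cut", {
  for (seed in 1:3) {
    sim <- simulate_reaction_network(n_modules = 2, module_size = 5,
                                     module_phase_centers = c(2, 14),
                                     phase_spread_h = 0.5, seed = seed)
    net <- build_reaction_graph(sim$reactions)
    nodes <- suppressMessages(gene_reaction_nodes(sim$reactions, sim$phases))
    fit <- cluster_phase_coherent(nodes, net, lambda = 1, h = 12)
    expect_gte(module_recovery_ari(fit, sim$truth), 0.9)
  }
})

test_that("clustering is invariant under global phase rotation", {
  sim <- simulate_reaction_network(seed = 17)
  net <- build_reaction_graph(sim$reactions)
  nodes <- suppressMessages(gene_reaction_nodes(sim$reactions, sim$phases))
  fit <- cluster_phase_coherent(nodes, net)
  rotated <- sim$phases
  rotated$phase_h <- (rotated$phase_h + 9.5) %% 24
  nodes_rot <- suppressMessages(gene_reaction_nodes(sim$reactions, rotated))
  fit_rot <- cluster_phase_coherent(nodes_rot, net)
  expect_equal(fit_rot$members$cluster, fit$members$cluster)
  expect_equal(fit_rot$clusters$coherency_p, fit$clusters$coherency_p,
               tolerance = 1e-9)
})

test_that("with lambda = 0 the clustering uses network distance alone", {
  sim <- simulate_reaction_network(n_background = 0, seed = 9)
  net <- build_reaction_graph(sim$reactions)
  nodes <- suppressMessages(gene_reaction_nodes(sim$reactions, sim$phases))
  fit0 <- cluster_phase_coherent(nodes, net, lambda = 0, h = 12)
  # both 5-reaction chains plus a bridge: all hop distances < 12, one cluster
  expect_equal(length(unique(fit0$members$cluster)), 1)
  fit1 <- cluster_phase_coherent(nodes, net, lambda = 1, h = 12)
  expect_gt(length(unique(fit1$members$cluster)), 1)
})

test_that("dendrograms export to Newick and iTOL annotation files", {
  sim <- simulate_reaction_network(seed = 30)
  net <- build_reaction_graph(sim$reactions)
  nodes <- suppressMessages(gene_reaction_nodes(sim$reactions, sim$phases))
  fit <- cluster_phase_coherent(nodes, net)
  dir <- tempfile()
  paths <- export_newick(fit, dir)
  expect_true(length(paths) >= 1)
  phy <- ape::read.tree(paths[1])
  comp1 <- names(fit$trees)[1]
  expect_setequal(phy$tip.label, fit$trees[[comp1]]$labels)

  itol <- file.path(dir, "itol.txt")
  write_itol_phase_annotation(fit, itol)
  lines <- readLines(itol)
  expect_equal(lines[1], "DATASET_COLORSTRIP")
  data_lines <- lines[-seq_len(which(lines == "DATA"))]
  expect_equal(length(data_lines), nrow(fit$members))
  expect_true(all(grepl("\t#[0-9A-Fa-f]{6}$", data_lines)))
})
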
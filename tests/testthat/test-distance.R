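test_that("phase penalty reproduces its calibration and trigonometry", {
  expect_equal(phase_penalty(0, c(0, 4, 6, 8, 12)), c(0, 1, 2, 3, 4),
               tolerance = 1e-12)
  # a 23 h vs 1 h pair is a 2 h circular difference
  expect_equal(phase_penalty(23, 1), 4 * sin(pi / 12)^2, tolerance = 1e-12)
  expect_equal(phase_penalty(23, 1), 0.26795, tolerance = 1e-4)
  expect_equal(phase_penalty(5, 5, lambda = 7), 0)
  expect_error(phase_penalty(NA, 3), "finite")
  expect_error(phase_penalty(1, 3, lambda = -1), "nonnegative")
})

test_that("phase penalty is symmetric, periodic and monotone up to antiphase", {
  deltas <- seq(0, 12, by = 0.25)
  pen <- phase_penalty(0, deltas)
  expect_equal(pen, phase_penalty(0, 24 - deltas), tolerance = 1e-12)
  expect_true(all(diff(pen) > 0))
  expect_equal(max(pen), 4)
  # periodic in the raw difference with period 24
  expect_equal(phase_penalty(0, deltas + 24), pen, tolerance = 1e-12)
  expect_equal(phase_penalty(deltas, 0), pen, tolerance = 1e-12)
})

test_that("hop distances match breadth-first search and the Floyd oracle", {
  path3 <- make_records(
    ids = c("R1", "R2", "R3"), genes = list("gA", "gB", "gC"),
    substrates = list("A", "B", "C"), products = list("B", "C", "D")
  )
  net <- build_reaction_graph(path3, currency = character(0))
  d <- network_distances(net)
  expect_equal(d["R1", "R3"], 2)
  expect_equal(diag(d), stats::setNames(rep(0, 3), path3$reaction_id))

  iso <- make_records(
    ids = c("R1", "R2"), genes = list("gA", "gB"),
    substrates = list("A", "X"), products = list("B", "Y")
  )
  expect_equal(network_distances(build_reaction_graph(iso,
                                                      currency = character(0)))["R1", "R2"],
               Inf)

  for (seed in 1:3) {
    rec <- random_records(n_reactions = 30, n_metabolites = 20, seed = seed)
    net <- build_reaction_graph(rec, currency = character(0))
    d <- network_distances(net)
    oracle <- bfs_distances(rec$reaction_id, tidy(net))
    expect_equal(d[rec$reaction_id, rec$reaction_id],
                 oracle[rec$reaction_id, rec$reaction_id])
  }

  # cross-check against the all-shortest-paths implementation in e1071
  rec <- random_records(n_reactions = 15, n_metabolites = 10, seed = 4)
  net <- build_reaction_graph(rec, currency = character(0))
  d <- network_distances(net)
  adj <- matrix(Inf, nrow(rec), nrow(rec),
                dimnames = list(rec$reaction_id, rec$reaction_id))
  e <- tidy(net)
  for (k in seq_len(nrow(e))) {
    adj[e$from[k], e$to[k]] <- 1
    adj[e$to[k], e$from[k]] <- 1
  }
  diag(adj) <- 0
  ref <- e1071::allShortestPaths(adj)$length
  finite <- is.finite(d)
  expect_equal(unname(d[finite]), unname(ref[finite]))
  expect_true(all(is.na(ref[!finite]) | !is.finite(ref[!finite])))
})

test_that("combined distance adds hop count and phase penalty", {
  rec <- make_records(
    ids = c("R1", "R2", "R3"),
    genes = list(c("gA", "gB"), "gC", "gD"),
    substrates = list("A", "B", "X"), products = list("B", "C", "Y")
  )
  phases <- tibble::tibble(gene = c("gA", "gB", "gC", "gD"),
                           phase_h = c(2, 2, 8, 5))
  net <- build_reaction_graph(rec, currency = character(0))
  nodes <- gene_reaction_nodes(rec, phases)
  D <- combined_distance(nodes, net, lambda = 1)

  # adjacent reactions (d = 1), 6 h apart: D = 1 + 2
  expect_equal(D["gA|R1", "gC|R2"], 3, tolerance = 1e-12)
  # same reaction, equal phases: D = 0
  expect_equal(D["gA|R1", "gB|R1"], 0)
  # cross-component pairs keep the infinity sentinel
  expect_equal(D["gA|R1", "gD|R3"], Inf)

  unknown <- tibble::tibble(node = "gZ|R9", gene = "gZ", reaction_id = "R9",
                            phase = 1)
  expect_error(combined_distance(unknown, net), "absent from the network")

  # lambda = 0 degenerates to the pure hop distance
  D0 <- combined_distance(nodes, net, lambda = 0)
  d <- network_distances(net)
  expect_equal(unname(D0["gA|R1", "gC|R2"]), unname(d["R1", "R2"]))

  long <- distance_long(D)
  expect_equal(long$D, long$d + long$penalty)
  expect_equal(nrow(long), choose(nrow(nodes), 2))
})

test_that("the combined matrix is invariant under global phase rotation", {
  sim <- simulate_reaction_network(seed = 21)
  net <- build_reaction_graph(sim$reactions)
  nodes <- suppressMessages(gene_reaction_nodes(sim$reactions, sim$phases))
  D <- combined_distance(nodes, net)
  for (shift in c(1.5, 7, 18.25)) {
    rotated <- sim$phases
    rotated$phase_h <- (rotated$phase_h + shift) %% 24
    nodes_rot <- suppressMessages(gene_reaction_nodes(sim$reactions, rotated))
    D_rot <- combined_distance(nodes_rot, net)
    expect_equal(matrix(D_rot, nrow(D_rot)), matrix(D, nrow(D)),
                 tolerance = 1e-9)
  }
})
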
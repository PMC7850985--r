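test_that("triangle centralities match the closed form", {
  k3 <- complete_net(3)
  ct <- compute_centralities(k3)
  expect_equal(ct$degree, rep(2L, 3))
  expect_equal(ct$clustering, rep(1, 3))
  expect_equal(ct$betweenness, rep(0, 3))
  expect_equal(ct$closeness, rep(1, 3))
  expect_equal(network_centrality_index(k3), 2 / 3)
})

test_that("star centralities match hand computation", {
  st <- star_net(4)   # center C, leaves L1..L4; n = 5
  ct <- compute_centralities(st)
  center <- ct[ct$node == "C", ]
  leaf <- ct[ct$node == "L1", ]
  expect_equal(center$betweenness, 1)
  expect_equal(center$clustering, 0)
  expect_equal(center$closeness, 1)
  # leaf: one neighbor at distance 1, three at distance 2
  expect_equal(leaf$closeness, (1 + 3 * 0.5) / 4)
  expect_equal(leaf$betweenness, 0)
})

test_that("centrality index is 0 for edgeless and single-node graphs", {
  lone <- net_from_pairs(nodes = "A")
  expect_equal(network_centrality_index(lone), 0)
  edgeless <- net_from_pairs(nodes = c("A", "B", "C"))
  expect_equal(network_centrality_index(edgeless), 0)
})

test_that("complete-graph symmetry: all deletion scores equal", {
  k5 <- complete_net(5)
  p <- perturbation_scores(k5)
  expect_equal(max(p) - min(p), 0)
  d <- disruption_scores(k5)
  expect_equal(max(d$disruption) - min(d$disruption), 0)
  expect_equal(d$severed_pairs, rep(0L, 5))
})

test_that("5-cycle deletion lengthens exactly one pair: D = 1/6", {
  ring <- generate_network(5, "ring_lattice", seed = 1)
  d <- disruption_scores(ring)
  expect_equal(d$disruption, rep(1 / 6, 5))
  expect_equal(d$severed_pairs, rep(0L, 5))
})

test_that("path cut vertex severs its pair with the |V| penalty", {
  path3 <- net_from_pairs(c("A", "B"), c("B", "C"))
  d <- disruption_scores(path3)
  b <- d[d$node == "B", ]
  expect_equal(b$disruption, 1)       # penalty |V| - d = 3 - 2
  expect_equal(b$severed_pairs, 1L)
  p <- perturbation_scores(path3)
  expect_equal(p[["B"]],
               abs(network_centrality_index(path3) -
                   network_centrality_index(
                     induce_subnetwork(path3, c("A", "C")))))
})

test_that("leaf law: degree-1 nodes disrupt nothing", {
  net <- generate_network(30, "preferential_attachment",
                          attachment_edges = 1, seed = 4)
  d <- disruption_scores(net)
  ct <- compute_centralities(net)
  leaves <- ct$node[ct$degree == 1]
  expect_gt(length(leaves), 0)
  expect_equal(d$disruption[d$node %in% leaves],
               rep(0, length(leaves)))
  expect_equal(d$severed_pairs[d$node %in% leaves],
               rep(0L, length(leaves)))
})

test_that("severed pairs are positive exactly at articulation points", {
  for (seed in 1:20) {
    net <- random_small_net(seed)
    d <- disruption_scores(net)
    aps <- igraph::articulation_points(net)$name
    expect_setequal(d$node[d$severed_pairs > 0], aps)
  }
})

test_that("adding an isolated node leaves disruption fixed and shifts
           perturbation only via normalization", {
  # biconnected fixture: with no articulation points the |V|-dependent
  # severed-pair penalty is never invoked, so D must be unchanged exactly
  ring <- list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"),
               c("E", "A"))
  net <- do.call(net_from_pairs, ring)
  aug <- do.call(net_from_pairs, c(ring, list(nodes = c(LETTERS[1:5], "Z"))))
  d0 <- disruption_scores(net)
  d1 <- disruption_scores(aug)
  expect_equal(d1$disruption[d1$node %in% d0$node], d0$disruption)
  # the isolate severs nothing; deleting it just undoes the renormalization
  expect_equal(d1$disruption[d1$node == "Z"], 0)
  p1 <- perturbation_scores(aug)
  expect_equal(p1[["Z"]],
               abs(network_centrality_index(aug) -
                   network_centrality_index(net)),
               tolerance = 1e-12)
})

test_that("deletion scores demand the documented minimum sizes", {
  expect_error(perturbation_scores(net_from_pairs(nodes = "A")),
               "at least 2")
  expect_error(disruption_scores(net_from_pairs(c("A", "B"))), "at least 3")
})

test_that("fast path agrees with brute-force oracles on random graphs", {
  for (seed in 1:50) {
    net <- random_small_net(seed + 1000)
    fast <- compute_centralities(net)
    slow <- oracle_centralities(net)
    expect_equal(fast$betweenness, slow$betweenness, tolerance = 1e-9)
    expect_equal(fast$closeness, slow$closeness, tolerance = 1e-9)
    expect_equal(fast$clustering, slow$clustering, tolerance = 1e-9)
    expect_equal(as.numeric(perturbation_scores(net)),
                 as.numeric(oracle_perturbation(net)), tolerance = 1e-9)
    fast_d <- disruption_scores(net)
    slow_d <- oracle_disruption(net)
    expect_equal(fast_d$disruption, slow_d$disruption, tolerance = 1e-9)
    expect_equal(fast_d$severed_pairs, slow_d$severed_pairs)
  }
})

test_that("score table carries all per-node columns in lexicographic order", {
  net <- generate_network(25, "preferential_attachment", seed = 8)
  sc <- score_nodes(net)
  expect_equal(sc$node, sort(sc$node))
  expect_named(sc, c("node", "degree", "clustering", "betweenness",
                     "closeness", "perturbation", "disruption",
                     "severed_pairs"))
  expect_true(all(sc$clustering >= 0 & sc$clustering <= 1))
  expect_true(all(sc$betweenness >= 0 & sc$betweenness <= 1))
  expect_true(all(sc$closeness >= 0 & sc$closeness <= 1))
  expect_true(all(sc$perturbation >= 0))
  expect_true(all(sc$disruption >= 0))
})
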
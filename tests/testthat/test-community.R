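test_that("modularity of canonical partitions", {
  net <- net_from_edges(triangle_pair_edges(bridge = FALSE))
  one <- tibble::tibble(id = net$nodes$id, community = 0)
  expect_equal(modularity_q(net, one), 0)
  two <- tibble::tibble(id = net$nodes$id,
                        community = rep(0:1, each = 3))
  expect_equal(modularity_q(net, two), 0.5)  # 2 * (0.5 - 0.25)
  expect_error(modularity_q(net, one[-1, ]), "misses")
})

test_that("modularity and assortativity match the mixing-matrix oracle", {
  set.seed(97)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    net <- random_test_network(n, p = stats::runif(1, 0.3, 0.9))
    if (nrow(net$edges) == 0) next
    labels <- sample(0:2, n, replace = TRUE)
    names(labels) <- net$nodes$id
    adj <- as_adjacency(net)
    oracle <- mixing_oracle(adj, labels[rownames(adj)])
    expect_equal(modularity_q(net, labels), oracle$Q, tolerance = 1e-12)
    if (length(unique(labels)) >= 2 && !is.na(oracle$r) &&
        is.finite(oracle$r)) {
      expect_equal(assortativity_categorical(net, labels), oracle$r,
                   tolerance = 1e-10)
    }
  }
})

test_that("modularity agrees with igraph on weighted random graphs", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:10) {
    net <- random_test_network(sample(5:25, 1), p = 0.3)
    if (nrow(net$edges) == 0) next
    labels <- sample(0:3, nrow(net$nodes), replace = TRUE)
    names(labels) <- net$nodes$id
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$id)
    expect_equal(
      modularity_q(net, labels),
      igraph::modularity(g, labels[igraph::V(g)$name] + 1,
                         weights = igraph::E(g)$weight),
      tolerance = 1e-12
    )
  }
})

test_that("edge betweenness matches igraph under the 1/w cost convention", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (rep in 1:10) {
    net <- random_test_network(sample(5:20, 1), p = 0.4)
    if (nrow(net$edges) == 0) next
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$id)
    expect_equal(edge_betweenness(net, weighted = TRUE)$betweenness,
                 igraph::edge_betweenness(g, weights = 1 / igraph::E(g)$weight),
                 tolerance = 1e-8)
    expect_equal(edge_betweenness(net, weighted = FALSE)$betweenness,
                 igraph::edge_betweenness(g, weights = rep(1, igraph::ecount(g))),
                 tolerance = 1e-8)
  }
})

test_that("the bridge between two triangles is removed first", {
  net <- net_from_edges(triangle_pair_edges(bridge = TRUE))
  part <- girvan_newman(net, weighted = FALSE)
  bridge_row <- which(net$edges$from == "c" & net$edges$to == "d")
  expect_equal(part$removal_order[1], bridge_row)
  expect_equal(part$n_communities, 2)
  memb <- stats::setNames(part$membership$community, part$membership$id)
  expect_equal(length(unique(memb[c("a", "b", "c")])), 1)
  expect_equal(length(unique(memb[c("d", "e", "f")])), 1)
})

test_that("edgeless networks yield singleton communities with Q = 0", {
  empty <- network_from_matrix(matrix(0, 4, 4,
                                      dimnames = list(letters[1:4], letters[1:4])))
  part <- girvan_newman(empty)
  expect_equal(part$n_communities, 4)
  expect_equal(part$q, 0)
})

test_that("girvan_newman recovers planted communities when p_in >> p_out", {
  aris <- vapply(1:5, function(s) {
    sim <- small_sim(seed = s, n_communities = 3, p_within = 0.95,
                     n_flocks = 150)
    gbi <- filter_individuals(build_gbi(sim$observations), 3)
    net <- build_flock_network(gbi, sim_attributes(sim))
    part <- girvan_newman(net)
    truth <- stats::setNames(sim$truth$planted_community, sim$truth$id)
    mclust::adjustedRandIndex(part$membership$community,
                              truth[part$membership$id])
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("returned partition maximises Q over the whole dendrogram", {
  set.seed(7)
  for (rep in 1:20) {
    net <- random_test_network(sample(4:8, 1), p = 0.5)
    if (nrow(net$edges) == 0) next
    part <- girvan_newman(net, keep_steps = TRUE)
    qs <- apply(part$memb_steps, 1, function(m) {
      modularity_q(net, stats::setNames(m, net$nodes$id))
    })
    expect_equal(part$q, max(qs), tolerance = 1e-10)
    expect_gte(part$q, -1e-12)  # one-community partition (Q = 0) always available
  }
})

test_that("exhaustive max-Q diagnostic on tiny graphs (dendrogram may miss it)", {
  set.seed(19)
  shortfalls <- 0
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    net <- random_test_network(n, p = 0.5)
    if (nrow(net$edges) == 0) next
    part <- girvan_newman(net)
    best <- max(vapply(all_partitions(n), function(p) {
      modularity_q(net, stats::setNames(p, net$nodes$id))
    }, numeric(1)))
    expect_lte(part$q, best + 1e-10)
    if (part$q < best - 1e-10) shortfalls <- shortfalls + 1
  }
  # diagnostic, not a guarantee: GN is a heuristic for global max-Q
  message("girvan_newman below exhaustive max-Q on ", shortfalls,
          "/10 tiny graphs")
})

test_that("assortativity hits its extremes on canonical graphs", {
  cliques <- net_from_edges(triangle_pair_edges(bridge = FALSE))
  labels <- stats::setNames(rep(c("x", "y"), each = 3), cliques$nodes$id)
  expect_equal(assortativity_categorical(cliques, labels), 1)

  bip <- net_from_edges(data.frame(
    from = c("a1", "a1", "a2", "a2"),
    to = c("b1", "b2", "b1", "b2"), weight = 1))
  side <- stats::setNames(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2"))
  expect_equal(assortativity_categorical(bip, side), -1)

  one_class <- stats::setNames(rep("A", 6), cliques$nodes$id)
  expect_error(assortativity_categorical(cliques, one_class), "single label")
})

test_that("assortativity is invariant to global edge-weight rescaling", {
  set.seed(3)
  net <- random_test_network(10, p = 0.4)
  labels <- stats::setNames(sample(c("A", "B"), 10, replace = TRUE),
                            net$nodes$id)
  r1 <- assortativity_categorical(net, labels)
  scaled <- net
  scaled$edges$weight <- scaled$edges$weight * 7.3
  expect_equal(assortativity_categorical(scaled, labels), r1,
               tolerance = 1e-12)
})

test_that("girvan_newman is deterministic and label-isomorphic", {
  sim <- small_sim(seed = 21, n_flocks = 80)
  gbi <- filter_individuals(build_gbi(sim$observations), 3)
  net <- build_flock_network(gbi)
  p1 <- girvan_newman(net)
  p2 <- girvan_newman(net)
  expect_identical(p1$membership, p2$membership)

  # renaming the nodes (reversing lexicographic order) must permute the
  # partition, not change it
  ids <- net$nodes$id
  newids <- stats::setNames(rev(sprintf("Z%03d", seq_along(ids))), ids)
  gbi2 <- gbi
  colnames(gbi2) <- unname(newids[colnames(gbi)])
  gbi2 <- gbi2[, order(colnames(gbi2)), drop = FALSE]
  p3 <- girvan_newman(build_flock_network(gbi2))
  m1 <- stats::setNames(p1$membership$community, p1$membership$id)
  m3 <- stats::setNames(p3$membership$community, p3$membership$id)
  m3_back <- m3[unname(newids[ids])]
  expect_equal(mclust::adjustedRandIndex(m1, m3_back), 1)
})

test_that("mixing matrix entries are a symmetric unit-sum distribution", {
  net <- net_from_edges(triangle_pair_edges(bridge = TRUE))
  labels <- stats::setNames(rep(c("x", "y"), each = 3), net$nodes$id)
  mm <- mixing_matrix(net, labels)
  expect_equal(sum(mm$e), 1)
  expect_equal(mm$e, t(mm$e))
  expect_equal(mm$a, rowSums(mm$e))
})
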
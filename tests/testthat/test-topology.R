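path_graph <- function() build_graph(data.frame(from = c("a", "b"),
                                                to = c("b", "c")))
star_graph <- function(k = 5) {
  build_graph(data.frame(from = "hub", to = sprintf("leaf%d", seq_len(k))),
              roles = c(hub = "chaperone"))
}

test_that("build_graph deduplicates edges, drops loops, keeps isolates", {
  g <- build_graph(data.frame(from = c("a", "b"), to = c("b", "a")))
  expect_equal(igraph::ecount(g), 1)

  expect_warning(g2 <- build_graph(data.frame(from = c("a", "a"),
                                              to = c("a", "b"))),
                 "self-loop")
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::graph_attr(g2, "n_self_loops_dropped"), 1)

  g3 <- build_graph(data.frame(from = character(0), to = character(0)),
                    nodes = c("x", "y", "z"))
  expect_equal(igraph::vcount(g3), 3)
  expect_equal(igraph::ecount(g3), 0)

  ## unknown roles default to substrate
  g4 <- build_graph(data.frame(from = "a", to = "b"),
                    roles = c(a = "chaperone"))
  roles <- setNames(igraph::V(g4)$role, igraph::V(g4)$name)
  expect_equal(unname(roles["b"]), "substrate")

  expect_error(build_graph(data.frame(from = "", to = "b")), "non-empty")
})

test_that("node deletion retains orphans and keeps exact edge bookkeeping", {
  st <- star_graph(5)
  del <- delete_node(st, "hub")
  expect_equal(igraph::vcount(del$network), 5)
  expect_equal(igraph::ecount(del$network), 0)
  expect_equal(sort(del$orphans), sort(sprintf("leaf%d", 1:5)))
  expect_equal(del$orphan_fraction, 1)

  p <- path_graph()
  del2 <- delete_node(p, "a")  # leaf of a path: no orphans
  expect_equal(del2$n_orphans, 0)
  expect_equal(igraph::ecount(del2$network), 1)
  expect_error(delete_node(p, "zzz"), "unknown node")
})

test_that("deletion bookkeeping identities hold on generated networks", {
  for (seed in c(21L, 22L)) {
    cfg <- tiny_config(); cfg$seed <- seed
    g <- generate_network(cfg)
    deg <- igraph::degree(g)
    chaps <- igraph::V(g)$name[igraph::V(g)$role == "chaperone"]
    target <- chaps[which.max(deg[chaps])]
    del <- delete_node(g, target)
    expect_equal(igraph::vcount(del$network), igraph::vcount(g) - 1)
    expect_equal(igraph::ecount(del$network),
                 igraph::ecount(g) - deg[[target]])
    ## orphans are exactly the degree-1 neighbours of the deleted node
    nbrs <- igraph::neighbors(g, target)$name
    expect_setequal(del$orphans, nbrs[deg[nbrs] == 1])
  }
})

test_that("degree, neighborhood connectivity and clustering match hand values", {
  tri <- build_graph(data.frame(from = c("a", "b", "c"),
                                to = c("b", "c", "a")))
  expect_true(all(node_degree(tri)$degree == 2))
  expect_equal(unname(neighborhood_connectivity(tri)), rep(2, 3))
  expect_true(all(clustering_coefficient(tri)$per_node == 1))

  st <- star_graph(5)
  nd <- node_degree(st)
  expect_equal(unname(nd$degree["hub"]), 5)
  expect_equal(unname(nd$degree["leaf1"]), 1)
  expect_equal(nd$distribution$n_nodes[nd$distribution$k == 1], 5)
  nc <- neighborhood_connectivity(st)
  expect_equal(unname(nc["hub"]), 1)
  expect_equal(unname(nc["leaf3"]), 5)
  cc <- clustering_coefficient(st)
  expect_equal(unname(cc$per_node["hub"]), 0)

  p <- path_graph()
  ncp <- neighborhood_connectivity(p)
  expect_equal(unname(ncp["a"]), 2)
  expect_equal(unname(ncp["b"]), 1)

  iso <- build_graph(data.frame(from = "a", to = "b"), nodes = "lone")
  expect_equal(unname(node_degree(iso)$degree["lone"]), 0)
  expect_true(is.na(neighborhood_connectivity(iso)["lone"]))

  ## square with one diagonal: a diagonal endpoint has k = 3 and 2 connected
  ## neighbour pairs -> C = 2*2/(3*2) = 2/3
  sq <- build_graph(data.frame(from = c("a", "b", "c", "d", "a"),
                               to = c("b", "c", "d", "a", "c")))
  ccs <- clustering_coefficient(sq)
  expect_equal(unname(ccs$per_node["a"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(ccs$per_node["b"]), 1, tolerance = 1e-12)
  ## two average conventions both reported
  expect_equal(ccs$average_all_nodes, mean(ccs$per_node))
  expect_equal(ccs$average_degree_ge2, mean(ccs$per_node[c("a", "b", "c", "d")]))
})

test_that("betweenness matches hand-derived values with component normalization", {
  p <- path_graph()
  bc <- betweenness_centrality(p)
  expect_equal(unname(bc["b"]), 1)
  expect_equal(unname(bc["a"]), 0)

  st <- star_graph(6)
  expect_equal(unname(betweenness_centrality(st)["hub"]), 1)

  ## 4-cycle: each node interior to half the geodesics of one antipodal
  ## pair; normalizer 3 -> 1/6
  cyc <- build_graph(data.frame(from = c("a", "b", "c", "d"),
                                to = c("b", "c", "d", "a")))
  expect_equal(unname(betweenness_centrality(cyc)), rep(1 / 6, 4),
               tolerance = 1e-12)

  ## nodes in components of size <= 2 (orphans) get 0
  two <- build_graph(data.frame(from = c("a", "x"), to = c("b", "y")),
                     nodes = "lone")
  expect_true(all(betweenness_centrality(two) == 0))
})

test_that("betweenness equals the brute-force enumeration oracle", {
  set.seed(2024)
  n_graphs <- 60
  for (i in seq_len(n_graphs)) {
    n <- sample(5:30, 1)
    adj <- random_adjacency(n, runif(1, 0.05, 0.3))
    g <- adjacency_to_graph(adj)
    got <- betweenness_centrality(g)[sprintf("n%02d", seq_len(n))]
    expect_lt(max(abs(unname(got) - bc_oracle(adj))), 1e-9)
  }
})

test_that("unnormalized betweenness obeys the pairwise sum rule", {
  ## summed over nodes, interior path fractions count each reachable pair
  ## (distance >= 2) exactly (d - 1) times... verified via the oracle's
  ## distance matrix on small random graphs
  set.seed(99)
  for (i in 1:5) {
    adj <- random_adjacency(12, 0.25)
    g <- adjacency_to_graph(adj)
    raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
    dist <- bfs_distances(adj)
    d <- dist[upper.tri(dist)]
    expected <- sum((d[is.finite(d) & d >= 2] - 1))
    expect_equal(sum(raw), expected, tolerance = 1e-9)
  }
})

test_that("degree-binned averages equal brute-force group-by means", {
  tri <- build_graph(data.frame(from = c("a", "b", "c"),
                                to = c("b", "c", "a")))
  prof_tri <- node_topology(tri)
  b <- degree_binned_average(prof_tri, "clustering")
  expect_equal(nrow(b), 1)
  expect_equal(b$mean_value, 1)

  st <- star_graph(5)
  prof <- node_topology(st)
  b2 <- degree_binned_average(prof, "neighborhood_connectivity")
  expect_equal(b2$k, c(1, 5))
  expect_equal(b2$mean_value, c(5, 1))
  expect_equal(sum(b2$n_nodes), 6)

  cfg <- tiny_config()
  g <- generate_network(cfg)
  profg <- node_topology(g)
  got <- degree_binned_average(profg, "betweenness")
  oracle <- tapply(profg$betweenness, profg$degree, mean)
  expect_equal(got$mean_value, unname(as.numeric(oracle)), tolerance = 1e-12)
  expect_equal(sum(got$n_nodes), nrow(profg))
  expect_error(degree_binned_average(profg, "nope"), "unknown attribute")
})

test_that("KS comparison matches hand-evaluated ECDF differences", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_compare(1:4, 101:104)$D, 1)
  expect_equal(ks_compare(c(1, 2, 3, 4), c(3, 4, 5, 6))$D, 0.5)
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")
})

test_that("hub deletion perturbs binned attribute distributions only modestly", {
  cfg <- sim_config(n_chaperones = 40L, n_substrates = 800L,
                    mean_substrate_multiplicity = 4, hub_exponent = 1.5,
                    chaperone_edge_prob = 0.05, seed = 404L)
  g <- generate_network(cfg)
  prof <- node_topology(g)
  chap <- prof[prof$role == "chaperone", ]
  hub <- chap$node[which.max(chap$degree)]
  del_hub <- delete_node(g, hub)
  cmp_hub <- compare_attribute_distributions(prof,
                                             node_topology(del_hub$network))
  D_hub <- cmp_hub$D[cmp_hub$attribute == "neighborhood_connectivity"]
  expect_lt(D_hub, 0.35)

  ## deleting a random low-degree substrate barely moves the distribution
  subs <- prof[prof$role == "substrate" & prof$degree == 1, ]
  del_leaf <- delete_node(g, subs$node[1])
  cmp_leaf <- compare_attribute_distributions(prof,
                                              node_topology(del_leaf$network))
  expect_lt(max(cmp_leaf$D), 0.1)
  expect_lte(cmp_leaf$D[cmp_leaf$attribute == "neighborhood_connectivity"],
             D_hub + 1e-12)
})
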
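test_that("networks keep exactly the taxa touched by edges", {
  e <- tibble::tibble(taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "d"),
                      r = c(0.6, 0.7, -0.8), sign = c(1L, 1L, -1L))
  net <- build_network(e)
  expect_setequal(igraph::V(net$graph)$name, c("a", "b", "c", "d"))
  empty <- build_network(e[0, ])
  expect_equal(igraph::vcount(empty$graph), 0)
  expect_error(build_network(rbind(e, e[1, ])), "duplicate")
  eself <- e
  eself$taxon_b[1] <- "a"
  expect_error(build_network(eself), "self-loop")
})

test_that("triangle and disjoint-triangle topology match closed forms", {
  tri <- make_net(data.frame(taxon_a = c("a", "b", "c"),
                             taxon_b = c("b", "c", "a")))
  ts <- topology_summary(tri)
  expect_equal(ts$clustering_coefficient, 1)
  expect_equal(ts$diameter, 1)
  expect_equal(ts$modularity, 0)
  expect_equal(ts$n_modules, 1L)
  expect_equal(ts$average_degree, 2)

  two <- make_net(data.frame(
    taxon_a = c("a", "b", "c", "x", "y", "z"),
    taxon_b = c("b", "c", "a", "y", "z", "x")))
  ts2 <- topology_summary(two)
  expect_equal(ts2$modularity, 0.5)
  expect_equal(ts2$n_modules, 2L)
  # exhaustive partition search confirms 0.5 is the optimum
  expect_equal(oracle_modularity_max(net_adjacency(two)), 0.5)
})

test_that("topology identities hold on random signed networks", {
  for (s in 1:10) {
    net <- random_net(n = sample(5:10, 1), p = 0.5, seed = 100 + s,
                      signed = TRUE)
    ts <- topology_summary(net)
    expect_equal(ts$average_degree,
                 round(2 * ts$n_edges / ts$n_nodes, 3))
    expect_equal(ts$n_positive + ts$n_negative, ts$n_edges)
    expect_equal(ts$pct_positive + ts$pct_negative, 100, tolerance = 0.11)
    expect_equal(ts$weighted_degree,
                 2 * sum(abs(net$edges$r)) / ts$n_nodes, tolerance = 1e-10)
  }
})

test_that("Louvain module assignment is reproducible run-to-run", {
  net <- random_net(12, p = 0.3, seed = 42, signed = TRUE)
  s1 <- topology_summary(net, seed = 9)
  s2 <- topology_summary(net, seed = 9)
  expect_identical(s1, s2)
})

test_that("star and path centralities match closed forms", {
  st <- star_net(4)
  cent <- centralities(st)
  hub <- cent[cent$taxon == "hub", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$betweenness, 1)
  expect_equal(hub$closeness, 1)
  expect_equal(hub$eigenvector, 1)
  leaves <- cent[cent$taxon != "hub", ]
  expect_true(all(leaves$betweenness == 0))
  expect_equal(leaves$eigenvector, rep(0.5, 4), tolerance = 1e-6)

  pth <- path_net(c("A", "B", "C"))
  cp <- centralities(pth)
  expect_equal(cp$betweenness[cp$taxon == "B"], 1)
  expect_equal(cp$betweenness[cp$taxon != "B"], c(0, 0))

  rg <- ring_net(6)
  cr <- centralities(rg)
  for (col in c("degree", "betweenness", "closeness", "eigenvector")) {
    expect_equal(diff(range(cr[[col]])), 0, tolerance = 1e-6)
  }
})

test_that("ego subnetworks are induced closed neighborhoods", {
  st <- star_net(5)
  ego <- ego_subnetwork(st, "hub")
  expect_equal(igraph::vcount(ego$graph), 6)
  expect_false(ego$focal_absent)

  absent <- ego_subnetwork(st, "Wolbachia")
  expect_true(absent$focal_absent)
  expect_equal(igraph::vcount(absent$graph), 0)

  # focus with 3 neighbors and 1 edge among them: 4 nodes, 4 edges
  net <- make_net(data.frame(
    taxon_a = c("f", "f", "f", "n1", "n2"),
    taxon_b = c("n1", "n2", "n3", "n2", "x")))
  ego2 <- ego_subnetwork(net, "f")
  expect_equal(igraph::vcount(ego2$graph), 4)
  expect_equal(igraph::ecount(ego2$graph), 4)
  expect_false("x" %in% igraph::V(ego2$graph)$name)
})

test_that("GraphML and GEXF exports are valid and Gephi-shaped", {
  net <- random_net(8, p = 0.5, seed = 77, signed = TRUE)
  tmp <- withr::local_tempdir()
  write_graphml(net, file.path(tmp, "n.graphml"))
  back <- igraph::read_graph(file.path(tmp, "n.graphml"), format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net$graph))
  expect_equal(igraph::ecount(back), igraph::ecount(net$graph))
  expect_true("module" %in% igraph::vertex_attr_names(back))

  write_gexf(net, file.path(tmp, "n.gexf"))
  doc <- xml2::read_xml(file.path(tmp, "n.gexf"))
  ns <- xml2::xml_ns(doc)
  nodes <- xml2::xml_find_all(doc, "//d1:node", ns)
  edges <- xml2::xml_find_all(doc, "//d1:edge", ns)
  expect_length(nodes, igraph::vcount(net$graph))
  expect_length(edges, igraph::ecount(net$graph))

  # positive-only export drops exactly the negative edges
  write_graphml(net, file.path(tmp, "pos.graphml"), positive_only = TRUE)
  pos <- igraph::read_graph(file.path(tmp, "pos.graphml"), format = "graphml")
  expect_equal(igraph::ecount(pos), sum(net$edges$sign == 1))
})
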
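test_that("star and complete-graph attacks match pair counting", {
  st <- star_net(5)
  curve <- attack(st, "degree")
  # removing the hub first disconnects all 15 pairs at once
  expect_equal(curve$connectivity_loss[2], 1)
  expect_equal(pct_disconnection_point(curve), 1 / 6)

  k4 <- make_net(t(combn(c("a", "b", "c", "d"), 2)))
  for (s in c("random", "degree", "betweenness", "cascading")) {
    cv <- attack(k4, s, seed = 3)
    expect_equal(cv$connectivity_loss[2], 1 - 3 / 6)
  }
  expect_error(attack(build_network(st$edges[0, ])), "empty")
})

test_that("disconnection points handle boundary levels", {
  st <- star_net(5)
  curve <- attack(st, "degree")
  expect_equal(pct_disconnection_point(curve, level = 0), 0)
  # a complete graph loses pairs gradually; level 0.999 only at the end
  k5 <- make_net(t(combn(letters[1:5], 2)))
  cv <- attack(k5, "degree")
  expect_equal(pct_disconnection_point(cv, level = 0.999), 4 / 5)
})

test_that("connectivity loss is monotone for every strategy and seed", {
  for (s in 1:6) {
    net <- random_net(n = sample(6:12, 1), p = 0.35, seed = 200 + s,
                      signed = TRUE)
    for (strat in c("random", "degree", "betweenness", "cascading")) {
      cv <- attack(net, strat, seed = s)
      expect_true(all(diff(cv$connectivity_loss) >= -1e-12))
      expect_equal(cv$connectivity_loss[1], 0)
      expect_equal(cv$connectivity_loss[nrow(cv)], 1)
    }
  }
})

test_that("degree and cascading attacks coincide on stars", {
  st <- star_net(7)
  cd <- attack(st, "degree")
  cc <- attack(st, "cascading")
  expect_equal(cd$connectivity_loss, cc$connectivity_loss)
  expect_equal(cd$removed[2], cc$removed[2])  # hub falls first in both
})

test_that("attack curves equal BFS-oracle pair recounting at every step", {
  for (s in 1:4) {
    net <- random_net(n = 9, p = 0.3, seed = 300 + s, signed = TRUE)
    cv <- attack(net, "degree")
    g <- net$graph
    pairs0 <- oracle_pair_connectivity(net_adjacency(net))
    for (k in seq_len(nrow(cv) - 1)) {
      g <- igraph::delete_vertices(g, cv$removed[k + 1])
      adj <- as.matrix(igraph::as_adjacency_matrix(g))
      expect_equal(cv$connectivity_loss[k + 1],
                   1 - oracle_pair_connectivity(adj) / pairs0,
                   tolerance = 1e-12)
    }
  }
})

test_that("adding one node to a triangle gives the hand-enumerated APL", {
  tri <- make_net(data.frame(taxon_a = c("a", "b", "c"),
                             taxon_b = c("b", "c", "a")))
  curves <- add_nodes(tri, n_add = 1, reps = 1, seed = 2)
  expect_equal(curves$lcc_size, c(3, 4))
  # distances: 3 triangle pairs at 1, new node at 1,2,2 -> mean 8/6
  expect_equal(curves$apl[2], 8 / 6, tolerance = 1e-12)
  # n_add = 0 returns the base network's stats
  base <- add_nodes(tri, n_add = 0)
  expect_equal(base$lcc_size, 3)
  expect_equal(base$apl, 1)
})

test_that("LCC never shrinks while nodes are added", {
  net <- random_net(8, p = 0.3, seed = 11, signed = TRUE)
  curves <- add_nodes(net, n_add = 40, reps = 3, seed = 5)
  for (r in unique(curves$replicate)) {
    expect_true(all(diff(curves$lcc_size[curves$replicate == r]) >= 0))
  }
  expect_identical(curves, add_nodes(net, n_add = 40, reps = 3, seed = 5))
})

test_that("multi-edge attachment can bridge disjoint components", {
  two_tri <- make_net(data.frame(
    taxon_a = c("a", "b", "c", "x", "y", "z"),
    taxon_b = c("b", "c", "a", "y", "z", "x")))
  # with one edge per new node components can never merge
  c1 <- add_nodes(two_tri, n_add = 30, reps = 3, m = 1, seed = 8)
  expect_true(all(c1$lcc_size <= 3 + c1$step))
  expect_true(all(c1$lcc_size < 6 + c1$step))
  # with two edges per new node some replicate bridges the triangles
  c2 <- add_nodes(two_tri, n_add = 30, reps = 5, m = 2, seed = 8)
  bridged <- c2 |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(b = any(lcc_size == 6 + step))
  expect_true(any(bridged$b))
})

test_that("identical addition curves give p = 1; shifts match sign enumeration", {
  base <- tibble::tibble(replicate = 1L, step = 0:10,
                         lcc_size = c(5, 5:14), apl = seq(1, 2, length = 11))
  same <- compare_addition(base, base)
  expect_equal(same$p_value, c(1, 1))

  shifted <- base
  shifted$apl <- base$apl + 0.3          # strict shift in APL only
  cmp <- compare_addition(base, shifted)
  apl_row <- cmp[cmp$metric == "apl", ]
  expect_equal(apl_row$p_value,
               oracle_wilcoxon_exact(base$apl - shifted$apl),
               tolerance = 1e-12)
  expect_equal(apl_row$p_value, 2 / 2^11, tolerance = 1e-12)
  expect_lt(apl_row$ci_upper, 0)
  # BH adjustment is monotone and bounded by the raw maximum
  expect_true(all(cmp$p_adjusted >= cmp$p_value - 1e-15))
})
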
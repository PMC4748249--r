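test_that("classic graphs have the defining edge counts and degrees", {
  k5 <- make_classic("complete", n = 5)
  expect_equal(igraph::ecount(k5), 10)
  expect_true(all(igraph::degree(k5) == 4))

  st <- make_classic("star", n = 11)
  expect_equal(igraph::ecount(st), 10)
  expect_equal(sort(unname(igraph::degree(st))), c(rep(1, 10), 10))

  kb <- make_classic("complete_bipartite", m = 3, n2 = 4)
  expect_equal(igraph::ecount(kb), 12)
  expect_equal(max(igraph::distances(kb)), 2)

  lat <- make_classic("lattice", w = 4, h = 3)
  expect_equal(igraph::vcount(lat), 12)
  expect_equal(igraph::ecount(lat), 4 * 2 + 3 * 3)  # grid edges

  expect_error(make_classic("cycle", n = 2), "cycle")
  expect_error(make_classic("complete", n = 1), "complete")
})

test_that("hierarchical network is deterministic with the stated counts", {
  # level 1 is the seed clique itself
  h1 <- make_hierarchical(1)
  expect_true(igraph::isomorphic(h1, igraph::make_full_graph(4)))

  # level 2 by hand enumeration of the wiring rule: 4 cliques (24 edges)
  # + 9 peripheral-to-centre links + the replica-centre triangle
  h2 <- make_hierarchical(2)
  expect_equal(igraph::vcount(h2), 16)
  expect_equal(igraph::ecount(h2), 24 + 9 + 3)

  # node count is module_size^levels exactly
  expect_equal(igraph::vcount(make_hierarchical(3)), 64)
  h4 <- make_hierarchical(4)
  expect_equal(igraph::vcount(h4), 256)
  expect_equal(igraph::ecount(h4), 879)

  # deterministic and idempotent
  expect_identical(igraph::as_edgelist(make_hierarchical(3)),
                   igraph::as_edgelist(make_hierarchical(3)))

  expect_error(make_hierarchical(4, wiring_rule = "nope"), "wiring_rule")
  expect_error(make_hierarchical(0), "levels")
})

test_that("toy-worm networks are valid, reproducible, and grid-sized", {
  tw <- make_toy_worm(grid_side = 8, seed = 5)
  expect_true(is_network(tw))
  expect_lte(igraph::vcount(tw), 64)
  expect_gte(igraph::vcount(tw), 3)
  tw2 <- make_toy_worm(grid_side = 8, seed = 5)
  expect_identical(igraph::as_edgelist(tw), igraph::as_edgelist(tw2))
  tw3 <- make_toy_worm(grid_side = 8, seed = 6)
  expect_false(identical(igraph::as_edgelist(tw), igraph::as_edgelist(tw3)))
  expect_error(make_toy_worm(grid_side = 1), "grid_side")
})

test_that("preferential attachment adds m edges per node and stays simple", {
  ba <- make_barabasi_albert(n = 60, m = 3, m0 = 5, seed = 2)
  expect_true(is_network(ba))
  expect_equal(igraph::ecount(ba), 3 * (60 - 5))
  # default study parameters: mean degree exactly 19
  ba200 <- make_barabasi_albert(seed = 1)
  expect_equal(igraph::vcount(ba200), 200)
  expect_equal(mean(igraph::degree(ba200)), 19)
  expect_error(make_barabasi_albert(n = 20, m = 6, m0 = 5), "m <= m0")
})

test_that("degree-preserving randomisation keeps degrees and connectivity", {
  # triangle: no feasible swap, input returned unchanged with a warning
  k3 <- make_classic("complete", n = 3)
  expect_warning(out <- randomize_degree_preserving(k3, 100, seed = 1),
                 "no feasible")
  expect_true(igraph::isomorphic(out, k3))

  # 12-node graph: degree sequence identical for 10^3 swaps, several seeds
  g <- random_connected_graph(12, 0.35, 7)
  for (s in 1:4) {
    rg <- randomize_degree_preserving(g, 1000, seed = s)
    expect_equal(unname(igraph::degree(rg)), unname(igraph::degree(g)))
    expect_equal(igraph::ecount(rg), igraph::ecount(g))
    expect_true(is_network(rg))  # simple + connected
  }
  # actually randomises
  rg <- randomize_degree_preserving(make_hierarchical(3), 2000, seed = 1)
  expect_false(identical(igraph::as_edgelist(rg),
                         igraph::as_edgelist(make_hierarchical(3))))
})

test_that("ensembles are seeded, reproducible, and sized as requested", {
  one <- sample_ensemble(function(s) make_toy_worm(8, seed = s), 1, seed = 3)
  expect_length(one, 1)
  expect_true(is_network(one[[1]]))

  e1 <- sample_ensemble(function(s) make_toy_worm(8, seed = s), 3, seed = 3)
  e2 <- sample_ensemble(function(s) make_toy_worm(8, seed = s), 3, seed = 3)
  for (i in 1:3)
    expect_identical(igraph::as_edgelist(e1[[i]]), igraph::as_edgelist(e2[[i]]))

  # ensemble statistics equal a recomputation from the stored samples
  es <- ensemble_stats(e1, components = "degree")
  expect_equal(es$mean$delta,
               mean(sapply(e1, function(g) mean(igraph::degree(g)))))
})
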
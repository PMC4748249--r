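test_that("closed forms match their algebraic special cases", {
  expect_equal(rho1_complete(256, 1), 1 / 256)
  expect_equal(rho1_complete(2, 2), 2 / 3)
  expect_equal(rho2_bipartite_limit(17, 1), 1 / 17)
  # amplifier ordering for advantageous invaders
  expect_gt(rho2_bipartite_limit(256, 1.5), rho1_complete(256, 1.5))
  # and the reverse for disadvantageous ones
  expect_lt(rho2_bipartite_limit(50, 0.8), rho1_complete(50, 0.8))
  expect_error(rho1_complete(10, -1), "r must be")
  expect_error(rho2_bipartite_limit(10, 0), "r must be")
})

test_that("exact solver agrees with closed forms and a dense oracle", {
  # single-pair random walk: K2 at r = 2 fixes with probability 2/3
  expect_equal(exact_fixation(make_classic("complete", n = 2), 2)$average,
               2 / 3, tolerance = 1e-12)
  # complete graph equals the Moran closed form
  expect_equal(exact_fixation(make_classic("complete", n = 5), 1.5)$average,
               rho1_complete(5, 1.5), tolerance = 1e-10)
  # isothermal (circulation theorem): cycle reduces to the homogeneous case
  expect_equal(exact_fixation(make_classic("cycle", n = 5), 1.5)$average,
               rho1_complete(5, 1.5), tolerance = 1e-10)
  # star is an amplifier and matches an independent dense full-chain solve
  st <- make_classic("star", n = 4)
  ex <- exact_fixation(st, 2)
  expect_gt(ex$average, rho1_complete(4, 2))
  oracle <- dense_fixation(st, 2)
  expect_equal(ex$per_node, oracle$per_node, tolerance = 1e-9)
  expect_error(exact_fixation(make_classic("complete", n = 15), 1.5), "cap")
})

test_that("isothermal theorem holds exactly on regular fixtures", {
  for (g in list(make_classic("cycle", n = 7),
                 make_classic("complete", n = 6),
                 igraph::make_lattice(c(3, 4), periodic = TRUE))) {
    N <- igraph::vcount(g)
    for (r in c(0.5, 1.5, 2)) {
      expect_equal(exact_fixation(g, r)$average, rho1_complete(N, r),
                   tolerance = 1e-10)
    }
  }
})

test_that("neutral law: per-node fixation sums to 1, average is 1/N", {
  for (g in fixture_battery()) {
    ex <- exact_fixation(g, 1)
    expect_equal(sum(ex$per_node), 1, tolerance = 1e-10)
    expect_equal(ex$average, 1 / igraph::vcount(g), tolerance = 1e-10)
  }
})

test_that("exact average fixation is strictly increasing in r", {
  rs <- c(0.5, 1, 1.5, 2, 3)
  for (g in fixture_battery()) {
    avg <- vapply(rs, function(r) exact_fixation(g, r)$average, 0)
    expect_true(all(diff(avg) > 0))
  }
})

test_that("star amplification flips sign at neutrality", {
  st <- make_classic("star", n = 5)
  expect_gt(exact_fixation(st, 1.5)$average, rho1_complete(5, 1.5))
  expect_lt(exact_fixation(st, 0.7)$average, rho1_complete(5, 0.7))
})

test_that("transition distribution matches hand enumeration", {
  # K2, one mutant, r = 1: fixation or extinction, each 1/2
  k2 <- make_classic("complete", n = 2)
  td <- transition_distribution(k2, mutants = 1, r = 1)
  expect_equal(sort(td$prob), c(0.5, 0.5))
  expect_setequal(td$change, c("gain", "loss"))

  # star hub mutant (1 hub + 2 leaves): raw events are hub->leaf1 and
  # hub->leaf2 at r/2 each, leaf_i -> hub at 1 each; total r + 2
  st <- make_classic("star", n = 3)
  hub <- which(igraph::degree(st) == 2)
  r <- 1.7
  td <- transition_distribution(st, mutants = hub, r = r)
  gains <- td$prob[td$change == "gain"]
  losses <- td$prob[td$change == "loss"]
  expect_equal(sort(gains), rep((r / 2) / (r + 2), 2))
  expect_equal(losses, 2 / (r + 2))

  # normalisation over random states on random graphs
  set.seed(42)
  for (i in 1:20) {
    g <- random_connected_graph(sample(4:9, 1), 0.5, i)
    N <- igraph::vcount(g)
    m <- sample(N - 1, 1)
    td <- transition_distribution(g, mutants = sample(N, m), r = runif(1, 0.5, 2))
    expect_equal(sum(td$prob), 1, tolerance = 1e-12)
  }
  expect_error(transition_distribution(k2, mutants = 1:2, r = 1), "absorbing")
})

test_that("EMC simulator agrees with the exact solver on the battery", {
  for (g in fixture_battery()) {
    N <- igraph::vcount(g)
    for (r in c(0.5, 1, 1.5, 2)) {
      ex <- exact_fixation(g, r)$average
      mc <- simulate_fixation(g, r, trials = 20000, seed = 17)
      tol <- 3 * max(mc$stderr, sqrt(ex * (1 - ex) / mc$trials))
      expect_lt(abs(mc$p_hat - ex), tol + 1e-12)
    }
  }
})

test_that("simulator is seeded and reproducible", {
  g <- make_classic("star", n = 8)
  a <- simulate_fixation(g, 1.3, 5000, seed = 9)
  b <- simulate_fixation(g, 1.3, 5000, seed = 9)
  expect_identical(a$p_hat, b$p_hat)
  expect_equal(a$stderr, sqrt(a$p_hat * (1 - a$p_hat) / 5000))
})

test_that("bipartite graphs: balanced are isothermal, unbalanced amplify", {
  # balanced K_{m,m} is regular, hence isothermal: fixation equals the
  # homogeneous Moran form
  kb <- make_classic("complete_bipartite", m = 40, n2 = 40)
  expect_equal(unname(node_temperature(kb)), rep(1, 80), tolerance = 1e-12)
  mc <- simulate_fixation(kb, 1.2, trials = 30000, seed = 4)
  expect_lt(abs(mc$p_hat - rho1_complete(80, 1.2)), 3 * mc$stderr)

  # strongly unbalanced K_{1,n} (star) sits between the isothermal form
  # and the amplifier limit, approaching the latter as n grows
  st80 <- make_classic("star", n = 80)
  mc80 <- simulate_fixation(st80, 1.2, trials = 30000, seed = 6)
  expect_gt(mc80$p_hat - 3 * mc80$stderr, rho1_complete(80, 1.2))
  expect_lt(mc80$p_hat - 3 * mc80$stderr, rho2_bipartite_limit(80, 1.2))

  st20 <- make_classic("star", n = 20)
  mc20 <- simulate_fixation(st20, 1.2, trials = 30000, seed = 7)
  excess80 <- mc80$p_hat - rho1_complete(80, 1.2)
  excess20 <- mc20$p_hat - rho1_complete(20, 1.2)
  expect_gt(excess80, excess20)
})
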
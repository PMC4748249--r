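test_that("degree statistics use population moments", {
  cyc <- make_classic("cycle", n = 10)
  ds <- degree_stats(cyc)
  expect_equal(ds$mean, 2)
  expect_equal(ds$variance, 0)
  expect_equal(ds$skewness, 0)

  # star 1+4: degrees {4,1,1,1,1}; hand: mean 1.6, population variance 1.44
  st <- make_classic("star", n = 5)
  ds <- degree_stats(st)
  expect_equal(ds$mean, 1.6)
  expect_equal(ds$variance, 1.44)
  expect_equal(ds$sd, 1.2)
  expect_equal(ds$median, 1)
})

test_that("temperatures are conserved and heat heterogeneity is exact", {
  # regular graphs are isothermal
  for (g in list(make_classic("cycle", n = 8), make_classic("complete", n = 6))) {
    ts <- temperature_stats(g)
    expect_equal(ts$temperatures, rep(1, igraph::vcount(g)), tolerance = 1e-12)
    expect_equal(ts$heat_heterogeneity, 0, tolerance = 1e-12)
  }
  # star 1+4 by hand: T_hub = 4, T_leaf = 1/4, population variance 2.25
  st <- make_classic("star", n = 5)
  ts <- temperature_stats(st)
  expect_setequal(round(ts$temperatures, 10), c(4, 0.25))
  expect_equal(ts$heat_heterogeneity, 2.25)

  # conservation sum(T) = N on random graphs, to 1e-10
  for (i in 1:30) {
    g <- random_connected_graph(sample(4:20, 1), 0.3, 100 + i)
    expect_equal(sum(node_temperature(g)), igraph::vcount(g), tolerance = 1e-10)
  }

  # entropy of a regular graph: p_i = 1/N exactly
  expect_equal(temperature_stats(make_classic("cycle", n = 16))$entropy,
               log(16), tolerance = 1e-12)
  expect_equal(temperature_stats(make_classic("cycle", n = 16), base = 2)$entropy,
               4, tolerance = 1e-12)
})

test_that("heterogeneities are relabelling-invariant", {
  g <- random_connected_graph(12, 0.35, 5)
  set.seed(2)
  gp <- igraph::permute(g, sample(12))
  expect_equal(degree_stats(g)$variance, degree_stats(gp)$variance)
  expect_equal(temperature_stats(g)$heat_heterogeneity,
               temperature_stats(gp)$heat_heterogeneity, tolerance = 1e-12)
})

test_that("small-world statistics match hand-enumerated cases", {
  k6 <- make_classic("complete", n = 6)
  sw <- smallworld_stats(k6)
  expect_equal(sw$clustering, 1)
  expect_equal(sw$transitivity, 1)
  expect_equal(sw$path_length, 1)
  expect_equal(sw$diameter, 1)

  # path P4: pairs at distances 1,1,1,2,2,3 -> L = 10/6 = 5/3
  p4 <- igraph::make_lattice(4)
  sw <- smallworld_stats(p4)
  expect_equal(sw$clustering, 0)
  expect_equal(sw$path_length, 5 / 3)

  # cycles: local clustering equals transitivity (both 0 for n > 4)
  c8 <- make_classic("cycle", n = 8)
  expect_equal(smallworld_stats(c8)$clustering,
               smallworld_stats(c8)$transitivity)
})

test_that("power-law fit recovers planted exponents and rejects no-tail input", {
  expect_error(powerlaw_exponent(make_classic("cycle", n = 60)), "degenerate")

  # preferential attachment tail exponent ~ 3
  ba <- make_barabasi_albert(n = 10000, m = 3, m0 = 3, seed = 8)
  fit <- powerlaw_exponent(ba)
  expect_lt(abs(fit$exponent - 3), 0.35)

  # parameter recovery on a synthetic discrete power-law sample
  set.seed(31)
  alpha <- 2.5
  x <- floor((runif(10000))^(-1 / (alpha - 1)))  # discretised Pareto, xmin 1
  x <- x[x >= 1 & x <= 1e6]
  f <- igraph::fit_power_law(x, implementation = "plfit")
  expect_lt(abs(f$alpha - alpha), 0.15)
})

test_that("stats_record assembles rows and ensembles average them", {
  rec <- stats_record(make_classic("cycle", n = 10))
  expect_equal(rec$delta, 2)
  expect_equal(rec$degree_variance, 0)
  expect_equal(rec$H_t, 0)
  expect_equal(rec$C, 0)
  expect_equal(rec$L, mean(igraph::distances(make_classic("cycle", n = 10))[
    upper.tri(diag(10))]))

  nets <- lapply(1:5, function(s) make_toy_worm(7, seed = s))
  es <- ensemble_stats(nets, components = c("degree", "temperature"))
  singles <- sapply(nets, function(g) degree_stats(g)$mean)
  expect_equal(es$mean$delta, mean(singles))
  expect_equal(es$sd$delta, sd(singles))
})
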
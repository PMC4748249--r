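# Independent oracles used across the suite.  These deliberately take
# different computational routes from the package implementations:
# dense full-chain linear algebra instead of the sparse embedded-chain
# solver, literal double loops instead of vectorised forms, exhaustive
# search instead of greedy heuristics.

# Fixation probabilities by dense solve of the FULL Moran chain
# (self-transitions included), base::solve on the complete 2^N matrix.
dense_fixation <- function(net, r) {
  N <- igraph::vcount(net)
  stopifnot(N <= 12)
  deg <- igraph::degree(net)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  n_states <- 2^N
  full <- n_states - 1
  P <- matrix(0, n_states, n_states)  # rows/cols indexed by state + 1
  for (S in 0:full) {
    in_s <- bitwAnd(S, bitwShiftL(1, 0:(N - 1))) > 0
    if (!any(in_s) || all(in_s)) { P[S + 1, S + 1] <- 1; next }
    fit <- ifelse(in_s, r, 1)
    Wf <- sum(fit)
    for (u in 1:N) {
      for (v in adj[[u]]) {
        p_ev <- fit[u] / Wf / deg[u]
        Tst <- if (in_s[u]) bitwOr(S, bitwShiftL(1, v - 1))
               else bitwAnd(S, bitwNot(bitwShiftL(1, v - 1)))
        P[S + 1, Tst + 1] <- P[S + 1, Tst + 1] + p_ev
      }
    }
  }
  trans <- 2:(n_states - 1)
  A <- diag(length(trans)) - P[trans, trans]
  b <- P[trans, n_states]
  x <- solve(A, b)
  per_node <- x[match(bitwShiftL(1, 0:(N - 1)) + 1, trans)]
  list(per_node = per_node, average = mean(per_node))
}

# Literal double-loop evaluation of the sign-score rank correlation
double_loop_tau <- function(x, y) {
  n <- length(x)
  num <- sa <- sb <- 0
  for (i in 1:n) for (j in 1:n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    num <- num + a * b; sa <- sa + a^2; sb <- sb + b^2
  }
  num / sqrt(sa * sb)
}

# Exhaustive minimum number of boxes of diameter < l_B (subset DP)
brute_min_boxes <- function(net, l_B) {
  N <- igraph::vcount(net)
  stopifnot(N <= 10)
  D <- igraph::distances(net)
  n_states <- 2^N
  valid <- logical(n_states)
  for (S in 1:(n_states - 1)) {
    mem <- which(bitwAnd(S, bitwShiftL(1, 0:(N - 1))) > 0)
    valid[S + 1] <- max(D[mem, mem, drop = FALSE]) < l_B
  }
  dp <- rep(Inf, n_states); dp[1] <- 0
  for (S in 1:(n_states - 1)) {
    # iterate proper submasks containing the lowest set bit (canonical)
    low <- bitwAnd(S, -S)
    sub <- S
    while (sub > 0) {
      if (bitwAnd(sub, low) == low && valid[sub + 1] &&
          is.finite(dp[bitwAnd(S, bitwNot(sub)) + 1])) {
        dp[S + 1] <- min(dp[S + 1], dp[bitwAnd(S, bitwNot(sub)) + 1] + 1)
      }
      sub <- bitwAnd(sub - 1, S)
    }
  }
  dp[n_states]
}

# Connected Erdos-Renyi graph for property tests
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  for (i in 1:50) {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::vcount(g) >= 2) return(g)
  }
  igraph::make_ring(n)
}

# Small fixture battery for simulator-vs-exact comparisons
fixture_battery <- function() {
  list(path5 = igraph::make_lattice(5),
       cycle6 = igraph::make_ring(6),
       star6 = igraph::make_star(6, mode = "undirected"),
       k5 = igraph::make_full_graph(5),
       bip23 = igraph::make_full_bipartite_graph(2, 3),
       gnp8 = random_connected_graph(8, 0.4, 99))
}
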
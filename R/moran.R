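#' Fixation probability of the classical (complete-graph) Moran process
#'
#' Closed form for the homogeneous population of size `N`: a single
#' invader of relative fitness `r` fixes with probability
#' `(1 - 1/r) / (1 - r^-N)`.  By the Circulation Theorem every
#' isothermal network (all node temperatures equal, e.g. complete
#' graphs, cycles, toroidal lattices) has exactly this fixation
#' function.  The removable singularity at `r = 1` is handled by an
#' explicit limit branch with value `1/N`.
#'
#' @param N Population size (>= 2).
#' @param r Fitness (> 0); vectorised.
#' @return Fixation probability in `[0, 1]`.
#' @export
rho1_complete <- function(N, r) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (any(r <= 0)) stop("fitness r must be > 0", call. = FALSE)
  out <- numeric(length(r))
  at1 <- abs(r - 1) < 1e-12
  out[at1] <- 1 / N
  rr <- r[!at1]
  out[!at1] <- (1 - 1 / rr) / (1 - rr^(-N))
  out
}

#' Limit fixation probability of large complete bipartite networks
#'
#' Complete bipartite networks are evolutionary amplifiers: as both
#' parts grow, their fixation probability converges to the classical
#' Moran form evaluated at the squared fitness,
#' `(1 - r^-2) / (1 - r^-2N)`.  For `r > 1` this exceeds
#' `rho1_complete(N, r)`; at `r = 1` the limit is `1/N`.
#'
#' @inheritParams rho1_complete
#' @return Fixation probability in `[0, 1]`.
#' @export
rho2_bipartite_limit <- function(N, r) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (any(r <= 0)) stop("fitness r must be > 0", call. = FALSE)
  out <- numeric(length(r))
  at1 <- abs(r - 1) < 1e-12
  out[at1] <- 1 / N
  rr <- r[!at1]
  out[!at1] <- (1 - rr^(-2)) / (1 - rr^(-2 * N))
  out
}

#' Exact fixation probabilities by solving the absorbing-chain system
#'
#' The Moran invasion process on a network of order `N` is a Markov
#' chain on the `2^N` subsets of mutant nodes with two absorbing states
#' (no mutants, all mutants).  This solver assembles the embedded-chain
#' transition probabilities over all transient states and solves the
#' sparse linear system for the fixation probability of every state,
#' returning the per-node values (initial mutant at each single node)
#' and their uniform average.
#'
#' @param net An igraph network with at most `cap` nodes.
#' @param r Fitness (> 0).
#' @param cap Safety cap on `N` (default 14; the system has `2^N` rows).
#' @return List with `per_node` (fixation probability from each initial
#'   mutant), `average`, `r`, and `method = "exact"`.
#' @examples
#' exact_fixation(make_classic("complete", n = 4), r = 2)$average  # 8/15
#' @export
exact_fixation <- function(net, r, cap = 14L) {
  assert_network(net)
  if (r <= 0) stop("fitness r must be > 0", call. = FALSE)
  N <- igraph::vcount(net)
  if (N > cap)
    stop("exact_fixation solves a 2^N system; N = ", N,
         " exceeds the cap of ", cap, call. = FALSE)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  deg <- igraph::degree(net)
  masks <- bitwShiftL(1L, 0:(N - 1L))
  full <- sum(masks)

  n_states <- 2L^N
  trans <- vector("list", n_states - 2L)  # transient states 1 .. full-1
  ti <- tj <- tx <- list()
  rhs <- numeric(n_states - 2L)
  for (S in 1:(full - 1L)) {
    in_s <- bitwAnd(S, masks) > 0L
    rate_gain <- numeric(N)  # v joins the mutant set
    rate_lose <- numeric(N)  # v leaves it
    for (v in seq_len(N)) {
      nb <- adj[[v]]
      if (in_s[v]) {
        rate_lose[v] <- sum(1 / deg[nb[!in_s[nb]]])
      } else {
        rate_gain[v] <- r * sum(1 / deg[nb[in_s[nb]]])
      }
    }
    W <- sum(rate_gain) + sum(rate_lose)
    gain_v <- which(rate_gain > 0)
    lose_v <- which(rate_lose > 0)
    succ <- c(S + masks[gain_v], S - masks[lose_v])
    prob <- c(rate_gain[gain_v], rate_lose[lose_v]) / W
    keep <- succ != 0L & succ != full
    if (any(succ == full)) rhs[S] <- sum(prob[succ == full])
    ti[[S]] <- rep.int(S, sum(keep))
    tj[[S]] <- succ[keep]
    tx[[S]] <- prob[keep]
  }
  i <- unlist(ti); j <- unlist(tj); x <- unlist(tx)
  A <- Matrix::sparseMatrix(i = c(i, 1:(full - 1L)), j = c(j, 1:(full - 1L)),
                            x = c(-x, rep.int(1, full - 1L)),
                            dims = c(full - 1L, full - 1L))
  sol <- as.numeric(Matrix::solve(A, rhs))
  per_node <- sol[masks]
  list(per_node = per_node, average = mean(per_node), r = r, method = "exact")
}

#' Embedded-chain transition distribution of one invasion state
#'
#' For a non-absorbing mutant set, every state-changing replacement
#' event "node u replaces neighbour v" has raw weight `f_u / d_u`
#' (`f_u = r` for mutants, 1 for residents); events that leave the state
#' unchanged are excluded and the rest renormalised.  The returned
#' distribution aggregates events by the replaced node `v`.
#'
#' @param net An igraph network.
#' @param mutants Integer vector of mutant node indices (1-based).
#' @param r Fitness (> 0).
#' @return Data frame with columns `node` (the replaced node), `change`
#'   (`"gain"` if it becomes mutant, `"loss"` otherwise) and `prob`;
#'   probabilities sum to 1.
#' @export
transition_distribution <- function(net, mutants, r) {
  assert_network(net)
  if (r <= 0) stop("fitness r must be > 0", call. = FALSE)
  N <- igraph::vcount(net)
  mutants <- as.integer(mutants)
  if (length(mutants) == 0L || length(mutants) == N)
    stop("state is absorbing: no transitions", call. = FALSE)
  if (any(mutants < 1L | mutants > N)) stop("mutant ids out of range", call. = FALSE)
  is_mut <- logical(N); is_mut[mutants] <- TRUE
  deg <- igraph::degree(net)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  rate <- numeric(N); gain <- logical(N)
  for (v in seq_len(N)) {
    nb <- adj[[v]]
    opp <- nb[is_mut[nb] != is_mut[v]]
    if (length(opp) == 0L) next
    f <- ifelse(is_mut[opp], r, 1)
    rate[v] <- sum(f / deg[opp])
    gain[v] <- !is_mut[v]
  }
  keep <- rate > 0
  data.frame(node = which(keep),
             change = ifelse(gain[keep], "gain", "loss"),
             prob = rate[keep] / sum(rate[keep]))
}

#' Monte Carlo fixation probability by the EMC method
#'
#' Runs `trials` independent realisations of the Moran invasion process
#' using the embedded Markov chain (only state-changing replacement
#' events are simulated).  Each trial starts from a single mutant placed
#' uniformly at random and runs to absorption; the fixation fraction
#' estimates the average fixation probability.
#'
#' @param net An igraph network.
#' @param r Fitness (> 0).
#' @param trials Number of trials (>= 1).
#' @param seed Integer RNG seed.
#' @return A `fixation_estimate`: list with `r`, `p_hat`, `trials`,
#'   `stderr` (binomial), `method = "mc"`, and `mean_steps` (average EMC
#'   steps to absorption).
#' @export
simulate_fixation <- function(net, r, trials, seed = 1L) {
  assert_network(net)
  if (r <= 0) stop("fitness r must be > 0", call. = FALSE)
  trials <- as.integer(trials)
  if (is.na(trials) || trials < 1L) stop("trials must be >= 1", call. = FALSE)
  csr <- graph_csr(net)
  res <- cpp_emc_fixation(csr$idx, csr$ptr, r, trials,
                          derive_seed(seed, paste0("emc", r)))
  p <- res$fixed / trials
  structure(list(r = r, p_hat = p, trials = trials,
                 stderr = sqrt(p * (1 - p) / trials),
                 method = "mc", mean_steps = res$mean_steps),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Fixation estimate (%s): r = %g, p = %.5f (se %.5f, %d trials)\n",
              x$method, x$r, x$p_hat, x$stderr, x$trials))
  invisible(x)
}

# 0-based CSR adjacency for the C++ simulator
graph_csr <- function(net) {
  N <- igraph::vcount(net)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  deg <- lengths(adj)
  list(idx = as.integer(unlist(adj) - 1L),
       ptr = as.integer(cumsum(c(0L, deg))))
}
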
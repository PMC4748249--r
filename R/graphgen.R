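#' Classic benchmark graphs
#'
#' Small deterministic graphs used as oracles for the Moran process:
#' the complete graph and cycle (isothermal), the star and large
#' complete bipartite graphs (amplifiers of selection), and the
#' rectangular grid.
#'
#' @param family One of `"complete"`, `"cycle"`, `"star"`,
#'   `"complete_bipartite"`, `"lattice"`.
#' @param n Order of the graph (`complete`, `cycle`: total nodes;
#'   `star`: total nodes, one hub plus `n - 1` leaves).
#' @param m,n2 Part sizes for `complete_bipartite`.
#' @param w,h Grid dimensions for `lattice`.
#' @return An igraph network with 0-based integer `name` labels.
#' @examples
#' make_classic("complete", n = 5)
#' make_classic("complete_bipartite", m = 3, n2 = 4)
#' @export
make_classic <- function(family = c("complete", "cycle", "star",
                                    "complete_bipartite", "lattice"),
                         n = NULL, m = NULL, n2 = NULL, w = NULL, h = NULL) {
  family <- match.arg(family)
  g <- switch(family,
    complete = {
      if (is.null(n) || n < 2) stop("complete: need n >= 2", call. = FALSE)
      igraph::make_full_graph(n)
    },
    cycle = {
      if (is.null(n) || n < 3) stop("cycle: need n >= 3", call. = FALSE)
      igraph::make_ring(n)
    },
    star = {
      if (is.null(n) || n < 2) stop("star: need n >= 2", call. = FALSE)
      igraph::make_star(n, mode = "undirected", center = 1)
    },
    complete_bipartite = {
      if (is.null(m) || is.null(n2) || m < 1 || n2 < 1 || m + n2 < 2)
        stop("complete_bipartite: need part sizes m, n2 >= 1", call. = FALSE)
      igraph::make_full_bipartite_graph(m, n2)
    },
    lattice = {
      if (is.null(w) || is.null(h) || w < 2 || h < 1)
        stop("lattice: need grid sizes w >= 2, h >= 1", call. = FALSE)
      igraph::make_lattice(c(w, h))
    }
  )
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  assert_network(g)
  g
}

#' Deterministic hierarchical modular network
#'
#' Builds the hierarchical network by iterated replication of a small
#' complete seed module.  Starting from a clique on `module_size` nodes
#' whose first node acts as the module centre, each replication step
#' creates `module_size - 1` replicas of the current network, connects
#' every peripheral node of the replicas (the nodes that are not the
#' centre of their own seed clique) to the centre of the original, and
#' joins the replica centres by a cycle among themselves.  The level-`k`
#' network therefore has exactly `module_size^k` nodes; with the default
#' `module_size = 4` the level-4 network has 256 nodes and 879 edges,
#' combining a dominant central hub (degree 192) with dense local
#' clustering — the benchmark used throughout the package.
#'
#' The construction is deterministic: no seed is involved, and repeated
#' calls return identical graphs.
#'
#' @param levels Number of hierarchy levels (>= 1); level 1 is the seed
#'   clique itself.
#' @param module_size Seed clique order (>= 3; default 4).
#' @param wiring_rule Identifier of the replication wiring.  Only
#'   `"peripheral-hub-ring"` (peripheral nodes to the original centre,
#'   replica centres in a cycle) is defined; the id isolates the rule so
#'   that alternative readings can be added without touching callers.
#' @return An igraph network with 0-based integer `name` labels.
#' @examples
#' hr <- make_hierarchical(levels = 4)
#' igraph::vcount(hr)  # 256
#' igraph::ecount(hr)  # 879
#' @export
make_hierarchical <- function(levels, module_size = 4L,
                              wiring_rule = "peripheral-hub-ring") {
  if (!identical(wiring_rule, "peripheral-hub-ring"))
    stop("unknown wiring_rule: ", wiring_rule, call. = FALSE)
  levels <- as.integer(levels)
  q <- as.integer(module_size)
  if (is.na(levels) || levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (is.na(q) || q < 3L) stop("module_size must be >= 3", call. = FALSE)

  # 0-based edge list of the seed clique
  pairs <- utils::combn(q, 2L) - 1L
  edges <- cbind(pairs[1L, ], pairs[2L, ])
  n <- q
  if (levels > 1L) {
    for (lev in 2:levels) {
      s <- n
      new_edges <- list(edges)
      centres <- integer(0)
      for (k in seq_len(q - 1L)) {
        off <- k * s
        new_edges[[length(new_edges) + 1L]] <- edges + off
        peripheral <- off + which(seq_len(s) %% q != 1L) - 1L
        new_edges[[length(new_edges) + 1L]] <-
          cbind(0L, peripheral)
        centres <- c(centres, off)
      }
      nc <- length(centres)
      ring <- cbind(centres, centres[c(2:nc, 1L)])
      if (nc == 2L) ring <- ring[1L, , drop = FALSE]
      new_edges[[length(new_edges) + 1L]] <- ring
      edges <- do.call(rbind, new_edges)
      n <- q * s
    }
  }
  g <- igraph::graph_from_edgelist(edges + 1L, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n) - 1L)
  assert_network(g)
  g
}

#' Spatial toy-worm random network
#'
#' Places nodes on the integer points of a `grid_side` x `grid_side`
#' square and connects each pair independently with probability
#' `f(d) / f(0) = exp(-d^2 / 2)`, where `f` is the standard normal
#' density and `d` the Euclidean distance between the points.  The
#' largest connected component is returned (ties broken by the smallest
#' minimum node id).  With the default 16 x 16 grid the component has
#' 255 nodes on average (sd about 1.3) and mean degree about 4.75,
#' emulating the spatially embedded wiring of a small connectome.
#'
#' @param grid_side Side of the square grid (>= 2; default 16).
#' @param seed Integer RNG seed.
#' @param max_retries Resampling attempts should the component
#'   degenerate to fewer than 3 nodes (never observed at the default
#'   size; guards tiny grids).
#' @return An igraph network; vertex attribute `label` keeps the grid
#'   coordinates of each retained node.
#' @export
make_toy_worm <- function(grid_side = 16L, seed = 1L, max_retries = 100L) {
  grid_side <- as.integer(grid_side)
  if (is.na(grid_side) || grid_side < 2L) stop("grid_side must be >= 2", call. = FALSE)
  pts <- as.matrix(expand.grid(x = seq_len(grid_side) - 1L,
                               y = seq_len(grid_side) - 1L))
  n <- nrow(pts)
  d2 <- as.matrix(stats::dist(pts))^2
  iu <- which(upper.tri(d2))
  p <- exp(-d2[iu] / 2)
  for (attempt in seq_len(max_retries)) {
    set.seed(derive_seed(seed, paste0("toy_worm", attempt)))
    keep <- stats::runif(length(iu)) < p
    row <- ((iu[keep] - 1L) %% n) + 1L
    col <- ((iu[keep] - 1L) %/% n) + 1L
    g <- igraph::graph_from_edgelist(cbind(row, col), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)
    big <- which(comp$csize == max(comp$csize))
    if (length(big) > 1L) {
      # deterministic tie-break: component holding the smallest node id
      first_member <- vapply(big, function(b) min(which(comp$membership == b)), 1L)
      big <- big[which.min(first_member)]
    }
    members <- which(comp$membership == big)
    if (length(members) >= 3L) {
      sub <- igraph::induced_subgraph(g, members)
      igraph::V(sub)$label <- paste0("(", pts[members, 1L], ",", pts[members, 2L], ")")
      igraph::V(sub)$name <- as.character(seq_along(members) - 1L)
      assert_network(sub)
      return(sub)
    }
  }
  stop("toy-worm component degenerate after ", max_retries, " retries", call. = FALSE)
}

#' Preferential attachment (Barabasi-Albert) network
#'
#' Grows a network by preferential attachment: starting from `m0`
#' edgeless nodes, each new node attaches to `m` distinct existing nodes
#' chosen with probability proportional to their degree; while all
#' existing nodes still have degree zero the choice is uniform instead.
#' Duplicate targets within one attachment step are redrawn, so the
#' result is simple; with `m <= m0` it is also connected.  The defaults
#' (`n = 200`, `m = m0 = 10`) give 1900 edges and mean degree exactly 19.
#'
#' @param n Final number of nodes.
#' @param m Edges added per new node.
#' @param m0 Number of initial edgeless nodes (`m <= m0 < n`).
#' @param seed Integer RNG seed.
#' @return An igraph network with 0-based integer `name` labels.
#' @export
make_barabasi_albert <- function(n = 200L, m = 10L, m0 = m, seed = 1L) {
  n <- as.integer(n); m <- as.integer(m); m0 <- as.integer(m0)
  if (anyNA(c(n, m, m0)) || m < 1L) stop("need integer n, m >= 1, m0", call. = FALSE)
  if (m > m0) stop("need m <= m0 (cannot attach ", m, " edges to ", m0,
                   " initial nodes)", call. = FALSE)
  if (m0 >= n) stop("need m0 < n", call. = FALSE)
  for (attempt in seq_len(50L)) {
  set.seed(derive_seed(seed, paste0("barabasi_albert", attempt)))
  from <- integer(m * (n - m0)); to <- integer(m * (n - m0))
  # degree-proportional sampling via the accumulated edge-endpoint list:
  # drawing a uniform element of `ends` is drawing a node with
  # probability proportional to its current degree.  Nodes still at
  # degree zero carry one unit of weight each (the uniform fallback),
  # so isolated initial nodes remain reachable.
  ends <- integer(2L * m * (n - m0)); n_ends <- 0L
  zeros <- seq_len(m0)
  k <- 0L
  for (v in (m0 + 1L):n) {
    targets <- integer(0)
    while (length(targets) < m) {
      i <- sample.int(n_ends + length(zeros), 1L)
      t1 <- if (i <= n_ends) ends[i] else zeros[i - n_ends]
      if (!(t1 %in% targets)) targets <- c(targets, t1)
    }
    idx <- k + seq_len(m)
    from[idx] <- v; to[idx] <- targets
    k <- k + m
    ends[n_ends + seq_len(2L * m)] <- c(rep.int(v, m), targets)
    n_ends <- n_ends + 2L * m
    zeros <- setdiff(zeros, targets)
  }
  if (length(zeros) == 0L) break  # every initial node was reached
  }
  if (length(zeros) > 0L)
    stop("initial nodes remained isolated after 50 attempts; ",
         "increase n or decrease m0", call. = FALSE)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n) - 1L)
  assert_network(g)
  g
}

#' Degree-preserving randomisation by double-edge swaps
#'
#' Runs the Markov-chain "swap" scheme: repeatedly pick two edges
#' (a,b), (c,d) and rewire them to (a,d), (c,b).  A swap is counted only
#' when it actually rewires the graph while keeping it simple ("true"
#' swap).  Connectivity is enforced by a windowed check: after every
#' `window` accepted swaps the graph is tested for connectedness and the
#' whole window is rolled back if it broke the graph apart.  The
#' stationary distribution of the accepted chain is asymptotically
#' uniform over connected simple graphs with the given degree sequence.
#'
#' @param net An igraph network.
#' @param n_swaps Number of true swaps to perform (>= 0).
#' @param seed Integer RNG seed.
#' @param window Accepted swaps between connectivity checks.
#' @param max_tries Attempt budget as a multiple of `n_swaps`; if no
#'   feasible swap exists (e.g. a triangle) the input is returned
#'   unchanged with a warning.
#' @return An igraph network with the same degree sequence.
#' @export
randomize_degree_preserving <- function(net, n_swaps, seed = 1L,
                                        window = 100L, max_tries = 100L) {
  assert_network(net)
  n_swaps <- as.integer(n_swaps)
  if (is.na(n_swaps) || n_swaps < 0L) stop("n_swaps must be >= 0", call. = FALSE)
  if (n_swaps == 0L) return(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  res <- cpp_swap_randomize(el - 1L, igraph::vcount(net), n_swaps,
                            as.integer(window), as.integer(max_tries),
                            derive_seed(seed, "swap"))
  if (res$swaps_done == 0L) {
    warning("no feasible degree-preserving swap; returning input unchanged")
    return(net)
  }
  g <- igraph::graph_from_edgelist(res$edges + 1L, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  assert_network(g)
  g
}

#' Sample an ensemble of networks
#'
#' Draws `n_samples` independent networks, each from its own sub-seed
#' derived from `seed`, so that the whole ensemble is reproducible and
#' individual samples can be regenerated in isolation.  `base` is either
#' a generator function taking a single `seed` argument (e.g.
#' `function(s) make_toy_worm(seed = s)`) or a network to be randomised
#' by `n_swaps` degree-preserving true swaps per sample.
#'
#' @param base Generator `function(seed)` or an igraph network.
#' @param n_samples Number of samples (>= 1).
#' @param seed Master integer seed.
#' @param n_swaps True swaps per sample (randomisation ensembles only).
#' @return List of igraph networks.
#' @export
sample_ensemble <- function(base, n_samples, seed = 1L, n_swaps = NULL) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (igraph::is_igraph(base)) {
    if (is.null(n_swaps)) stop("randomisation ensembles need `n_swaps`", call. = FALSE)
    lapply(seq_len(n_samples), function(i)
      randomize_degree_preserving(base, n_swaps,
                                  seed = derive_seed(seed, paste0("sample", i))))
  } else if (is.function(base)) {
    lapply(seq_len(n_samples), function(i)
      base(derive_seed(seed, paste0("sample", i))))
  } else {
    stop("`base` must be an igraph network or a generator function", call. = FALSE)
  }
}
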
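#' Newman-Girvan modularity of a partition
#'
#' Direct evaluation of
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} - \frac{d_i d_j}{2m}\right)
#'            \delta(c_i, c_j)}
#' for a given node-to-module assignment.
#'
#' @param net An igraph network with `m` edges.
#' @param membership Integer module id per node (any labelling; every
#'   node must be assigned).
#' @return Modularity `Q` in `[-1, 1]`.
#' @export
modularity_q <- function(net, membership) {
  assert_network(net)
  N <- igraph::vcount(net)
  if (length(membership) != N || anyNA(membership))
    stop("membership must assign every node exactly once", call. = FALSE)
  m <- igraph::ecount(net)
  deg <- igraph::degree(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  intra <- membership[el[, 1L]] == membership[el[, 2L]]
  q <- 0
  for (mod in unique(membership)) {
    in_mod <- membership == mod
    e_c <- sum(intra & in_mod[el[, 1L]])
    d_c <- sum(deg[in_mod])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Louvain community detection
#'
#' Seeded run of the Louvain multilevel modularity optimiser.  The
#' returned `Q` is recomputed from the partition with
#' \code{\link{modularity_q}}, so it agrees exactly with the direct
#' formula.
#'
#' @param net An igraph network.
#' @param seed Integer RNG seed (Louvain's node order is randomised).
#' @return List with `membership` (module ids, contiguous from 0),
#'   `n_modules`, `Q`.
#' @export
louvain <- function(net, seed = 1L) {
  assert_network(net)
  set.seed(derive_seed(seed, "louvain"))
  cl <- igraph::cluster_louvain(net)
  memb <- as.integer(factor(igraph::membership(cl))) - 1L
  list(membership = memb,
       n_modules = length(unique(memb)),
       Q = modularity_q(net, memb))
}

#' Infomap minimum description length
#'
#' Seeded run of the Infomap map-equation optimiser (as wrapped by
#' igraph); returns the description length of the partition in bits.
#' Infomap is used off the shelf — only the codelength and partition are
#' exposed, not reimplemented internals.
#'
#' @param net An igraph network.
#' @param seed Integer RNG seed.
#' @param partition Also return the partition? (default `FALSE`).
#' @return Description length in bits, or a list with `I` and
#'   `membership` when `partition = TRUE`.
#' @export
infomap_mdl <- function(net, seed = 1L, partition = FALSE) {
  assert_network(net)
  if (!"cluster_infomap" %in% getNamespaceExports("igraph"))
    stop("Infomap is not available in this igraph build", call. = FALSE)
  set.seed(derive_seed(seed, "infomap"))
  cl <- igraph::cluster_infomap(net)
  I <- igraph::code_len(cl)
  if (!partition) return(I)
  list(I = I, membership = as.integer(factor(igraph::membership(cl))) - 1L)
}
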
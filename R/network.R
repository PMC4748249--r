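#' Validate a network object
#'
#' All public functions in moranet operate on undirected, simple
#' (loop-free, multi-edge-free), connected igraph graphs with at least
#' two vertices.  `assert_network()` checks these invariants and fails
#' with an informative message naming the first violated one.
#'
#' @param net An igraph object.
#' @param min_order Minimal number of vertices accepted (default 2).
#' @return `net`, invisibly, if valid.
#' @export
assert_network <- function(net, min_order = 2L) {
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(net)) stop("network must be undirected", call. = FALSE)
  if (igraph::vcount(net) < min_order)
    stop("network must have at least ", min_order, " nodes", call. = FALSE)
  if (any(igraph::which_loop(net))) stop("network must not contain self-loops", call. = FALSE)
  if (any(igraph::which_multiple(net))) stop("network must not contain multi-edges", call. = FALSE)
  if (!igraph::is_connected(net)) stop("network must be connected", call. = FALSE)
  invisible(net)
}

#' Is a graph a valid moranet network?
#'
#' @param net An igraph object.
#' @return `TRUE` if `net` is an undirected, simple, connected graph of
#'   order at least 2, else `FALSE`.
#' @export
is_network <- function(net) {
  igraph::is_igraph(net) && !igraph::is_directed(net) &&
    igraph::vcount(net) >= 2L && !any(igraph::which_loop(net)) &&
    !any(igraph::which_multiple(net)) && igraph::is_connected(net)
}

#' Read a network from an edge-list or GraphML file
#'
#' Edge lists are whitespace/tab separated files with two integer columns
#' of 0-based node ids (an optional header line is detected and skipped).
#' GraphML files are parsed by igraph.  By default the loader is strict:
#' directed input, self-loops, multi-edges or a disconnected graph are
#' rejected.  With `simplify = TRUE` the graph is symmetrised (each arc
#' becomes an undirected edge), de-duplicated, stripped of self-loops,
#' and restricted to its largest connected component — the preprocessing
#' applied to directed connectome data, where reciprocal arc pairs are
#' replaced by a single undirected edge.
#'
#' @param path File path.
#' @param format `"edgelist"` or `"graphml"`; `NULL` (default) guesses
#'   from the file extension.
#' @param simplify Apply the symmetrise/deduplicate/largest-component
#'   preprocessing instead of rejecting non-conforming input.
#' @return An igraph network.
#' @export
read_network <- function(path, format = NULL, simplify = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  }
  format <- match.arg(format, c("edgelist", "graphml"))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty edge list: ", path, call. = FALSE)
    first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
    skip <- if (suppressWarnings(anyNA(as.integer(first)))) 1L else 0L
    el <- tryCatch(
      utils::read.table(text = lines, skip = skip, colClasses = "integer",
                        col.names = c("from", "to")),
      error = function(e) stop("cannot parse edge list ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    n <- max(el) + 1L
    g <- igraph::graph_from_edgelist(as.matrix(el) + 1L, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  if (simplify) {
    g <- igraph::as_undirected(g, mode = "collapse")
    g <- igraph::simplify(g)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  assert_network(g)
  g
}

#' Write a network to an edge-list or GraphML file
#'
#' The edge-list writer emits two tab-separated columns of 0-based node
#' ids with a `from\tto` header; `read_network()` round-trips both
#' formats losslessly (up to vertex attributes for edge lists).
#'
#' @param net An igraph network.
#' @param path Output file path.
#' @param format `"edgelist"` or `"graphml"`; `NULL` guesses from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = NULL) {
  assert_network(net)
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  }
  format <- match.arg(format, c("edgelist", "graphml"))
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = FALSE) - 1L
    utils::write.table(data.frame(from = el[, 1L], to = el[, 2L]),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Node temperatures
#'
#' The temperature of node *i* is the sum of the reciprocal degrees of
#' its neighbours.  It measures how often the node is replaced
#' under the Moran birth-death process; temperatures sum to the network
#' order exactly, and a network is isothermal when all temperatures
#' equal 1.
#'
#' @param net An igraph network.
#' @return Numeric vector of per-node temperatures.
#' @export
node_temperature <- function(net) {
  assert_network(net)
  deg <- igraph::degree(net)
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  as.numeric(adj %*% (1 / deg))
}

# Seed derivation: every stochastic stage derives its own sub-seed from
# the master seed and a stage label so that stages are independently
# reproducible.  Plain integer hashing, kept below 2^31.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}
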
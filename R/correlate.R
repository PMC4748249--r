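#' Kendall rank correlation from antisymmetric sign scores
#'
#' Direct evaluation of the general rank-correlation form
#' \deqn{\Gamma = \frac{\sum_{i,j} a_{ij} b_{ij}}
#'                     {\sqrt{\sum_{i,j} a_{ij}^2 \sum_{i,j} b_{ij}^2}}}
#' with the sign scores `a_ij = sign(x_i - x_j)`,
#' `b_ij = sign(y_i - y_j)`.  Without ties this is Kendall's tau; with
#' ties the denominator discounts tied pairs, so the coefficient reduces
#' to the standard tau-b.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Kendall's tau in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  a <- sign(outer(x, x, `-`))
  b <- sign(outer(y, y, `-`))
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

#' Pairwise Kendall correlation matrix of a statistics table
#'
#' Each network (deterministic, or the mean of a random ensemble) is one
#' observation; the selected statistic columns are correlated pairwise
#' with \code{\link{kendall_tau}}.
#'
#' @param table Data frame of statistics, one row per network.
#' @param columns Character vector of column names to correlate
#'   (default: all numeric columns).
#' @return A symmetric matrix of class `correlation_matrix` with unit
#'   diagonal.
#' @export
correlation_matrix <- function(table, columns = NULL) {
  if (is.null(columns)) columns <- names(table)[vapply(table, is.numeric, TRUE)]
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("columns not in table: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  sub <- table[, columns, drop = FALSE]
  if (!all(stats::complete.cases(sub)))
    stop("statistics table has missing cells among compared columns", call. = FALSE)
  if (nrow(sub) < 3L) stop("need at least 3 networks (rows)", call. = FALSE)
  k <- length(columns)
  m <- diag(1, k)
  dimnames(m) <- list(columns, columns)
  if (k > 1L) {
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      m[i, j] <- m[j, i] <- kendall_tau(sub[[i]], sub[[j]])
    }
  }
  class(m) <- c("correlation_matrix", "matrix")
  m
}

#' Hierarchical clustering of statistics by correlation profile
#'
#' Agglomerates the statistics (columns of the correlation matrix)
#' using the taxicab (L1) distance between their correlation profiles
#' and a configurable linkage (default average).  The result can be
#' serialised to Newick via \code{\link{dendrogram_newick}}.
#'
#' @param corr A `correlation_matrix` (>= 3 columns).
#' @param linkage Linkage method passed to `hclust` (default
#'   `"average"`).
#' @return An `hclust` object whose leaves are the statistic names.
#' @export
cluster_statistics <- function(corr, linkage = "average") {
  if (nrow(corr) < 3L) stop("need at least 3 statistics", call. = FALSE)
  d <- stats::dist(unclass(corr), method = "manhattan")
  stats::hclust(d, method = linkage)
}

#' Serialise a statistic dendrogram to Newick
#'
#' @param hc An `hclust` object (e.g. from
#'   \code{\link{cluster_statistics}}).
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export", call. = FALSE)
  tree <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
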
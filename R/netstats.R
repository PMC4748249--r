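#' Degree distribution statistics
#'
#' Population moments (denominator `N`, not `N - 1`) of the degree
#' sequence: mean, median, variance, standard deviation, skewness and
#' (non-excess) kurtosis.
#'
#' @param net An igraph network.
#' @return List with `mean`, `median`, `variance`, `sd`, `skewness`,
#'   `kurtosis`.
#' @export
degree_stats <- function(net) {
  assert_network(net)
  d <- igraph::degree(net)
  m <- mean(d)
  v <- mean((d - m)^2)
  list(mean = m,
       median = stats::median(d),
       variance = v,
       sd = sqrt(v),
       skewness = if (v > 0) mean((d - m)^3) / v^1.5 else 0,
       kurtosis = if (v > 0) mean((d - m)^4) / v^2 else NA_real_)
}

#' Temperature statistics
#'
#' Node temperatures (sum of reciprocal neighbour degrees), their
#' population variance (heat heterogeneity, 0 iff the network is
#' isothermal) and the temperature entropy, i.e. the Shannon entropy of
#' the normalised temperature distribution `p_i = T_i / sum(T) = T_i/N`.
#'
#' @param net An igraph network.
#' @param base Logarithm base for the entropy (default natural log;
#'   use 2 for bits).
#' @return List with `temperatures`, `heat_heterogeneity` (variance),
#'   `heat_sd`, `entropy`.
#' @export
temperature_stats <- function(net, base = exp(1)) {
  temp <- node_temperature(net)
  p <- temp / sum(temp)
  v <- mean((temp - mean(temp))^2)
  list(temperatures = temp,
       heat_heterogeneity = v,
       heat_sd = sqrt(v),
       entropy = -sum(p * log(p, base = base)))
}

#' Small-world statistics
#'
#' Average local clustering coefficient (nodes of degree < 2 contribute
#' 0), global transitivity ratio, average shortest-path length over
#' unordered node pairs, diameter, and the small-worldness ratio `C/L`.
#'
#' @param net An igraph network.
#' @return List with `clustering`, `transitivity`, `path_length`,
#'   `diameter`, `c_over_l`.
#' @export
smallworld_stats <- function(net) {
  assert_network(net)
  loc <- igraph::transitivity(net, type = "local", isolates = "zero")
  C <- mean(loc)
  L <- igraph::mean_distance(net)
  list(clustering = C,
       transitivity = igraph::transitivity(net, type = "global"),
       path_length = L,
       diameter = igraph::diameter(net),
       c_over_l = C / L)
}

#' Power-law exponent of the degree-distribution tail
#'
#' Maximum-likelihood fit of a discrete power law to the degree tail,
#' with the lower cut-off `x_min` chosen by the Kolmogorov-Smirnov
#' criterion (Clauset-Shalizi-Newman, as implemented by igraph).
#'
#' @param net An igraph network (>= 50 nodes recommended).
#' @return List with `exponent`, `x_min`, `ks_stat`, `ks_p`.
#' @export
powerlaw_exponent <- function(net) {
  assert_network(net)
  d <- igraph::degree(net)
  if (length(unique(d)) < 2L)
    stop("degenerate (constant) degree sequence: no tail to fit", call. = FALSE)
  fit <- igraph::fit_power_law(d, implementation = "plfit")
  list(exponent = fit$alpha, x_min = fit$xmin,
       ks_stat = fit$KS.stat, ks_p = fit$KS.p)
}

#' One network's statistics row
#'
#' Assembles the selected statistic groups into a single-row data frame
#' — the unit of the benchmark comparison tables.  The `H_d` column
#' follows the benchmark tables' convention of printing the degree
#' standard deviation, while `H_t` holds the temperature variance;
#' `degree_variance` carries the plain variance as well.
#'
#' @param net An igraph network.
#' @param components Character vector among `"degree"`, `"temperature"`,
#'   `"smallworld"`, `"powerlaw"`, `"community"`, `"complexity"`.
#' @param seed Seed for the stochastic components (community detection,
#'   box covering).
#' @param name Row label.
#' @return One-row data frame.
#' @export
stats_record <- function(net,
                         components = c("degree", "temperature", "smallworld"),
                         seed = 1L, name = "network") {
  assert_network(net)
  components <- match.arg(components,
                          c("degree", "temperature", "smallworld",
                            "powerlaw", "community", "complexity"),
                          several.ok = TRUE)
  rec <- data.frame(name = name,
                    N = igraph::vcount(net),
                    E = igraph::ecount(net))
  if ("degree" %in% components) {
    ds <- degree_stats(net)
    rec$delta <- ds$mean; rec$q2 <- ds$median
    rec$H_d <- ds$sd; rec$degree_variance <- ds$variance
    rec$skewness <- ds$skewness; rec$kurtosis <- ds$kurtosis
  }
  if ("temperature" %in% components) {
    ts <- temperature_stats(net)
    rec$H_t <- ts$heat_heterogeneity; rec$I_t <- ts$entropy
  }
  if ("smallworld" %in% components) {
    sw <- smallworld_stats(net)
    rec$C <- sw$clustering; rec$transitivity <- sw$transitivity
    rec$L <- sw$path_length; rec$diameter <- sw$diameter
    rec$C_L <- sw$c_over_l
  }
  if ("powerlaw" %in% components) {
    pl <- tryCatch(powerlaw_exponent(net), error = function(e) NULL)
    rec$pl_exponent <- if (is.null(pl)) NA_real_ else pl$exponent
  }
  if ("community" %in% components) {
    lv <- louvain(net, seed = derive_seed(seed, "louvain"))
    rec$Q <- lv$Q
    rec$I <- tryCatch(infomap_mdl(net, seed = derive_seed(seed, "infomap")),
                      error = function(e) NA_real_)
  }
  if ("complexity" %in% components) {
    curve <- box_counting_curve(net, seed = derive_seed(seed, "boxes"))
    fit <- fractal_dimension(curve)
    rec$D <- fit$exponent; rec$D_stderr <- fit$std_err; rec$D_R2 <- fit$r_squared
    rent <- tryCatch(rent_fit(net, curve), error = function(e) NULL)
    rec$rent_p <- if (is.null(rent)) NA_real_ else rent$exponent
  }
  rec
}

#' Ensemble statistics: mean and spread over samples
#'
#' Computes `stats_record` for every network in a list and reports the
#' per-column mean and standard deviation (sample sd across networks),
#' the format of ensemble rows in the benchmark comparison tables.
#'
#' @param nets List of igraph networks.
#' @param ... Passed to `stats_record`.
#' @param name Row label.
#' @return List with `mean` and `sd` one-row data frames and the full
#'   `records` table.
#' @export
ensemble_stats <- function(nets, ..., name = "ensemble") {
  recs <- do.call(rbind, lapply(seq_along(nets), function(i)
    stats_record(nets[[i]], ..., name = paste0(name, "_", i))))
  num <- vapply(recs, is.numeric, TRUE)
  mu <- recs[1, , drop = FALSE]; sd_ <- recs[1, , drop = FALSE]
  mu$name <- name; sd_$name <- paste0(name, "_sd")
  for (cn in names(recs)[num]) {
    mu[[cn]] <- mean(recs[[cn]])
    sd_[[cn]] <- stats::sd(recs[[cn]])
  }
  list(mean = mu, sd = sd_, records = recs)
}
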
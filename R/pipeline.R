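#' Study configuration
#'
#' Bundles everything `run_study()` needs: the networks to analyse, the
#' fitness grid, Monte Carlo effort, ensemble sizes, the statistic
#' selection, a master seed (every stochastic stage derives its own
#' sub-seed from it) and an output directory.
#'
#' @param networks Named list.  Each element is one of: an igraph
#'   network (deterministic entry); a generator `function(seed)`
#'   (random-family entry, sampled `ensemble_size` times); or
#'   `list(base = "<name of an earlier entry>", randomize = TRUE)`
#'   (degree-preserving randomisation ensemble of that entry).
#' @param r_grid Fitness grid (default \code{\link{default_r_grid}}).
#' @param trials Trials per grid point for deterministic entries.
#' @param ensemble_size Samples per random/randomised entry.
#' @param ensemble_trials Trials per grid point per ensemble sample.
#' @param n_swaps True swaps per randomisation sample.
#' @param components Statistic groups for \code{\link{stats_record}}.
#' @param seed Master integer seed.
#' @param outdir Output directory (`NULL` = no files written).
#' @return A `study_config` list.
#' @export
study_config <- function(networks,
                         r_grid = default_r_grid(),
                         trials = 10000L,
                         ensemble_size = 10L,
                         ensemble_trials = 1000L,
                         n_swaps = 10000L,
                         components = c("degree", "temperature", "smallworld"),
                         seed = 1L,
                         outdir = NULL) {
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    stop("`networks` must be a fully named list", call. = FALSE)
  structure(list(networks = networks, r_grid = r_grid, trials = trials,
                 ensemble_size = ensemble_size,
                 ensemble_trials = ensemble_trials,
                 n_swaps = n_swaps, components = components,
                 seed = seed, outdir = outdir),
            class = "study_config")
}

#' Run a robustness-against-invasion study
#'
#' For every configured network (or ensemble) estimates the fixation
#' function on the fitness grid, computes the robustness index and the
#' selected statistics, and assembles a comparison table; with at least
#' three networks the pairwise Kendall correlation matrix of the
#' statistics is added.  Per-network failures are isolated: the run
#' continues and the failure is recorded in the result.  With an
#' `outdir`, per-network fixation CSVs (`fixation_<name>.csv`), the
#' statistics table (`stats_table.csv`) and the correlation matrix
#' (`kendall_tau.csv`) are written; identical config and seed give
#' byte-identical files.
#'
#' @param config A `study_config`.
#' @return List with `table` (one row per network: robustness, fixation
#'   at the grid ends and at r = 1 and 1.5 when on the grid, statistics),
#'   `fixation` (per-network fixation functions), `tau`
#'   (correlation matrix or `NULL`), `errors` (named list).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  rows <- list(); fixfuns <- list(); errors <- list()
  built <- list()
  for (nm in names(config$networks)) {
    spec <- config$networks[[nm]]
    res <- tryCatch(
      run_study_entry(nm, spec, config, built),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      message("study entry '", nm, "' failed: ", conditionMessage(res))
      next
    }
    built[[nm]] <- res$net
    rows[[nm]] <- res$row
    fixfuns[[nm]] <- res$fixfun
    message(sprintf("study entry '%s': N = %g, rho = %.4f",
                    nm, res$row$N, res$row$rho))
  }
  table <- do.call(rbind, rows)
  tau <- NULL
  if (!is.null(table) && nrow(table) >= 3L) {
    num <- names(table)[vapply(table, is.numeric, TRUE)]
    keep <- num[vapply(table[num], function(col) !anyNA(col), TRUE)]
    tau <- correlation_matrix(table, keep)
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(fixfuns)) {
      utils::write.csv(fixfuns[[nm]]$estimates,
                       file.path(config$outdir, paste0("fixation_", nm, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(table))
      utils::write.csv(table, file.path(config$outdir, "stats_table.csv"),
                       row.names = FALSE)
    if (!is.null(tau))
      utils::write.csv(as.data.frame(unclass(tau)),
                       file.path(config$outdir, "kendall_tau.csv"))
  }
  list(table = table, fixation = fixfuns, tau = tau, errors = errors)
}

# one study entry: deterministic network, generator ensemble, or
# randomisation ensemble of an earlier entry
run_study_entry <- function(nm, spec, config, built) {
  seed <- derive_seed(config$seed, nm)
  if (igraph::is_igraph(spec)) {
    net <- spec
    ff <- fixation_function(net, config$r_grid, config$trials, seed = seed)
    rob <- robustness_index(ff)
    row <- cbind(stats_record(net, config$components, seed = seed, name = nm),
                 summarise_fixation(ff, rob))
    return(list(net = net, fixfun = ff, row = row))
  }
  if (is.function(spec) ||
      (is.list(spec) && isTRUE(spec$randomize))) {
    if (is.function(spec)) {
      nets <- sample_ensemble(spec, config$ensemble_size, seed = seed)
    } else {
      base <- built[[spec$base]]
      if (is.null(base)) stop("randomisation base '", spec$base,
                              "' not built yet", call. = FALSE)
      nets <- sample_ensemble(base, config$ensemble_size, seed = seed,
                              n_swaps = config$n_swaps)
    }
    ffs <- lapply(seq_along(nets), function(i)
      fixation_function(nets[[i]], config$r_grid, config$ensemble_trials,
                        seed = derive_seed(seed, paste0("fix", i))))
    phi <- rowMeans(vapply(ffs, function(f) f$estimates$phi,
                           numeric(length(config$r_grid))))
    mean_ff <- ffs[[1L]]
    mean_ff$estimates$phi <- phi
    mean_ff$estimates$stderr <- mean_ff$estimates$stderr /
      sqrt(length(nets))
    rob <- robustness_index(mean_ff)
    es <- ensemble_stats(nets, config$components, seed = seed, name = nm)
    row <- cbind(es$mean, summarise_fixation(mean_ff, rob))
    row$name <- nm
    return(list(net = nets[[1L]], fixfun = mean_ff, row = row))
  }
  stop("unrecognised network spec for '", nm, "'", call. = FALSE)
}

summarise_fixation <- function(ff, rob) {
  df <- ff$estimates
  grab <- function(rv) {
    i <- which(abs(df$r - rv) < 1e-9)
    if (length(i)) df$phi[i] else NA_real_
  }
  data.frame(rho = rob$rho, sup_num = rob$sup_num, sup_den = rob$sup_den,
             phi_1 = grab(1), phi_1.5 = grab(1.5))
}
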
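#!/usr/bin/env Rscript
# Rank correlations between robustness, fixation and topology across
# the benchmark networks, and the statistic dendrogram (taxicab
# distance between Kendall-correlation profiles, average linkage).
#
# Runs a compact end-to-end study over generator-built networks only;
# each network (or ensemble) is one observation.

library(moranet)
seed <- 20260905L
outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

hr <- make_hierarchical(4)
cfg <- study_config(
  networks = list(
    HR = hr,
    HR_random = list(base = "HR", randomize = TRUE),
    BA = function(s) make_barabasi_albert(seed = s),
    TW = function(s) make_toy_worm(seed = s),
    cycle50 = make_classic("cycle", n = 50),
    bipartite = make_classic("complete_bipartite", m = 20, n2 = 20)
  ),
  r_grid = default_r_grid(), trials = 10000L,
  ensemble_size = 5L, ensemble_trials = 2000L, n_swaps = 10000L,
  components = c("degree", "temperature", "smallworld"),
  seed = seed, outdir = outdir)

res <- run_study(cfg)
print(res$table[, c("name", "N", "delta", "H_d", "H_t", "C", "L", "rho", "phi_1.5")])

cols <- c("rho", "phi_1.5", "delta", "q2", "H_d", "H_t", "C", "L", "C_L", "I_t")
cols <- intersect(cols, names(res$table))
tau <- correlation_matrix(res$table, cols)
print(round(unclass(tau), 2))
write.csv(as.data.frame(unclass(tau)), file.path(outdir, "kendall_matrix.csv"))

hc <- cluster_statistics(tau)
nwk <- dendrogram_newick(hc, file.path(outdir, "statistic_dendrogram.nwk"))
message("dendrogram: ", nwk)
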
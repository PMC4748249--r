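# moranet — Moran invasion processes and robustness against invasion on networks

How well does a network's wiring resist takeover by a fitter invader?
`moranet` implements the Moran birth–death invasion process on
undirected networks and a *robustness-against-invasion* index that
summarises where a network's fixation probability function lies between
two analytic extremes. It is aimed at researchers in evolutionary graph
theory and network biology who want to relate invasion dynamics to
topology (degree structure, temperature heterogeneity, modularity,
fractal and wiring complexity) on reproducible, generator-built
benchmarks.

## The model and the index

A single invader ("diseased" node) with fitness $r$ appears at a
uniformly chosen node of an undirected, simple, connected network of
order $N$; at each step an individual reproduces with probability
proportional to its fitness ($r$ for invaders, 1 for residents) and
replaces a uniformly chosen neighbour. The *fixation probability*
$\Phi(r)$ is the chance the invader eventually occupies the whole
network. Two reference topologies bracket typical behaviour:

* isothermal networks (all node temperatures $T_i = \sum_{j\sim i} 1/d_j$
  equal) follow the classical Moran form
  $\rho_1(r) = (1 - 1/r)/(1 - r^{-N})$;
* large complete bipartite networks amplify selection towards
  $\rho_2(r) = (1 - r^{-2})/(1 - r^{-2N})$, the Moran form at the
  squared fitness.

The robustness against invasion is

$$\rho \;=\; 1 - \frac{\sup_r |\Phi(r) - \rho_1(r)|}{\sup_r |\rho_2(r) - \rho_1(r)|},$$

with suprema over a discrete fitness grid: $\rho = 1$ for
isothermal-like networks, $\rho = 0$ for amplifier-like ones.

$\Phi(r)$ is estimated either exactly (sparse solve of the $2^N$
absorbing-chain system, $N \le 14$) or by a fast embedded-Markov-chain
Monte Carlo simulator (C++), which skips replacement events that do not
change the state.

The package also ships reproducible benchmark generators — a
deterministic hierarchical modular network, a spatial "toy worm" random
graph, preferential attachment, classic graphs, and degree-preserving
randomisation ensembles — plus estimators for degree/temperature
statistics, small-world measures, power-law tails, Louvain modularity
and Infomap description length, box-counting fractal dimension, Rent's
rule exponents, and Kendall rank correlations with a statistic
dendrogram. See `vignettes/robustness-methods.Rmd` for the methods and
design choices.

## Worked example

```r
library(moranet)

hr <- make_hierarchical(4)        # 256 nodes, 879 edges
degree_stats(hr)$mean             # 6.8672  (mean degree)
temperature_stats(hr)$heat_heterogeneity  # 6.123 (temperature variance)
smallworld_stats(hr)$clustering   # 0.5926

f <- simulate_fixation(hr, r = 1.5, trials = 20000, seed = 5)
f
#> Fixation estimate (mc): r = 1.5, p = 0.34700 (se 0.00337, 20000 trials)

ff <- fixation_function(hr, default_r_grid(), trials = 10000, seed = 11)
robustness_index(ff)
#> Robustness against invasion: rho = 0.9424 (sup|Phi-rho1| = 0.0144, sup|rho2-rho1| = 0.25, N = 256)
```

The fixation fraction 0.347 means an invader with a 50% reproductive
advantage takes over this 256-node network in about a third of
invasions — above the isothermal baseline $\rho_1(1.5) = 1/3$, so the
topology mildly amplifies selection, and the robustness index near
0.94 places the network close to the isothermal extreme (the
high-precision value under this protocol is 0.944; the supremum over
a noisy grid biases low-trial estimates slightly downward).

## Analysis workflow

`analysis/01_build_networks.R` … `05_correlations.R` run the full
analysis pipeline at reduced scale: build the benchmarks and their
statistics tables, estimate fixation functions and robustness for the
hierarchical network, an isothermal control and a randomised ensemble,
run community detection, compute fractal dimensions and Rent
exponents, and assemble the Kendall correlation matrix and statistic
dendrogram. Each script prints what it finds and writes CSV/Newick
outputs under `results/`.

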
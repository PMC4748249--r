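---
title: "Robustness against invasion: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness against invasion: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
invasion model, the robustness index built on it, the benchmark
generators, the estimators for network statistics and complexity, and
the numerical choices that were genuinely open.

## The Moran invasion process

A population lives on an undirected, simple, connected network with one
individual per node. All residents are healthy; a single node turns
"diseased" (mutant, invader) with relative fitness $r > 0$. At every
step one individual is chosen to reproduce with probability
proportional to its fitness ($r$ for mutants, $1$ for residents), and
its offspring replaces a uniformly chosen network neighbour
(birth–death updating). The chain has two absorbing states — extinction
of the invader, or *fixation*, where the whole network is diseased.
The *fixation probability* $\Phi(r)$ is the probability of fixation
averaged over a uniformly placed initial mutant; at neutrality
($r = 1$) exchangeability forces $\Phi(1) = 1/N$ exactly, a law the
test suite uses as an anchor.

Three computational routes are provided:

* `exact_fixation()` solves the absorbing-chain linear system over all
  $2^N$ mutant subsets (sparse LU; capped at $N \le 14$ because of the
  exponential state space).
* `simulate_fixation()` runs the *embedded Markov chain* (EMC) Monte
  Carlo: replacement events that do not change the state are excluded
  and the remaining events renormalised, so trajectories only spend
  time on state changes. The simulator (C++) keeps per-node event
  weights in a flat array with per-block partial sums, giving $O(1)$
  weight updates and $O(\sqrt N)$ sampling per step.
* `rho1_complete()` and `rho2_bipartite_limit()` are the closed forms
  for the two reference topologies (below). Both handle the removable
  singularity at $r = 1$ with an explicit limit branch rather than
  floating-point division.

## Temperature, isothermal networks and amplifiers

The *temperature* of a node, $T_i = \sum_{j \sim i} 1/d_j$, measures
how often it is replaced; temperatures sum to $N$ on every undirected
network (an exact identity, tested at $10^{-10}$). Networks whose nodes
all have temperature 1 — complete graphs, cycles, toroidal lattices —
are *isothermal*, and by the Circulation Theorem their fixation
function collapses to the classical Moran form

$$\rho_1(r) = \frac{1 - 1/r}{1 - r^{-N}}.$$

At the other extreme, large complete bipartite networks *amplify*
selection: their fixation probability converges to the Moran form
evaluated at $r^2$,

$$\rho_2(r) = \frac{1 - r^{-2}}{1 - r^{-2N}},$$

which exceeds $\rho_1$ for every $r > 1$. The *robustness against
invasion* locates a network between these extremes:

$$\rho = 1 - \frac{\sup_r\,\lvert \Phi(r) - \rho_1(r)\rvert}
                  {\sup_r\,\lvert \rho_2(r) - \rho_1(r)\rvert},$$

with both suprema taken over a discrete fitness grid (never by
continuous optimisation). Isothermal networks give $\rho = 1$ up to
Monte Carlo noise; a network following the amplifier limit gives
$\rho = 0$. The value is reported unclamped so that suppressors or
sampling noise remain visible.

**Fitness grid.** The default grid is $r = 0.25, 0.5, \dots, 2$
(step 0.25, `default_r_grid()`). The denominator's supremum
$\lvert\rho_2 - \rho_1\rvert$ peaks at $r = 2$ (value $1/r - 1/r^2 =
0.25$ for large $N$), so the grid spans the whole informative range;
below $r \approx 1$ both references are numerically zero for the
network orders studied here. The endpoints and step are configuration
defaults and can be overridden in every estimator. Because the
numerator is a supremum of noisy estimates, it carries a positive bias
of order the per-point standard error; at $10^4$ trials per grid point
this depresses $\rho$ by roughly $0.005$–$0.01$ for a 256-node network.
The package reports the estimate as defined rather than attempting a
bias correction.

## Benchmark generators and what they emulate

`make_hierarchical(levels, module_size = 4)` builds the deterministic
hierarchical modular network by iterated replication of a complete seed
module: at each step three replicas of the current network are created,
every peripheral node of the replicas (nodes that are not the centre of
their own seed clique) is wired to the centre of the original, and the
three replica centres are joined in a triangle. Level 4 gives 256
nodes, 879 edges, mean degree 6.87, a dominant hub of degree 192,
average clustering 0.59 and mean path length 2.41 — a topologically
complex but highly robust small world. The construction is
deterministic; the wiring is isolated behind the
`"peripheral-hub-ring"` rule identifier so alternative readings can
coexist.

`make_toy_worm(grid_side = 16)` emulates a spatially embedded nervous
system: nodes sit on the integer grid and each pair is connected
independently with probability $f(d)/f(0) = e^{-d^2/2}$, the standard
normal density at the pair's Euclidean distance rescaled to 1 at
distance 0. The largest component (ties broken towards the smallest
node id) has on average 255 of the 256 possible nodes (sd about 1.3)
and mean degree about 4.75. It reproduces the *statistics* of a small
spatial connectome — short-range wiring, moderate clustering, planar
fractal dimension near 2 — but none of its biology: no neuron types,
no directionality, no synaptic weights.

`make_barabasi_albert(n = 200, m = 10, m0 = 10)` grows a preferential
attachment network from `m0` edgeless nodes; while all degrees are
zero the attachment is uniform, duplicate targets are redrawn, so the
result is simple and connected with exactly $m(n - m_0) = 1900$ edges
and mean degree 19.

`randomize_degree_preserving()` runs the double-edge-swap Markov chain:
only *true* swaps count (the proposal must actually rewire and keep the
graph simple), and connectivity is enforced by checking every
`window = 100` accepted swaps and rolling back the window on failure —
the windowed variant of the standard scheme, asymptotically uniform
over connected simple graphs with the given degree sequence.
`sample_ensemble()` derives an independent sub-seed per sample so any
sample can be regenerated in isolation; ensembles are therefore
independent of evaluation order.

Passing tests on these generators shows the package reproduces the
*benchmark families'* statistics, not that any real power grid or
connectome would behave identically; loaders for user-supplied edge
lists and GraphML files (with an optional symmetrise/simplify
preprocessing) are provided for real data.

## Network statistics

Degree and temperature moments are population moments (denominator
$N$); skewness and kurtosis are the standardised third and fourth
central moments (kurtosis non-excess). One printing convention of the
benchmark tables is worth flagging: their degree-heterogeneity column
holds the degree *standard deviation* while the heat-heterogeneity
column holds the temperature *variance*. `stats_record()` follows that
convention for its `H_d` and `H_t` columns (both the variance and the
sd of the degree sequence are included) so that rows are directly
comparable with the benchmark tables. The temperature entropy is the
Shannon entropy of $p_i = T_i/N$, natural log by default with a `base`
argument (set `base = 2` before comparing bit-valued entropies).
Average path length averages over unordered pairs; the clustering
coefficient is the mean local neighbourhood density with degree-<2
nodes contributing 0. Power-law tails are fitted by discrete maximum
likelihood with KS-optimal lower cut-off (igraph's `plfit`).

Modularity $Q$ is evaluated directly from the Newman–Girvan sum;
`louvain()` returns a partition whose $Q$ is *recomputed* through that
formula, so optimiser and evaluator cannot drift apart. The Infomap
minimum description length is taken from igraph's wrapped Infomap and
reported in bits; it is treated as an off-the-shelf component, and its
absolute values depend on the Infomap build — comparisons should be
within one build only.

## Box counting, fractal dimension, Rent's rule

`box_cover_greedy()` implements the greedy-colouring box covering: the
auxiliary graph joins every pair at graph distance $\ge \ell_B$, and a
seeded random-order greedy colouring of it yields boxes of internal
diameter $< \ell_B$. One seeded covering is produced per network and
box size (per-$\ell_B$ seeds derived from the master seed); repetition
to minimise box counts is deliberately not done: one covering per
network keeps ensemble runs affordable, and the box-count spread
across seeds is small. Since a partition valid at $\ell_B$ is valid at
$\ell_B + 1$, the curve builder reuses the previous covering whenever a
fresh colouring would use more boxes, making $N_B(\ell_B)$ monotone by
construction.

The fractal dimension is the negative slope of
$\log N_B$ versus $\log \ell_B$. The default fit drops the trivial
$\ell_B = 1$ point (its box count is the network order and carries no
box structure) and uses all remaining sizes — the convention that
reproduces the benchmark table values on the hierarchical network
(D = 4.1, slope standard error 1.4, $R^2 = 0.81$ on the level-4
network). For large-diameter networks whose curve flattens near the
diameter, `scaling_region()` restricts the fit to the maximal linear
prefix (longest prefix whose $R^2$ is within 0.005 of the best
achievable — the slack keeps three-point prefixes from winning on
noise). Region detection is a heuristic stand-in for a more elaborate
changepoint rule and is documented as such.

A known limitation, verified against an independent implementation of
the same algorithm: on finite regular lattices the random-order greedy
colouring is increasingly suboptimal at larger box sizes, and the
fitted dimension of a 32×32 grid comes out near 1.6 rather than the
Euclidean 2. The lattice bias is a property of the greedy-colouring
estimator itself, not of this implementation.

Rent's rule is read off the same box decompositions: every box
contributes a point (box size $g$, boundary-edge count $T$), and the
exponent $p$ of $T = t\,g^p$ is the OLS slope of $\log T$ on $\log g$.
Singleton boxes ($T$ is then just the node degree) and the whole-network
box are excluded; the fitted range is restricted by the same prefix
heuristic applied to the per-$g$ mean profile. Low $p$ indicates
cost-efficient wiring; degree-preserving randomisation raises both the
fractal dimension and the Rent exponent of the hierarchical benchmark,
which the test suite checks as an ordering, not as absolute values.

## Rank correlations and the statistic dendrogram

`kendall_tau()` evaluates the antisymmetric sign-score form
$\Gamma = \sum_{ij} a_{ij} b_{ij} / \sqrt{\sum a_{ij}^2 \sum b_{ij}^2}$
with $a_{ij} = \mathrm{sign}(x_i - x_j)$; with ties this reduces to the
standard tau-b (tied pairs drop out of both numerator and denominator),
and without ties to the plain Kendall tau. Each network — deterministic,
or the mean of an ensemble — is one observation. Significance is a
descriptive comparison against the critical value for the row count; no
multiple-testing correction is applied: with ten observations per
column, descriptive comparison is all the data supports.
Statistics are clustered by the taxicab (L1) distance between their
correlation profiles with average linkage by default (the linkage of
the original figure is unstated; it is a configuration knob), and the
dendrogram serialises to Newick via ape.

## Numerical and protocol choices

* **Seeds.** Every stochastic stage derives a 31-bit sub-seed from the
  master seed and a stage label, so ensembles, grid points and
  coverings are independently reproducible and results do not depend on
  evaluation order.
* **Exact solver cap.** $N \le 14$ by default (the system has $2^N$
  unknowns); the cap is named in the error message.
* **EMC budgets.** A full-scale protocol (ensembles of $10^3$
  networks, $10^5$–$10^6$ trials per fitness value) is cluster-scale.
  The package defaults target a workstation: $10^4$ trials per grid
  point for deterministic networks, $10^3$–$5\times10^3$ per ensemble
  sample, 16-point grids, 20-sample randomisation ensembles. At these
  sizes a full hierarchical-benchmark sweep takes a few minutes; all
  statistics in the analysis scripts state the sizes they used.
* **Degenerate inputs.** Absorbing states are rejected by
  `transition_distribution()`; a single-point grid at $r = 1$ makes the
  robustness denominator vanish and raises an explicit error; graphs
  with no feasible swap return unchanged with a warning; constant
  degree sequences raise an error in the power-law fit.
* **Toy-worm retries.** If the largest component degenerates below 3
  nodes the generator resamples, at most 100 times (relevant only for
  tiny grids).

## What the tests do and do not show

The suite validates the simulator against the exact solver on an
enumerable fixture battery, the closed forms against each other and
against independent dense solves, the generators against the benchmark
statistics they are built to reproduce, and each estimator against hand-computed or
brute-force oracles. Green tests mean the implementations agree with
the models and the benchmark tables at the stated tolerances on
generator-built networks; they do not certify behaviour on real
networks, which differ from the benchmarks in ways the generators do
not emulate (directedness, weights, degree-degree correlations,
geography).
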
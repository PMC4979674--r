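---
title: "Modelling chaperone deletion mutants: SILAC statistics, network topology and folding workload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chaperone deletion mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaperflux)
```

## The problem

Budding yeast tolerates the deletion of individual HSP70 chaperones
remarkably well, even though single HSP70s such as SSA1 or SSB1 interact
with thousands of substrate proteins. `chaperflux` models this robustness
quantitatively from three coupled angles:

1. **SILAC quantification.** Heavy-labelled wild-type cells are mixed 1:1
   (by cell count) with a light mutant strain; protein-level heavy/light
   MS1 intensities across biological replicates yield per-protein
   log2(L/H) ratios. Deletion mutants grow larger, so the whole ratio
   distribution shifts up — a global cell-size effect that must be
   estimated (median fold change) and removed (normalization) before
   individual differential proteins can be called.
2. **Network topology.** The chaperome is an undirected, unweighted graph
   of chaperones and substrates. An in silico deletion removes one
   chaperone node and its edges; substrates whose only link was to that
   node stay in the network as degree-zero *orphans*. Degree, neighborhood
   connectivity, clustering coefficient and betweenness centrality
   quantify how much the deletion perturbs the remaining network.
3. **Folding workload.** At steady state a protein's synthesis flux is
   `k_syn = cpc × k_deg` (copies/cell/min). Each substrate's flux is
   divided equally pro rata among its chaperones; a chaperone's workload
   `F_c` is the sum of its shares. Deleting a chaperone redistributes each
   of its shares equally among the substrate's remaining chaperones, so
   the extra load on the survivors — and the flux orphaned with
   unprotected substrates — can be computed exactly.

Because the measured chaperome and the study's raw MS data are not
redistributable, the package ships a synthetic-data generator that
reproduces the statistical structure all three stages assume; every claim
the package makes is validated against that generator plus closed-form and
brute-force oracles.

## The synthetic-data generator

`sim_config()` fixes the study conditions. The network generator attaches
each substrate to `1 + Poisson(multiplicity − 1)` chaperones drawn with
probability proportional to `(degree + 1)^hub_exponent` — preferential
attachment on a bipartite backbone, plus independent chaperone–chaperone
edges. Defaults (63 chaperones, 2000 substrates, multiplicity 5, hub
exponent 1, chaperone edge probability 0.05) are a scaled-down analogue of
a measured yeast chaperome (4403 nodes, 21946 edges, ~60 chaperones with
strongly hub-dominated degrees): the simulated top hub carries about 5% of
all edges, comparable to the real network's biggest hub. The scale-down
keeps the whole test suite and the acceptance script inside a couple of
minutes while preserving the hub-dominated shape that drives orphan
creation and betweenness shifts.

SILAC intensities follow a deliberately minimal model: on the log2 scale,
heavy is `log2(a_i) + ε` and light is
`log2(a_i) + log2(g) + δ_i + ε`, with `a_i` log-normal abundance
(`meanlog log(5000)`, `sdlog 1.5` — a realistic span of copies per cell),
`g` the global light:heavy mixing factor, `δ_i ~ N(0, 1)` for the spiked
differential subset (two-sided: real mutants show both up- and
down-regulation) and `ε ~ N(0, 0.3)` independent per cell. Replicate noise
of 0.3 log2 units per channel and 10% missing-completely-at-random dropout
were chosen once as plausible for protein-level SILAC quadruplicates (no
published value was available); note that with four replicates this fixes
the detectable effect size at roughly 1.5–1.75 log2 units for 80% power
after FDR control (see *Limitations*). Degradation rates are log-normal
around 0.01/min (≈70 min half-life), with 30% flagged missing to exercise
imputation.

What the generator does **not** emulate: peptide-level aggregation,
intensity-dependent (MNAR) dropout, isotope impurity, correlated
replicates, or any fidelity to the measured chaperome beyond its
hub-dominated shape. Passing tests therefore demonstrate the statistical
machinery is correct under its own assumptions, not that those assumptions
exhaust real data.

All generators derive their RNG state deterministically from
`config$seed`, so identical configurations are byte-identical across runs.

## Quantification choices

**Ratios and filtering.** log2(L/H) is defined only where both channels
carry signal; MaxQuant-style zero intensities are treated as missing, not
−∞. A protein is kept when at least `min_reps` replicates (default 3, of
4) show signal in either channel — the "3 of 4" selection rule; for
technical triplicates the analogous 2-of-3 setting is used.

**Normalization.** Each channel's log2 intensities are regressed by
ordinary least squares (slope *and* intercept; `method = "center"`
restricts to intercept-only) against the across-replicate mean over
commonly observed proteins, and mapped onto that reference. Because moving
the columns moves the reference mean, a single pass is not an exact fixed
point; the pass is iterated to convergence (tolerance 1e-12, typically
< 10 iterations), which makes the operation idempotent to machine
precision — a property the test suite asserts at 1e-9. On noise-free
symmetric input the post-normalization median log2(L/H) is 0 to 1e-6.

**Testing.** Differential abundance per protein is a one-way, two-group
ANOVA of normalized log2 heavy vs light intensities with replicates as
observations (equivalent to a pooled-variance t-test) — the simplest
design for one knockout against one reference; it is vectorized across
proteins and cross-checked against `stats::aov`. Proteins with fewer than
two observations per channel, or zero within-group variance, are flagged
untestable rather than given a p-value. Benjamini–Hochberg control uses
`stats::p.adjust`. Both raw-p and adjusted-p significance counts are
reported, since both are informative at different stringency.

**Diagnostics.** `median_fold_change()` estimates the global shift (it
recovers log2 of a known mixing factor to ±0.05 at n = 1000 under the
default noise); `ma_loess()` (span 0.3, locally linear — the span is a
diagnostic default, nothing downstream depends on it) draws the MA-plot
trend; `cell_volume()` implements the oblate-spheroid rule
`V = 4/3 π r1 r2²` used to relate shift to cell size;
`incorporation_efficiency()` computes RIA = H/(H+L)×100 for label checks.

## Topology choices

Graphs are simple and undirected; duplicate edges collapse and self-loops
are dropped with a warning. Deletion mutants retain orphans — this matters
because orphan counts are themselves a result, and because dropping them
would silently change attribute distributions.

Betweenness follows the component-normalized definition: endpoints
excluded, unordered pairs counted once, equal shortest paths counted
fractionally, normalized by `(N−1)(N−2)/2` with `N` the node's own
component size; components of size ≤ 2 score 0. The implementation rides
on igraph's Brandes algorithm with the per-component normalization applied
by the package, and is verified to 1e-9 against a pure base-R brute-force
geodesic-enumeration oracle on dozens of random graphs.

The clustering coefficient `C_n = 2e_n/(k_n(k_n−1))` is undefined below
degree 2; such nodes are assigned 0 and the network average is reported
both ways (all nodes vs degree ≥ 2), since published averages rarely state
the convention. Neighborhood connectivity is undefined for isolated nodes,
which are excluded from distributions.

Attribute distributions are compared by a two-sample two-sided
Kolmogorov–Smirnov test. By default the comparison runs on the
*degree-binned averages* (one value per observed degree), the form in
which such distributions are plotted for large networks; per-node
comparison is available via `binned = FALSE`. The binned default is a
documented reading, not the only defensible one.

## Workload choices

Only substrate nodes carry folding flux; chaperone–chaperone edges are
connectivity only. "Pro rata" is read literally as an equal split
`k_syn/m` over the substrate's `m` chaperones — abundance-weighted splits
would add an assumption with no support. Missing degradation rates are
imputed with the geometric mean of the observed ones, which provably
leaves the geometric mean of the table unchanged. Half-lives convert via
first-order decay, `k_deg = ln 2 / t_half`. Abundances given in ppm are
converted by a single configurable total-molecules-per-cell constant
(default 5×10⁷); every workload property of interest is scale-equivariant,
so this constant affects units only. When a filtered high-confidence
interaction subset is supplied, both the flux scope and the multiplicity
`m` come from that subset.

Conservation is exact by construction and asserted at 1e-9 relative: total
assigned flux equals total substrate synthesis flux, and after a deletion,
extra workload plus orphaned flux equals the deleted chaperone's `F_c`.
The HSP70-vs-other split uses a configurable family list defaulting to the
canonical yeast HSP70 genes (`hsp70_family()`).

## Numerical and degenerate-input policy

Zero intensities → missing; zero-degree nodes → `NA` neighborhood
connectivity, clustering 0, betweenness 0; all-missing turnover → error;
fewer than 2 shared proteins → normalization error; unknown node or
chaperone ids → error naming the id. Ties in shortest paths are never
broken — fractional counting uses all geodesics. The ANOVA returns F = 0,
p = 1 for identical groups with positive variance, and refuses (flags
untestable) degenerate ones.

## Problem sizes and what the checks show

The test suite and the acceptance script run entirely on synthetic data at
deliberately modest sizes chosen as the package's own validation design:
50–60 random graphs of ≤ 30 nodes against the brute-force betweenness
oracle; 20-chaperone/400-substrate networks for conservation; 1000-protein
standards in technical triplicate for normalization validation; five
1000-protein null experiments for type-I calibration; the default
63/2000-node network for hub-deletion and workload-vs-betweenness
analyses. Each check completes in seconds and scales linearly or better,
so larger runs are a matter of configuration, not code.

## Limitations

- With biological quadruplicates and 0.3 log2 noise per channel, 80%
  sensitivity after BH control requires effects around 1.5–1.75 log2
  units; two-fold spikes (|log2FC| = 1) are detected at only ~10–40%
  sensitivity. This is a power fact about the design, not a defect of the
  test; the acceptance summary reports the measured sensitivity honestly.
- The generator's missingness is MCAR; real SILAC dropout is
  intensity-dependent, which biases ratios of low-abundance proteins in
  ways these simulations do not probe.
- Workload treats the chaperome as a static interaction map: no kinetics,
  no co-chaperone stoichiometry, no compartmentalisation, and no rewiring
  after deletion.
- Betweenness-vs-workload agreement on synthetic networks (Spearman over
  the top 15 chaperones, typically 0.3–0.8 depending on seed) is driven by
  shared degree dependence but diluted by the wide log-normal abundance
  dispersion; it is a qualitative, not calibrated, reproduction of the
  positive correlation seen in measured chaperomes.

## A short worked example

```{r example}
cfg <- sim_config(global_shift = 1.3, de_fraction = 0.05, seed = 7)
report <- run_pipeline(cfg)
report

## the raw shift estimate recovers log2(1.3) = 0.379
report$quant$median_fold_change_raw

## hub deletion: exact bookkeeping and modest distribution change
report$topology$n_orphans
report$topology$ks

## workload redistribution after deleting the top-betweenness chaperone
head(report$workload$deletion_extra, 3)
report$workload$family_split
```
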
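---
title: "Models and methods behind microstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstab)
```

microstab analyses depth-stratified microbial surveys along four axes:
diversity, assembly processes, network complexity/stability, and
environmental tipping points. This vignette explains the models, the
tunable parameters that matter, the numerical choices, what the synthetic
generator does and does not emulate, and the known limitations.

## Community assembly: βMNTD, βNTI and RCbray

The phylogenetic turnover between two samples is the abundance-weighted beta
mean nearest taxon distance,

$$\beta\mathrm{MNTD}(A,B) = \tfrac12\Big(\sum_{i \in A} f_{iA}\,
\min_{j \in B} d_{ij} + \sum_{j \in B} f_{jB} \min_{i \in A} d_{ij}\Big),$$

with \(f\) relative abundances and \(d\) patristic distances. A taxon shared
by both samples contributes distance zero (conspecifics included), so two
identical one-taxon samples give βMNTD = 0.

βNTI standardizes the observed βMNTD against a **taxa-shuffle null**: taxon
labels are permuted across the tips of the (table-restricted) tree,
`null_reps` times, and
\( \beta\mathrm{NTI} = (\beta\mathrm{MNTD}_{obs} - \mu_{null})/\sigma_{null} \).
The permutation universe is every table taxon present in the tree —
including zero-count taxa — because the null asks how turnover would look if
phylogenetic positions were random with the community data fixed. One
permutation stream per call serves all sample pairs (the standard
standardized-effect-size practice); the inner loop is C++ and caches, per
permutation and sample, the nearest-taxon distance of every taxon to that
sample, making the all-pairs pass \(O(S\,T\,\bar n)\) rather than
\(O(\text{pairs}\,\bar n^2)\).

Degenerate nulls (zero variance, e.g. a star phylogeny or identical presence
sets) are returned as `NA` with a flag, never as ±∞, and are excluded from
process fractions with their count reported.

RCbray measures taxonomic turnover beyond random assembly. For each pair,
null communities preserve each sample's observed richness and total count:
taxa are drawn without replacement with probability proportional to their
**occurrence frequency** in the regional pool, each receives one individual,
and the remainder is filled with probability proportional to the pool's
**relative abundance** (weighted sampling uses exponential-race keys; the
fill uses sequential binomials; both in C++ on R's RNG so a seed fixes
everything). With \(m\) null Bray–Curtis values,
\( RC = 2\,[(\#\{BC_{null} < BC_{obs}\} + \tfrac12\#\{=\}) / m - \tfrac12] \in [-1, 1] \).
Per-pair random streams are derived from the master seed by integer mixing,
so results are independent of pair order.

Classification: βNTI > 2 heterogeneous selection, βNTI < −2 homogeneous
selection; otherwise dispersal limitation (RC > 0.95), homogenizing dispersal
(RC < −0.95), or drift. The boundary |βNTI| = 2 — a measure-zero event —
falls on the stochastic side. The regional pool for both nulls is the set of
samples in the same group (layer), the grouping under which fractions are
reported; `assembly_analysis()` makes that pooling explicit.

## Co-occurrence networks

Edges are Spearman rank correlations (midranks for ties) between taxa on
relative abundances, keeping taxa present in ≥ `min_prevalence` of samples
(default 20%). P-values use the t approximation; edges need
|ρ| ≥ `rho_threshold` (default 0.6) and an adjusted p < `alpha` (default
BH, 0.05). These thresholds are the co-occurrence literature's common
defaults; they are recorded in the network object and its GraphML output so
any tuning is visible. Raising the ρ threshold or lowering α can only remove
edges (tested as a monotonicity property).

Topology reports average degree \(2E/N\), density \(2E/\binom{N}{2}\),
the mean local clustering coefficient over nodes of degree ≥ 2 (the
Watts–Strogatz convention, matching what graph GUIs report; triangle-ratio
transitivity by option), Louvain modules and modularity on |ρ| weights with
a fixed seed, and the positive-edge fraction. An edge-free layer yields a
zeroed row with modularity flagged `NA` rather than an error.

## Cohesion (complexity) and robustness (stability)

Connectedness corrects raw Pearson correlations by an abundance-shuffle
null: each taxon's **counts** are permuted across samples independently and
the null samples re-normalised before correlating. Re-closing the null
matters: relative abundances carry a compositional correlation of about
\(-1/(T-1)\) even for independent taxa, and a null that shuffles already
normalised values does not reproduce it; with re-closure the corrected
correlations are centred at zero on independent data (a tested property).
A taxon's positive (negative) connectedness is the mean of its positive
(negative) corrected correlations; per-sample cohesion is the
relative-abundance-weighted sum. Complexity defaults to positive cohesion,
with |negative| and total |cohesion| as options.

Robustness removes \(\lfloor f \cdot n \rfloor\) random nodes
(default \(f = 0.5\), 100 repetitions) and counts the fraction of taxa that
keep at least one neighbour; secondary extinction is isolation. Per-sample
stability applies this to the layer network's induced subgraph on the taxa
detected in that sample — the only construction that yields per-sample
points for boxplots and gradient regressions. Network-level and per-sample
robustness are reported separately since they answer different questions.
Targeted (degree-ranked) removal is available by flag.

## Segmented regression and driver screening

Tipping points use the continuous broken-stick model
\(y = a + b x + c\,\max(0, x - \psi)\). ψ is profiled exhaustively over the
interior observed x values with at least `min_seg` (default 3) points on
each side; each candidate is an OLS fit, the smallest SSE wins, and SSE ties
go to the smallest ψ. Exhaustive profiling is deterministic and global — no
starting values, no convergence failures — and makes ψ̂ affine-equivariant
in x. The segmented fit is compared with the single line by Gaussian AIC,
charging one extra parameter for the profiled breakpoint; "significant
change point" means ΔAIC > 2 **and** overall F-test p < 0.05. Exactly
linear data short-circuit to a `no_change_point` flag (AIC is undefined at
zero residual variance). All fits are reported with flags; nothing is
filtered.

For pairwise responses (Bray–Curtis, βNTI) regressed on a scalar driver,
the pair's driver value is the pair mean by default (pair difference by
option). Pairwise points are not independent, so such p-values should be
read as naive; a Mantel-style permutation is the calibrated alternative.
Similarly, the Kruskal–Wallis comparison of within-layer distance
distributions is reported both with its (anti-conservative) nominal p and
with a label-permutation p that is exact by exchangeability.

The Mantel test correlates upper-triangle entries under simultaneous
row/column permutations of the second matrix, with
\(p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})\); for ≤ 8 samples the
full \(n!\) enumeration is available and is what the sampled p is tested
against.

## The synthetic generator

`simulate_metacommunity()` emulates a subtropical gulf depth survey: three
layers (surface/middle/bottom) with 21/16/19 sites and five replicates by
default (280 samples), a Yule tree over a few hundred taxa, and layered
environmental gradients (temperature, salinity, pH, DO, nutrient species,
TOC, COD, chlorophyll-a; DIN derived as NO2 + NO3 + NH4) with per-layer
means, site effects and physical bounds chosen as oceanographically
plausible values for such a system.

Under the **selection** regime each taxon's environmental optimum evolves by
Brownian motion on the tree, blended with independent noise by
`niche_conservatism` \(\in [0,1]\); expected abundance decays as
\(\exp(-s\,z^2/2)\) with \(z\) the standardized distance of the sample's
driver (DO by default) from the optimum and \(s\) = `selection_strength`.
Without conservatism βNTI has no power — selection must be phylogenetically
structured to move nearest-taxon distances. Setting \(s = 0\) reduces
exactly to the **neutral** regime: a shared log-normal species-abundance
distribution with multinomial sampling at log-normally distributed depths
(`sad_sdlog = 2` by default; a flatter SAD at typical depths makes nearly
every taxon ubiquitous, which degenerates presence-based nulls and does not
resemble amplicon data). Ground truth (optima, regime, breakpoints) is
always emitted; tests never reverse-engineer it.

What the generator does **not** emulate: sequencing error and chimeras,
taxonomic assignment, temporal dynamics, spatial autocorrelation beyond the
site effect, and interaction-driven (as opposed to environment-driven)
co-occurrence. Passing tests therefore demonstrate statistical correctness
and recoverability under a known model, not field realism.

Piecewise responses (`simulate_piecewise_response()` and `breakpoint_spec`)
place a response exactly on the broken-stick line plus Gaussian noise, with
the true ψ validated to lie strictly inside the generated driver range.

## Numerical choices and problem sizes

- "Simpson" means Gini–Simpson \(1 - \sum p_i^2\); the figure direction in
  typical reports cannot disambiguate the variant, so both are exposed and
  the default is logged in the output.
- No rarefaction; relative abundances throughout.
- RC ties are counted at half weight with a 1e-12 comparison tolerance;
  null standard deviations below 1e-12 are treated as degenerate.
- Seeds: every stage derives independent streams from one master seed by
  integer mixing (32-bit safe); reruns are byte-identical, which the test
  suite asserts on whole output directories.
- The test and acceptance runs use scaled-down designs (tens of samples,
  99–999 permutations, 100–400 Monte-Carlo replicates) chosen so each
  property is tested at the scale at which it is defined while the whole
  suite stays fast; the generator's scientific defaults are unchanged by
  that scaling.

## Limitations

- Spearman co-occurrence ignores compositionality; SparCC-style inference is
  out of scope by design, and network edges should be read as associations.
- βNTI assumes the supplied phylogeny is meaningful for the traits under
  selection; the package does not build trees.
- Only one breakpoint per fit; discontinuous change-point models and
  Davies-type tests are not implemented.
- The five-way classification inherits the usual sensitivity to the ±2 and
  ±0.95 thresholds; fractions near those boundaries move with `null_reps`.
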
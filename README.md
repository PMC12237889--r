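# microstab

Downstream analysis of depth-stratified microbial community surveys: who
assembles these communities (selection, dispersal, or drift), how complex and
stable their co-occurrence networks are, and at which point along an
environmental gradient those properties tip.

The package takes three inputs — a taxa-by-samples count table (TSV), a rooted
phylogeny with branch lengths (newick), and per-sample environmental
measurements (TSV) — and provides:

- **Diversity.** Richness, Shannon (natural log), Simpson (Gini–Simpson
  `1 − Σpᵢ²` by default, inverse Simpson by option), bias-corrected Chao1
  `S_obs + F1(F1−1)/(2(F2+1))`, Bray–Curtis dissimilarity on relative
  abundances, and within-layer dissimilarity comparisons (Kruskal–Wallis +
  pairwise Wilcoxon with BH correction and compact letter display, plus a
  calibrated label-permutation p-value).
- **Assembly partitioning.** Abundance-weighted βMNTD, its standardized
  effect size βNTI under a taxa-shuffle null (tip labels permuted, implemented
  in C++), abundance-based Raup–Crick with Bray–Curtis (RCbray: null
  communities drawn by occurrence-weighted richness and abundance-weighted
  fill), and the five-way classification: βNTI > 2 heterogeneous selection,
  βNTI < −2 homogeneous selection, otherwise RC > 0.95 dispersal limitation,
  RC < −0.95 homogenizing dispersal, |RC| ≤ 0.95 drift.
- **Co-occurrence networks.** All-pairs Spearman ρ on relative abundances
  with t-approximation p-values and BH/Bonferroni correction; topology
  (average degree 2E/N, density, mean local clustering, seeded Louvain
  modularity and module count, positive-edge fraction).
- **Complexity and stability.** Cohesion: per-taxon connectedness as observed
  Pearson correlation minus its mean under per-taxon abundance shuffles
  (null samples re-closed), abundance-weighted per sample. Robustness: the
  fraction of taxa that keep at least one neighbour after random removal of
  a fixed node fraction, per network and per sample-induced subgraph.
- **Gradient statistics.** Spearman screens, Mantel permutation tests (with
  exhaustive enumeration for small n), OLS fits, and segmented (broken-stick)
  regression `y = a + b·x + c·max(0, x − ψ)` with the breakpoint ψ profiled
  exhaustively over interior observed x values, compared to a single line by
  AIC.
- **Synthetic data with ground truth.** Yule trees, communities whose taxa
  carry Brownian-motion-evolved environmental optima (selection regime) or a
  shared log-normal abundance distribution (neutral regime), layered
  environmental gradients, and piecewise responses with known breakpoints.
- **A composed pipeline** (`run_pipeline()`) that writes every product
  (TSV/JSON/GraphML) plus `provenance.json`, byte-identical under a fixed
  master seed. A thin CLI wrapper lives in `inst/scripts/run_pipeline.R`.

## Worked example

```r
library(microstab)

sim <- simulate_metacommunity(simulation_config(
  n_taxa = 100, sites = c(SL = 5, ML = 5, BL = 10), replicates = 2,
  assembly_regime = "selection", selection_strength = 10,
  niche_conservatism = 0.95, seed = 1))

res <- assembly_analysis(sim$table, sim$tree, null_reps = 199, seed = 1)
print(res)
#> assembly_result: 280 sample pairs, 3 group(s), null_reps = 199
#> deterministic fraction (|betaNTI| > 2): BL = 0.279, ML = 0.089, SL = 0.111

d <- simulate_piecewise_response(100, psi_true = 6, slopes = c(1, 0),
                                 noise_sd = 0.5, x_range = c(0, 10), seed = 1)
fit <- segmented_fit(d$x, d$y)
print(fit)
#> Segmented regression (continuous broken-stick)
#>   breakpoint psi = 6.04933  (n = 100, 95 candidates)
#>   slopes: left 0.998436, right -0.12585; intercept 0.0733231
#>   r^2 = 0.9377 (linear fit: 0.8001), p = 3.419e-59, delta AIC = 112.59
#>   change point significant (delta AIC > 2, p < 0.05)
```

The deterministic fraction is the share of sample pairs whose phylogenetic
turnover departs from the taxa-shuffle null (|βNTI| > 2), i.e. pairs shaped by
selection rather than stochasticity; under the simulated selection regime it
is far above the ~5% a neutral community produces. The segmented fit recovers
the planted breakpoint ψ = 6 from noisy data and reports the improvement over
a straight line.

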
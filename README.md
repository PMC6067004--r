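# mlpr — multi-level PPI network reconstruction and complex detection

High-throughput protein–protein interaction (PPI) catalogs carry high
false-positive *and* false-negative rates, which caps the accuracy of any
complex-detection algorithm run on them. `mlpr` rebuilds a de-noised,
weighted PPI network first and clusters second:

1. **Every** unordered protein pair (not just cataloged edges) gets a
   17-component evidence vector: domain–domain interaction score `D`, GO
   semantic similarity `MF/BP/CC` and GO-slim sharing `mf/bp/cc`,
   coexpression `CE`, a STRING-like score `S`, five AP-MS reliability
   scores `TAP1..TAP5`, two curated-database memberships `EPPI1/EPPI2`,
   and a shared-neighborhood feature `CD` (1 − Czekanowski–Dice distance).
2. Pairs with identical (quantized) vectors collapse into a
   **fingerprint**; each fingerprint is linked to its `T = 10` most
   similar fingerprints, with min–max-rescaled Euclidean similarity
   weights `M_ij = 1 − (d_ij − d_min)/(d_max − d_min)`.
3. A **random walk with restart**, `F_r = (1−α) M F_{r−1} + α F_0` with
   `α = 0.8` and L1 tolerance `1e-6`, propagates mass from *reliable
   seeds* (fingerprints backed by ≥ 2 curated databases with > half of
   their components nonzero). Pairs inherit their fingerprint's
   steady-state score; the `top_n` ranked pairs become the reconstructed
   weighted network.
4. **Seeded expansion** detects complexes: vertices queue by summed
   incident weight, and a cluster `K` admits its best neighbor `v` while
   the interaction probability `E_vK = e_vK / w_K ≥ T_in` (default 0.6)
   and the cluster diameter stays ≤ `d = 2` hops.

Predictions are scored against a benchmark by neighborhood affinity
`NA(p,b) = |p∩b|²/(|p||b|) ≥ ω` (default 0.25), yielding precision,
recall and F-value, plus hypergeometric functional-homogeneity p-values.

A fully seedable synthetic-fixture generator (`truth_spec()`,
`generate_fixture()`) plants complexes and emulates all six evidence
sources with controlled corruption, so the entire pipeline is testable
offline.

## Worked example

```r
library(mlpr)

fx  <- generate_fixture(truth_spec(seed = 42))     # 300 proteins, 20 planted complexes
cfg <- mlpr_config(top_n = nrow(fx$true_edges))
run <- run_mlpr(fx$bundle, cfg, proteins = fx$proteins)
run
#> <mlpr_run> 300 proteins, 38819 fingerprints, network of 550 edges (walk: 6 iterations)

# how much of the reconstructed network is real?
truth <- paste(fx$true_edges$protein_a, fx$true_edges$protein_b)
kept  <- paste(run$network$protein_a, run$network$protein_b)
mean(kept %in% truth)
#> [1] 0.9981818

precision_recall_f(run$complexes, fx$complexes, omega = 0.25)
#> <eval_summary> 179 predicted vs 20 benchmark (omega = 0.25)
#>   matched: 124 / 20  precision 0.6927  recall 1.0000  F 0.8185
```

The 44,850 enumerated pairs collapse to ~39,000 fingerprints; the walk
converges in 6 iterations; 99.8% of the top-ranked edges are genuine
(the density-matched random baseline would get 1.2%), and the detected
clusters recover every planted complex.

A thin CLI wraps the same functions
(`inst/scripts/mlpr simulate|reconstruct|detect|evaluate`); configs are
flat YAML files mirroring `mlpr_config()`, and evidence sources are named
in a manifest YAML (see `bundle_from_manifest()`).

## Layout

- `R/` — io/config, ontology + information content, evidence bundle,
  pair features, fingerprinting, kNN graph, random walk, detection,
  evaluation, synthetic data, pipeline drivers
- `src/knn.cpp` — exact brute-force kNN with global distance extrema
- `vignettes/mlpr-methods.Rmd` — the model, parameter meanings, design
  decisions and limitations
- `tests/testthat/` — unit, property and whole-method tests
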
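---
title: "Multi-level PPI network reconstruction and complex detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level PPI network reconstruction and complex detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput protein–protein interaction (PPI) catalogs are noisy in
both directions: many reported edges are spurious, and many genuine
interactions are missing. Complex-detection algorithms that search for
dense regions inherit both error modes. `mlpr` addresses this by
*reconstructing* a weighted interaction network from many evidence sources
before any clustering happens, and then detecting complexes on the
reconstructed network.

The pipeline has four stages:

1. **Pair evidence vectors.** Every unordered pair of proteins — all
   $n(n-1)/2$ of them, not just the cataloged edges — is described by a
   17-component vector $(D, MF, mf, BP, bp, CC, cc, CE, S, TAP1..TAP5,$
   $EPPI1, EPPI2, CD)$: a domain–domain interaction score, GO semantic and
   GO-slim similarity per aspect, expression correlation, a STRING-like
   score, five AP-MS reliability scores, two curated-database memberships,
   and a shared-neighborhood topology feature.
2. **Fingerprints.** Pairs with identical (quantized) vectors collapse
   into one *fingerprint*; the fingerprint inherits the vector. This is
   both a computational device and a statistical one — evidence patterns,
   not individual pairs, are scored.
3. **Similarity graph and random walk.** Each fingerprint is linked to its
   $T$ most similar fingerprints (Euclidean distance on vectors, min–max
   rescaled into similarities). A random walk with restart from
   *reliable-seed* fingerprints gives every fingerprint a steady-state
   probability; every pair inherits its fingerprint's score, and the
   `top_n` ranked pairs become the reconstructed weighted network.
4. **Seeded expansion.** On the reconstructed network, vertices are queued
   by summed incident weight; clusters grow greedily from seeds under an
   interaction-probability threshold and a diameter bound.

## Models and formulas

### GO semantic similarity (components MF, BP, CC)

Information content is corpus-based: $IC(t) = -\log$ of the fraction of
annotated proteins whose (up-propagated) annotations include $t$. Two
terms are compared by their most informative common ancestor,
$sim(t_1, t_2) = 2\,IC(\mathrm{MICA}) / (IC(t_1) + IC(t_2))$ with $0/0$
defined as 0, and two proteins by the mean of $sim$ over all cross pairs
of their directly annotated terms. This IC-normalized form is bounded in
$[0,1]$, which the 0.5 relevance threshold of `edge_go_relevance()`
presupposes. The source material describes the coarse GO-slim features
(mf, bp, cc) as the binary ones — sharing at least one non-root slim term —
while also calling the uppercase triple boolean; the definitions force the
ranges used here (semantic similarity numeric in $[0,1]$, slim features
0/1), so that is what the package implements.

### The remaining components

* **CE** — Pearson correlation of (optionally log2(x+1)-transformed)
  expression profiles; missing or zero-variance profiles give 0.
* **D** — sum of domain–domain interaction confidences over all unordered
  cross pairs of the two proteins' domains; unknown pairs contribute 0.
* **S**, **TAP1–TAP5** — pass-through score tables; the package does not
  recompute STRING or AP-MS reliabilities.
* **EPPI1, EPPI2** — 0/1 membership in two curated edge sets.
* **CD** — the Czekanowski–Dice distance between self-inclusive
  interaction neighborhoods,
  $|N_a \triangle N_b| / (|N_a \cup N_b| + |N_a \cap N_b|)$. The stored
  feature is $1 - $ distance so that, like every other component, larger
  means stronger evidence; `cd_as_similarity = FALSE` restores the raw
  distance. Missing evidence of any kind is encoded as 0, never `NA`, so
  vectors are always complete and fingerprintable.

### Fingerprint similarity and the walk

Distances between fingerprint vectors are rescaled by the *global*
minimum and maximum realized distance,
$M_{ij} = 1 - (d_{ij} - d_{\min}) / (d_{\max} - d_{\min})$. The printed
form of this rescaling indexes its min/max by a vertex that does not
appear in the expression, so the domain is genuinely ambiguous; the global
reading is adopted because the top-$T$ neighbor choice is monotone in raw
distance and therefore unaffected, and a single global anchor keeps
weights comparable across rows. With `dmax == dmin` every weight is 1.
The directed top-$T$ relation is symmetrized by union, and the weighted
adjacency is row-normalized into the transition matrix.

The walk iterates $F_r = (1-\alpha)\,M\,F_{r-1} + \alpha F_0$ with
$F_1 = F_0$, exactly as written: $M$ multiplies on the left and no
renormalization happens between iterations, so total mass is not
conserved — rankings, which are all that is consumed downstream, are
unaffected. Iteration stops when the L1 difference between successive
iterates falls below `tol` ($10^{-6}$ by default; $\alpha = 0.8$). Because
the update is a contraction, the iterate count is bounded by roughly
$\log(\mathrm{tol}) / \log(1-\alpha) \approx 9$ at the defaults, which the
test suite asserts.

**Seed rule.** A fingerprint seeds the walk when at least two of its
database-indicator components are nonzero *and* strictly more than half of
all 17 components are nonzero. The indicator set defaults to
`{EPPI1, EPPI2, TAP1, TAP5}`: the methods text asks for curated-database
membership, while the results text names two AP-MS score columns and an
"equal to 1" test that continuous scores cannot satisfy; the union of both
readings is expressible because the indicator set and threshold are
configuration, not code. Seed mass is normalized to $1/|\mathrm{seeds}|$
rather than the verbatim "+1" per seed: the walk is linear in $F_0$, so
scaling the prior scales the posterior and leaves every ranking identical
(a property the tests verify), while a normalized prior keeps posteriors
on a probability-like scale.

### Cluster expansion

Vertex weight is the summed incident edge weight; the seed queue is
ordered by weight, then degree, then ID. A candidate neighbor $v$ of
cluster $K$ scores $E_{vK} = e_{vK} / w_K$ (edge weight into $K$ over edge
weight inside $K$) and is admitted while $E_{vK} \ge T_{in}$ and the
induced subgraph of $K + v$ has unweighted diameter at most $d$. Three
under-specified points are resolved as follows:

* $w_K = 0$ for a singleton seed makes $E_{vK}$ division-free nonsense;
  the package returns $+\infty$ for connected neighbors, so the seed's
  best-connected neighbor always boots the cluster. A "skip seed" flag is
  not provided; the sentinel is the documented behavior.
* The diameter bound has no stated value in the source material; the
  default is $d = 2$, the customary small-diameter constraint for
  complexes.
* Queue removal blocks *re-seeding* only; proteins may join several
  clusters (`allow_overlap = FALSE` forbids it). Clusters below
  `min_complex_size = 3` are discarded, mirroring the benchmark filter
  that drops singleton and pair "complexes".

A consequence worth knowing: in a uniform-weight clique of size $s$, the
last member joins with $E_{vK} = 2/(s-1)$, so a threshold $T_{in}$ caps
recoverable clique size at $2/T_{in} + 1$. The default $T_{in} = 0.6$
favors small dense cores; the clique-recovery tests use
$T_{in} = 0.25$ for exact recovery of cliques up to size 8.

### Evaluation

Predicted and benchmark complexes match when the neighborhood affinity
$NA(p, b) = |p \cap b|^2 / (|p|\,|b|)$ reaches $\omega$ (default 0.25;
0.20 is the other customary value). Precision counts matched predictions,
recall matched benchmark complexes, and the F-value is their harmonic
mean with $0/0$ defined as 0; an empty prediction set scores 0 rather
than erroring so parameter sweeps never crash. Functional homogeneity is
the minimum hypergeometric upper tail
$P(X \ge k)$ over annotation groups, computed through `phyper` (log-space
internally) and cross-checked in the tests against direct
binomial-coefficient summation; no multiple-testing correction is applied
by default, with a Bonferroni flag available. Edge relevance uses a
strict "> threshold" comparison.

## The synthetic study conditions

`truth_spec()` defaults define the study regime: 300 proteins, 20 disjoint
planted complexes of 5–8 members, within-complex edge probability 0.9
against a 0.005 background, every observed source corrupted with 10%
false negatives and 10% false positives (as a fraction of the true edge
count), 50 expression samples with within-complex pairwise correlation
0.7 via one latent factor per complex, and annotation/domain sharing
probability 0.9. TAP/STRING scores are Beta(5,2) for genuine edges and
Beta(2,5) for false positives — strong but overlapping score
distributions. The second database edge set doubles as the topology
network, as a curated physical-interaction catalog would.

What the generator does *not* emulate: realistic degree distributions,
overlapping complexes, GO DAG depth and annotation sparsity, batch
structure in expression, or correlated errors between sources (each
source is corrupted independently). Passing the end-to-end recovery test
therefore shows the machinery is sound and the signal path intact — not
that real-interactome performance is reproduced.

Problem sizes: the package's own validation runs the full pipeline at the
default 300-protein regime (44,850 pairs, typically ~37,000–40,000
fingerprints after quantization at 4 decimals), plus a pure enumeration
check at 7,018 proteins (24,622,653 pairs). Exact kNN is brute force in
compiled code, $O(F^2 d)$; at these scales a run completes in well under
a minute on one core.

## Numerical choices

* **Quantization** (4 decimals, round-half-even, `-0` normalized to `0`)
  defines "same vector" for fingerprinting; the collapse observed on real
  data implies heavy collisions but no stated rule, so the precision is
  configuration. IDs are assigned in lexicographic order of the quantized
  vectors, making fingerprint tables reproducible byte for byte.
* **Ordering and ties.** Every string comparison that can affect output —
  pair canonicalization (smaller ID first), rank ties (by canonical pair),
  kNN ties (smaller fingerprint ID), queue ties (degree, then ID),
  expansion ties (higher vertex weight, then ID) — uses C-locale byte
  order, so results are independent of the session locale.
* **Degenerate inputs.** Self-interactions are dropped at parse time
  (detection and affinity scoring are set-based); duplicate weighted edges
  keep the maximum score, preserving the strongest reported evidence;
  zero-variance expression and unannotated proteins contribute 0, with
  warnings where the user should know.
* **Sparse iteration.** The walk always runs on a sparse transition matrix
  (`Matrix::dgCMatrix`); a dense path would be numerically identical and
  is not worth a second code branch.

## Limitations

* Exact brute-force kNN is quadratic in the number of fingerprints;
  million-fingerprint corpora would need an approximate-neighbor backend
  behind `build_knn_graph()`'s contract.
* The benchmark-matching step uses the existential match of the
  definitions, not best-match bipartite assignment; composite measures
  (MMR, Sn-PPV accuracy) are out of scope.
* GO features assume the annotation corpus *is* the IC corpus; supplying
  a tiny annotation table makes IC estimates coarse.
* `T_in` interacts with expected complex size (see above); sweeping it
  against held-out benchmarks is advisable on real data.
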
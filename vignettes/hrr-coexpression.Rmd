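---
title: "HRR co-expression networks: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRR co-expression networks: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records how `hrrnet` models gene co-expression, what its
tunable parameters mean, which design questions were genuinely open and how
they were settled, and what the synthetic benchmarks do and do not
demonstrate about real data.

## The co-expression model

The package assumes a normalized, log-scale expression matrix (e.g. RMA
values), probesets × arrays, with at least 3 arrays and no zero-variance
rows — correlation is undefined below that, and the loaders refuse rather
than propagate NaN. Similarity is Pearson's *r* only: the rank transform
that follows absorbs most of the benefit other metrics would bring, and
using a single metric keeps ranks comparable across sub-compendia.

For each gene the other genes are ranked by decreasing *r* (rank 1 = most
strongly co-expressed). The phrase "ranks in ascending order of *r*" can be
read with rank 1 at the most *negative* correlation; that reading is
internally inconsistent with every downstream use of the index (strong
partners are always reported at small values), so rank 1 = highest *r* is
implemented. Negative correlations are not excluded — they simply land at
large ranks. Rank ties are broken by ascending probeset identifier
(C-locale), which makes every result of the package — ranks, HRR, guide
clusters, thresholded networks — a deterministic function of the input.

`HRR(A,B) = max(rank(A,B), rank(B,A))` is symmetric by construction,
bounded by `1 ≤ HRR ≤ n−1`, and dominates both directional ranks. Because
HRR is a *rank*, its scale is tied to the number of genes `n`: a cutoff of
30 retains roughly the reciprocal-top-30 neighbourhood regardless of how
strong the underlying correlations are. Consequences of this scale
dependence run through the whole design (see *Limitations*).

### Computation at genome scale

Correlation, ranking and HRR are computed in row blocks (`block_size`,
default 1024): a slab of correlations is formed by BLAS, ranked, and
discarded. Block boundaries provably do not change results (regression
tested at several block sizes). For guide clusters on array-genome-scale
inputs (~30,000 probesets) the full rank matrix is held in a compiled
16-bit store (`src/rank_store.cpp`) — ranks are bounded by `n − 1 < 2^16` —
and top-*k* selection runs over tiles with a packed 64-bit key
(HRR, guide's own rank, identifier rank), so the whole guide analysis fits
in about `2 n²` bytes. The streaming and the plain-R dense paths are
asserted identical on shared instances.

## Significance by permutation

The null hypothesis is "no co-expression structure": every probeset's
values are independently shuffled across arrays, which preserves each
gene's marginal distribution and destroys all inter-gene correlation.
Column-label permutation would preserve all correlations and tests nothing,
so it was rejected. Each of `n_permutations` (default 100) shuffles yields
a full HRR matrix whose `n(n−1)/2` values are pooled into one histogram.

- `cutoff_at(α)` is the largest integer `h` with empirical
  `P(HRR ≤ h) < α`; `α = 1` returns `n − 1` so the boundary behaves as "no
  filter". Pooling over all pairs (rather than per-gene minima) matches the
  use of a single network-wide cutoff; per-gene pooling is not implemented.
- `hrr_pvalue(h)` is the left-tail empirical p with add-one correction,
  `(#{null ≤ h} + 1)/(total + 1)`, so p is never exactly 0.

Under the null the HRR CDF is approximately `h/(n−1)` — far heavier than
the `(h/(n−1))²` that independent directional ranks would give, because
*r*(A,B) is one symmetric number: if it is high in A's list it is almost
surely high in B's. This empirical law is why significance cutoffs scale
with `n`, and it matches the behaviour of permutation cutoffs reported for
full-size compendia (about 1% of `n` at α = 0.01).

Because HRR scale depends on `n`, gene subsampling is only meaningful
*before* network construction; cutoffs estimated on a subsample apply to
the subsampled network size only.

## Thresholded networks and weights

`threshold_network` keeps all pairs with `HRR ≤ cutoff`; every retained
edge carries one uniform weight. The five canonical (cutoff, weight) pairs
— (10, 0.2), (20, 0.067), (30, 0.04), (40, 0.028), (50, 0.022) — are
returned verbatim; they satisfy `w = 1/(cutoff − 5)` exactly, and that
closed form extends the mapping to unlisted cutoffs above 5. For cutoffs of
5 or less the reciprocal form is undefined or negative, so unit weight is
used there. Nodes with no retained edge are excluded from the edge list but
reported, so downstream accounting (nodes in network vs. on array) stays
honest.

## Markov clustering

`mcl()` is a from-scratch implementation of the standard flow simulation:
add self-loops, column-normalize, then iterate expansion (matrix square by
default), inflation (entrywise power `I`, then renormalization) and pruning
(entries < `pruning_threshold`, then renormalization) until the max
absolute entrywise change falls below `convergence_tol` or `max_iterations`
is reached (then: warning, last iterate interpreted). Clusters are the
weakly connected components of the limit matrix's nonzero structure; a node
flowing to attractors of two systems merges them, so the result is a
disjoint partition. Clusters get stable integer ids by decreasing size
(ties: smallest member id), and clusters with fewer than `min_size = 3`
members are moved to `unassigned` — below three genes a "module" supports
no shared-function inference.

Defaults and their rationale:

- `inflation` grid 1.1–2.0 in 0.1 steps for the sweep; granularity
  increases with `I`.
- `self_loop_weight = "max"`: each node's loop equals the largest edge
  weight in its column, the documented default of the reference MCL
  implementation. On these uniformly weighted networks this makes the
  clustering invariant to the absolute scale of the cutoff weight, which is
  the correct behaviour — the same topology must not cluster differently at
  `w = 0.2` versus `w = 0.04`. A fixed unit loop (also selectable) breaks
  that invariance and, at loop-to-edge ratios of ~25:1, turns every node
  into its own attractor at moderate inflation. A numeric value overrides
  the default.
- `pruning_threshold = 1e-5`, `convergence_tol = 1e-8`,
  `max_iterations = 100`: conventional values; on desk-scale graphs results
  are insensitive to ±1 order of magnitude of the pruning threshold (tested).
  Column sums are tracked at every normalization and stay within 1e-9 of 1.

Inter-cluster connectivity is reported as the bipartite edge density
`|edges between A and B| / (|A|·|B|)`, flagged when strictly above 0.03.
The exact formula behind the published 0.03 convention is not printed
anywhere accessible; edge density reproduces its magnitude and normalization
and is documented here as this package's definition.

## Enrichment and clustering performance

For each cluster and each GO term with at least one annotated member, the
upper-tail hypergeometric probability is computed; BH adjustment is applied
per cluster × namespace (BP, MF, CC separately — matching the convention of
reporting BP and MF tables independently; whether the original tooling
pooled across clusters is not documented, and per-cluster is the standard
behaviour of the BiNGO-style test). A term is *significant* iff
FDR < 0.05 **and** it covers ≥ 2 cluster genes.

The sampling universe defaults to the background probesets carrying at
least one annotation in the tested namespace: unannotatable probesets can
never be drawn as successes, and counting them would only deflate p.
`universe = "all"` switches to the full compendium. Guide clusters are
tested with the guide included as a member — the guide's own pathway is
part of the cluster's function.

Performance of a clustering is specificity (fraction of clusters with ≥ 1
significant term), sensitivity (fraction of background-attested terms
significant in ≥ 1 cluster) and `F = 2·S·s/(S+s)`, with `F = 0` when both
components are 0 so sweep rankings stay total. The inflation sweep ranks
its grid by F.

## Expression specificity (ESI / cESI)

ESI is a two-stage standardization: (1) z-score each array across
probesets — removing array-level location/scale, e.g. residual intensity
differences; (2) z-score each probeset across arrays of the stage-1 matrix.
The exact formula of the original index is not printed in accessible form;
sequential two-stage z-scoring is the most direct reading of
"within, and then between microarray assays", and it gives the conventional
thresholds (ESI > 1 well expressed, > 5 specifically expressed) their
natural meaning in SD units. Stage 2 consumes stage-1 output (the
alternative — standardizing raw values in stage 2 — is not implemented, as
it would reintroduce the array effects stage 1 removed).

Population (n) standard deviations are used by default so that a one-hot
expression profile attains ESI exactly `sqrt(n_arrays − 1)` at its hot
array; a flag switches to n−1. Probesets whose stage-1 profile is constant
get ESI 0 everywhere (no specificity signal). ESI is exactly invariant to
per-array affine rescaling; per-gene shifts applied before stage 1 are
removed only up to their O(1/n_genes) effect on the cross-gene column
statistics (tested at that fidelity).

cESI of a cluster is the fraction of members with ESI above 1 per array;
per condition group it is the *mean of per-array fractions* within the
group rather than an all-arrays-in-group conjunction — robust to unequal
group sizes, and the size-weighted group means recover the all-array mean
exactly (tested).

## The synthetic compendium

Each planted module follows a single-latent-factor model: in its active
arrays, member `g` has value `base_expression + a·L_j + ε`, with `L_j ~
N(0,1)` per array, loading `a = amplitude`, and member noise chosen so the
expected pairwise correlation is exactly `r = a²/(a² + σ²)` — the closed
form is what makes generator checks derivable. Outside its active
condition a module gene sits at the compendium background level (7) with
background noise: a condition-restricted module is therefore specific in
*expression level* as well as in co-variation, which is what its cESI
profile should detect. Background genes are pure noise around the
background level; per-array additive offsets (`array_effect_sd = 0.25`)
emulate residual global effects after normalization. Annotations are a
planted term on 80% of each module's genes plus uniform background terms.

The default metadata design mirrors a typical plant compendium — a dominant
sub-species, mostly fruit and leaf arrays, a majority of biotic-stress
experiments — assigned deterministically in contiguous blocks.

What the generator does **not** emulate: probe-level effects, correlated
(batch-structured) noise, heavy-tailed expression distributions,
hierarchically overlapping modules, and annotation noise. Passing the
recovery benchmarks therefore demonstrates the machinery is correct and
calibrated, not that any particular real compendium will yield modules of
comparable purity.

## Problem sizes used by the test suite

Unit and property tests run on 25–500-gene instances; the brute-force HRR
oracle runs at 300 genes with block-independence checked at 2,000; the
permutation-calibration check uses 300 genes × 20 arrays × 100
permutations; end-to-end recovery uses 300 genes × 40 arrays with two
15-gene modules at r = 0.9 over 10 seeds; and the guide-cluster accounting
check runs at the full array scale of 30,217 probesets (streaming path).
These sizes were chosen so that each property is measurable with
comfortable statistical margin while the whole suite remains a
desk-scale run.

## Limitations

- **HRR cutoffs do not scale down.** Under the null, `P(HRR ≤ h) ≈
  h/(n−1)`. At `n ≈ 30,000`, HRR ≤ 30 keeps ~0.1% of pairs; at `n = 300` the
  same absolute cutoff keeps ~10% of all pairs — a dense graph in which low
  inflation (I ≈ 1.2–1.3) merges everything into one giant component. On
  desk-scale data the F-measure sweep selects a higher inflation
  (≈ 1.8–2.0) and then recovers planted modules cleanly (tested); the
  low-inflation optimum reported for full-size compendia is a property of
  that scale, not of the method in general. Users clustering small networks
  should trust the sweep, not a transplanted inflation value.
- Guide clusters are gene-centric and overlapping by design; they are not a
  partition and are not size-filtered.
- The permutation null assumes exchangeability of each gene's values across
  arrays; strong shared batch structure violates it and would make cutoffs
  anti-conservative.
- OBO support covers `is_a` parentage (true-path propagation); `part_of`
  and other relations are not traversed.
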
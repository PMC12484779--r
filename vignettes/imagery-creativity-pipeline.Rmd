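---
title: "Methods: semantic creativity metrics, network percolation and edge-centric brain communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic creativity metrics, network percolation and edge-centric brain communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgesem)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical decisions taken where a choice was
genuinely open, and what the synthetic-data generators do and do not
emulate.

## The scientific setting

The package serves studies that relate the vividness of mental imagery to
creative-writing performance through two intermediate layers: semantic
features extracted from the written text (how far the writing travels in
embedding space, how robust its word network is), and the brain's functional
organization during writing (how edges — region pairs — co-fluctuate and
organize into overlapping communities). All stages work on generic inputs
(token streams plus an embedding lexicon; region-by-time matrices plus an
atlas; three-column behavioral tables), so the same code runs on real data
and on the package's seeded synthetic data.

## Text metrics

**Global semantic distance** (`global_semantic_distance()`) divides the
cleaned, in-vocabulary token stream into windows of `window = 10` words
advancing by `step = 5`, represents each window by its mean embedding
vector, and averages the cosine distance between adjacent window means. Both
parameters are word counts; the defaults give 50%-overlapping windows, so
the score reflects the semantic displacement per half-window of text.
Cosine distance makes the score invariant to any positive rescaling of the
lexicon. A trailing window shorter than `window` is **kept when it holds at
least two tokens** (and dropped otherwise): short stories would otherwise
lose their final semantic move entirely, and a two-token mean is still a
meaningful window representation. Texts yielding fewer than two windows are
rejected with an error naming the minimum token count. Out-of-vocabulary
tokens are dropped, never imputed, and the drop count travels with the
score.

**Divergent semantic integration** (`divergent_semantic_integration()`)
expects a contextual embedder — any function mapping a sentence to per-token
vectors for exactly two layers. Sentence segmentation affects only the
embedding context; pairs are pooled across the entire story, because the
indicator describes the story as a whole, not individual sentences. Two
readings of "average distance across the two layers" are possible, and both
are implemented behind `combine`: the default pools the pairwise distances
of both layers with equal weight (each layer contributes the same number of
pairs, so this equals the mean of the two per-layer means); the alternative
averages the two layers' vectors per token first and computes one set of
distances. The default was chosen because it preserves each layer's
geometry instead of mixing representations before measurement.
`lexicon_embedder()` provides a deterministic, fully reproducible provider
backed by a static lexicon; transformer-backed providers plug in through
the same contract.

## Semantic networks and percolation

`build_semantic_network()` collapses the story to its unique in-vocabulary
words and weights every pair by the Pearson correlation of the two embedding
vectors. **Signed weights are retained.** The percolation rule removes
edges with weight strictly below the threshold, so at TH = 0 strictly
negative edges are already gone; this literal reading keeps the threshold
semantics uniform across the grid rather than special-casing negative
correlations.

`percolate()` sweeps TH from `start_th = 0` to `end_th = 1` in steps of
`th_res = 0.0125` (81 thresholds at the defaults; comparisons carry an
absolute guard of 1e-12 so grid values reconstructed by repeated addition
never misclassify an exactly-equal weight). The giant component is the
largest connected set among the surviving edges — isolated nodes never
count. Evaluation stops at the first threshold where GC < `gc_min = 3`, and
**the stopping threshold's term is excluded from the integral** (the process
has terminated there); `include_stop_term = TRUE` re-includes it for
sensitivity analysis, since the choice is a convention, not a substance.

`noise_robustness()` draws **one SD per realization**, uniformly between
1/E and 10/E for a network with E edges, and perturbs every edge with
independent zero-mean Gaussian noise of that SD. The per-realization
reading (rather than per-edge redraw) matches an SD "ranging randomly
between" a minimum and maximum across realizations: each realization probes
one noise level, and the 500-realization mean integrates over levels.
Weights are deliberately not clipped to [-1, 1]: values pushed above 1
simply survive every threshold, and clipping would bias the perturbation
asymmetrically.

`shuffle_robustness()` selects `frac = 0.8` of the edges without
replacement, pairs them at random, and swaps the weights within each pair
(an odd leftover edge is selected but unswapped). On a fully connected
network, exchanging two edges can only mean exchanging their weights —
rewiring endpoints is vacuous when every pair is already connected — so the
weight multiset is preserved exactly. Swaps accumulate over `n_iter = 20`
iterations, with the PI recorded after each and averaged; at these defaults
each edge is selected at least once with probability 1 − 0.2^20, i.e. ≈ 1.
`shuffle_coverage()` replays exactly the selection-and-swap procedure
(percolation does not influence which edges are selected) to estimate
per-edge coverage by Monte Carlo.

Because longer texts mechanically produce larger networks and integrals,
`pi_subsampled()` recomputes the PI on repeated order-preserving
subsamples of the token stream at a common target length — the recommended
control when comparing conditions with unequal word counts.

## Edge-centric connectomics

`zscore()` standardizes each region with the **population** SD (divisor T).
This convention is load-bearing: it makes the time mean of every edge
co-fluctuation series equal the region pair's Pearson correlation exactly,
which the suite asserts to 1e-10. Trials are z-scored individually before
concatenation (`concatenate_trials()`), so each trial contributes with unit
variance regardless of drifts between trials. Two analysis paths exist for
the two writing conditions: per-condition concatenated series (the default
pipeline) and the condition-difference series
(`condition_difference()`, re-standardized downstream); both are first-class
because the published record does not pin one down, and neither is asserted
as canonical.

`edge_time_series()` enumerates edges in row-major upper-triangle order
(`edge_index()`), a fixed bijection used everywhere labels map back to node
pairs. Group analysis averages edge series across subjects
(`group_average()`) **before** clustering, producing one representative
matrix; per-subject clustering remains available by simply not averaging.

`cluster_edges()` applies k-means with squared Euclidean distance directly
to the E×T matrix for each k in 2..20. The iteration figure used by
reference implementations is read as the **per-restart iteration cap**
(default `max_iter = 5000`), with `restarts = 10` random initializations
per k as a separate parameter; all randomness flows from one integer seed.
Restarts that converge with an empty cluster are re-initialized (up to 20
attempts); inputs with fewer distinct edge rows than k are labeled by row
pattern with the surplus clusters left empty, with a message.

`overlap_entropy()` uses the natural logarithm with a log k normalizer (the
base cancels), defining 0·log 0 = 0, so the value lies in [0, 1] with 1
attained exactly when a node's N−1 edges spread uniformly over all k
communities. `community_similarity()` compares two nodes' label columns
over the N−2 positions excluding the two nodes themselves — their own
diagonal entries are empty, so those positions carry no label to compare;
`include_pair = TRUE` adds the always-matching mutual edge position
(denominator N−1) as a sensitivity variant. Per-node maps are averaged
within atlas networks, and `average_over_k()` reports the mean pattern
across the whole k range, since any single k is arbitrary. Statistical
comparisons across networks treat nodes as observations.

## The statistical battery

Spearman correlations use average ranks and the t approximation on
n − 2 − q degrees of freedom (q covariates); partial correlations correlate
the residuals of rank-on-rank regressions. The FDR family is exactly the
set of pairs passed in one `spearman_fdr()` call — family boundaries are an
analysis decision, so they are declared explicitly by the caller rather
than guessed.

`mediate()` standardizes x, m and y before fitting, so a, b, c′ are
standardized paths and total = direct + indirect holds to machine precision
by OLS algebra (asserted at 1e-10). The indirect-effect interval is the
2.5th/97.5th percentile of case-resampled replicates (default
`n_boot = 1000`). Bootstrap coverage of the population standardized
indirect effect is property-tested at ~95% over 200 seeded generator runs.

`kruskal_wallis_eps2()` delegates the tie-corrected H to the standard test
and reports ε² = H/(n−1); an all-tied sample, where the tie correction
degenerates, returns H = 0 by convention. `dscf_posthoc()` computes, per
pair, the tie-corrected Wilcoxon rank-sum z scaled by √2 and refers it to
the studentized range distribution with g groups and infinite degrees of
freedom — the large-sample approximation used by common implementations;
exact small-sample tables are out of scope. The statistic equals √2 times
the uncorrected normal-approximation z of the rank-sum test, which the
suite verifies directly.

Two identities connect printed statistics to effect sizes and are exposed
as helpers: `cohens_d_from_t()` (d = t/√n for paired designs) and
`epsilon_squared()` (ε² = H/(n−1)).

## What the synthetic data emulates — and what it does not

`make_lexicon()` plants orthonormal cluster means with isotropic Gaussian
perturbation and unit-normalized vectors: within-cluster cosines near 1,
cross-cluster near 0. Defaults (`within_noise_sd = 0.05`) keep clusters
tight enough that cluster membership, not noise, drives every text metric.
Real embedding spaces have anisotropic, heavy-tailed, frequency-confounded
structure; passing tests on this lexicon shows the metrics respond to
controlled semantic geometry, not that they are calibrated for any real
corpus.

`make_bold()` plants node-block covariance: each node follows its block's
standard-normal latent plus `noise_sd` Gaussian noise, and the two
conditions use shifted block assignments so condition-specific edge
structure exists. Unordered block-pair identity induces the ground-truth
edge partition (`edge_ground_truth()`) that clustering must recover. There
is no hemodynamic response, autocorrelation, scanner drift or motion — the
generator validates the algebra and the recovery pipeline, not fMRI
realism.

`make_mediation_table()` simulates x → m → y with a direct path and
Gaussian disturbances; note that with standardized fitting the recovered
indirect effect is a·b·σx/σy, which the recovery tests account for.

## Problem sizes and numerical choices

The suite runs at deliberately small scales chosen to exercise every code
path while keeping the full run under a minute on one core: networks of
4–12 nodes for oracle equivalence (exhaustive matrix-power component
search), 16–24 nodes / T = 300 for edge-community recovery (adjusted Rand
≥ 0.9 against planted truth), 200 seeded runs for bootstrap coverage, 50
seeds for the semantic-distance ordering property. Tolerances are 1e-12
for algebraic identities, 1e-10 for the edge-mean/Pearson identity (error
accumulates over T products), and interval assertions elsewhere.

## Known limitations

- The DSI layer semantics depend entirely on the injected embedder; the
  package ships only the deterministic lexicon-backed provider.
- Percolation recomputes components per threshold from scratch; for the
  word networks involved (tens to hundreds of nodes) this is inexpensive,
  but very large graphs would want an incremental union-find sweep.
- DSCF p values are asymptotic; with groups under ~8 observations they are
  approximate.
- The tokenizer's default punctuation class targets alphanumeric scripts;
  languages without whitespace boundaries need a `splitter` adapter.
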
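---
title: "Methods: dynamic network reconfiguration analysis for block-design task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic network reconfiguration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreconfig)
```

# The analysis in one paragraph

`netreconfig` studies how a brain's functional network reorganizes across
the blocks of an n-back working-memory task.  ROI time series are turned
into weighted functional connectivity matrices — per task condition for
static analyses, per task block for dynamic ones — using correlations
weighted by the hemodynamically effective part of each block.  Static
segregation is quantified by modularity `Q` maximized with a Louvain
optimizer and normalized against rewired null networks.  Dynamics are
captured by treating the 20 block-wise matrices as layers of a multilayer
network, maximizing the multilayer quality with a generalized Louvain
optimizer, and summarizing an ensemble of such partitions into a module
allegiance matrix from which system-level *recruitment* and *integration*
are computed and normalized against a label-permutation null.  Behavioral
sensitivity is scored as signal-detection d′.  Every stage can be run on
synthetic panels with planted community structure, so the whole chain is
testable against ground truth.

# Models and estimators

## HRF-weighted connectivity

Block-design BOLD responses lag the task by several seconds, so raw
within-block correlation mixes task and off-task signal.  We build a
per-volume weight vector by convolving the 0/1 block regressor with a
canonical double-gamma HRF and rectifying the result, then compute a
weighted Pearson correlation (weighted means and central moments) between
every ROI pair over the selected volumes.  Correlations are Fisher
z-transformed (`atanh`) and negative weights are set to zero, giving a
symmetric nonnegative matrix with zero diagonal — the graph on which all
community detection runs.

Numerical choices:

* the double-gamma kernel uses a response gamma of shape 6 (peaking
  ~5 s), an undershoot gamma of shape 16 scaled by 1/6, and 32 s support,
  all config-exposed (`hrf_*` parameters);
* the operation order is fixed as correlate → Fisher → rectify.  Since
  `atanh` is odd and monotone, rectifying before or after the transform
  is equivalent; fixing the order makes outputs bit-stable;
* correlations are capped at `1 - 1e-12` before the Fisher transform so
  numerically perfect correlations (e.g. duplicated ROIs) map to a large
  finite weight rather than `Inf`;
* per-block matrices recompute the HRF weights from that block's own
  boxcar rather than restricting condition-level weights, so every block
  is weighted by its own hemodynamic envelope;
* self-edges are zero, never one, so modularity never counts self-weight.

## Static modularity and its null

Modularity is
`Q = (1/2m) * sum_ij (A_ij - gamma * k_i k_j / 2m) * delta(g_i, g_j)`
with the Newman–Girvan configuration null and resolution `gamma = 1` by
default.  The optimizer is a two-phase greedy Louvain: randomized node
sweeps moving each node to the community of maximal positive gain
(tolerance `1e-10`; a node may also retreat to a fresh singleton), then
community aggregation, repeated to convergence.  Each restart begins from
a seeded *random initial labeling* rather than from singletons: the
deterministic singleton start funnels every restart into the same
attractor on some graphs, while random initializations let a
best-of-restarts ensemble reach optima that require crossing a
non-improving intermediate state.  With 100 restarts the optimizer
matches the exhaustively enumerated optimum on every random graph of
n ≤ 8 we test.  Ties between equally good moves are broken uniformly at
random within the seeded stream; best-of-restarts ties go to the lowest
run index.  Module labels are canonicalized by order of first appearance.

Because raw `Q` depends on total connection strength, each observed value
is divided by the mean `Q` of rewired null networks.  The null is a
Maslov–Sneppen double-edge swap on the nonzero-edge topology (10
successful swaps per edge targeted), with each weight riding on its
edge: degrees, the weight multiset and the total weight are preserved
exactly, while node strengths — and any community structure — are not.
Graphs that admit no legal swap (e.g. complete graphs) fall back, with a
warning, to shuffling weights over the fixed topology.  Null networks are
scored with the same restart protocol as observed ones.

## Multilayer communities

The 20 block-wise matrices form layers of a categorical multilayer
network: every layer pair is coupled on node identities with weight
`omega_same = 1` when the layers share a task condition and
`omega_diff = 0.5` otherwise.  All-pairs coupling is the only topology
that can realize a condition-dependent coupling rule in an interleaved
design, where same-condition blocks are never adjacent.  The quality
function applies the configuration null within layers only; interlayer
couplings enter as bare `+omega` terms, and the normalization constant
`2*mu` accumulates intra-layer strength plus each node's couplings to all
other layers.  The optimizer is the same greedy machinery applied to the
supra-modularity matrix over (node, layer) pairs, so module labels are
global across layers.  With one layer everything reduces exactly to the
static case, which the test suite checks to `1e-10`.

We retain the full ensemble of `n_opt` optimizations (not just the best)
because module allegiance is defined as an average over repeated
optimizations.

## Allegiance, recruitment, integration

`P[i, j]` is the fraction of (optimization × layer) instances in which
nodes i and j share a module; we use the co-assignment indicator equal to
1 when the nodes are together, the only reading consistent with a
"fraction of layers together" and a unit diagonal.  Recruitment of a
system is the mean of `P` over its node pairs *including* the diagonal
(the literal double sum); `include_diagonal = FALSE` exposes the
diagonal-excluded variant for sensitivity checks.  Integration is the
mean of `P` across two systems' node pairs.  Because both depend on
system sizes, each coefficient is divided by its mean over `n_perm`
random permutations of the whole ROI→system label vector (sizes
preserved exactly).  The permutation null is regenerated, seeded, for
every allegiance matrix analyzed.  On label-exchangeable random `P`
matrices the normalized recruitment averages 1 to within 0.05, and a
constant `P` normalizes to exactly 1 — no separate matrix-level transform
is applied or needed.

## Behavior: d′

Responses per subject × session × condition × modality are divided into
hits, misses, false alarms and correct rejections.  `d' = Z(H) - Z(F)`
with H and F the hit and false-alarm rates; rates of exactly 0 or 1 are
replaced by 0.01 / 0.99 (only exact extremes — this is a discrete
correction, not a continuous shrinkage), giving a ceiling of
`2 * qnorm(0.99) ≈ 4.653`.  Per-subject d′ is the mean over the two
modalities.  A group-level "percent improvement" is ambiguous between
the percent change of the group-mean d′ and the mean of per-subject
percent changes; `dprime_change()` defaults to the former and exposes the
latter behind `aggregate = "mean_of_changes"`, and reports both `delta`
and `pct_improvement` so neither aggregation hides the other.

## Contrasts

The statistical layer is deliberately simple: paired t-tests on
session-change scores within group, Welch two-sample t-tests on change
scores between groups, and Pearson correlations between network-measure
changes and d′ changes, with Bonferroni and Benjamini–Hochberg
adjustments per test family.  Nested multilevel models are out of scope
by design; the contrasts are the package's inferential surface.  A change
score that is identically zero yields the null contrast (t = 0, p = 1);
zero-variance nonzero changes are reported as NA rather than inventing a
statistic.

# The synthetic generator

`scenario_spec()` + `generate_panel()` emulate one scanning session of
the design under study: 20 alternating 1-back/2-back blocks, 15 volumes
per block at TR = 2 s, with per-block planted partitions.  Each block's
signal is drawn from a zero-mean Gaussian whose covariance has unit
diagonal, `rho_within` (default 0.6) between same-module nodes and
`rho_between` (default 0.05) otherwise — the minimal generative model
matching what a correlation-defined community analysis assumes — plus
independent Gaussian noise (`noise_sd = 1`).  Requiring
`0 <= rho_between <= rho_within < 1` keeps every planted covariance
positive definite.  Block boundaries are clean by default; `smear_hrf =
TRUE` convolves the latent signal with the canonical HRF so block
transitions bleed, giving the HRF-weighting stage something to correct.
A master seed derives one stream per block (plus one for the noise), so
panels are bit-reproducible and per-block structure can be varied without
disturbing other blocks.

Trial outcomes are Bernoulli: hits binomial over targets, false alarms
binomial over non-targets, with the default cell sizes of a session of 20
blocks × 12 trials at 25% targets (60 targets / 180 non-targets).
`simulate_trial_table()` ramps hit probability linearly across sessions
(0.7 → 0.9 by default) at constant false-alarm probability 0.05 —
chosen as a realistic training trajectory, not fitted to any particular
dataset.

What the generator does *not* emulate: voxel-level structure, realistic
fMRI noise spectra (drift, physiological cycles), motion, or
inter-subject variability in the HRF.  Passing tests on synthetic panels
therefore demonstrate correctness of the estimators under the generative
assumptions, not robustness to every artifact of real data — upstream
preprocessing is assumed done by standard tools.

# Validation design and problem sizes

The test suite validates every stage against independent oracles: direct
double-summation of the modularity formula, exhaustive enumeration of
all partitions (n ≤ 8), brute-force quadruple-sum evaluation of the
multilayer quality, the weighted-moment formula for weighted
correlation, `igraph::modularity` and `mclust::adjustedRandIndex` as
external cross-checks, and eigen-decomposition for planted covariances.

End-to-end recovery runs the study-scale scenario — 60 nodes, 4 equal
systems, `rho_within 0.6 / rho_between 0.05`, 20 blocks × 15 volumes —
over 20 seeds and requires the session-level partition to match the
planted one at ARI ≥ 0.9 in at least 95% of seeds, normalized modularity
above 1, and the stable system's normalized recruitment to exceed that of
a system whose halves merge into other modules on alternating blocks in
at least 95% of seeds.  For these checks we scale the protocol sizes to
20 Louvain restarts (10 for nulls, with 10 rewired nulls), 10 multilayer
optimizations and 100 label permutations; these sizes are the package's
validation choices — production analyses default to the conventional 100
restarts, 100 nulls, 100 optimizations and 1000 permutations, and the
recovery margins (typical ARI of 1.0, normalized modularity ≈ 3.7) leave
the conclusions insensitive to the difference.

# Known limitations

* The greedy optimizer is a local heuristic; random-initialization
  restarts empirically reach exhaustive optima on small graphs, but no
  global guarantee exists at 264 nodes.
* Rewiring preserves degrees and the weight multiset but not joint
  weight–degree structure; on very dense graphs the swap acceptance rate
  drops and the null approaches a weight shuffle.
* The permutation null for recruitment/integration treats ROIs as
  exchangeable; spatial autocorrelation of real parcellations is not
  modeled.
* d′ clamping at 0.01/0.99 bounds attainable sensitivity; ceiling
  effects in near-perfect performers are inherited from the estimator.
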
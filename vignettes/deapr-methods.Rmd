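---
title: "Pathway path scoring and rotation inference in deapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway path scoring and rotation inference in deapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deapr)
```

`deapr` tests each biological pathway for a coherently differentially
expressed *path* — a simple chain (or simple cycle) of regulatory edges —
rather than for diffuse differential expression of the pathway's gene set.
This vignette records the model, the numerical choices, and the design
decisions behind the implementation, in enough detail that a maintainer
can predict its behaviour on edge cases without reading the code.

## Data model

A pathway is a directed graph. Nodes are *sets* of protein identifiers
(curated pathway databases often lump near-identical variants into one
reaction participant); node identity is the sorted, semicolon-joined
member list, so two reactions naming the same protein set share a node.
Edges carry a type: catalysis (multiplier T = +1, the reactant promotes
the product) or inhibition (T = −1). Bidirectional relations are written
as two opposed directed edges; parallel edges with the same endpoints and
kind collapse to one, while opposed kinds on the same node pair are kept.

Expression enters as a per-protein signed summary E(x):

* **paired** (two-channel) data — every column is already a per-sample
  log-ratio, and E(x) is the row mean;
* **unpaired** (single-channel) data — E(x) = log(mean case) −
  log(mean control) in a configurable base (default 2). Group means must
  be strictly positive; data that can go non-positive should be shifted
  by the user or supplied as paired log-ratios. The method is agnostic to
  how the per-sample values were produced (microarray ratios, RNA-seq
  counts, spectral counts), provided positive values mean over-expression
  on a sensible scale.

A node's value is the sum of its members' E values after collapsing
members with *exactly* equal values to one contribution. Exact ties in
continuous summaries almost surely indicate data duplication (one
measurement mapped to several redundant identifiers), which is why the
collapse uses exact equality and applies within a single node only.
Proteins missing from the summary contribute 0 — the null-effect choice —
and the fraction of measured proteins is reported as a per-pathway
`coverage` diagnostic.

## The path score

A path n0 → n1 → ... → nL scores by the nested signed sum

    E(n0) + T1 ( E(n1) + T2 ( E(n2) + ... + TL E(nL) ) ),

so each node effectively contributes E(nk) times the cumulative product of
the edge multipliers before it: a down-regulated node downstream of an
inhibitory edge *raises* the score of that path. The implementation
evaluates all paths at once with a memoized recursion over edges. For an
edge e, the edges leaving its product node are its children. An edge with
no children scores `E(reactant) + T · E(product)` for both its max and min
branch; otherwise the candidates are `E(reactant) + T · max_rec` and
`E(reactant) + T · min_rec`, where max_rec / min_rec are the extremes of
the children's *returned* scores, and every return is clamped:
`max(max_score, 0)` and `min(min_score, 0)`. The pathway statistic is

    s* = max over edges of max( max_score, −min_score ),

with the achieving path reconstructed from stored argmax pointers. The
recursion is seeded at leaf edges (edges whose reactant has no incoming
edge) and then at any still-unvisited edges until the edge set is
exhausted, so cycles are covered.

Two consequences of the clamp deserve emphasis, because they define what
"path" means for this statistic:

* **Truncation drops the stopping node.** Clamping a child's return to
  zero abandons the continuation *including the child's reactant node*
  (which is the current edge's product). A path therefore ends with its
  final node counted only where the recursion bottoms out — at a sink, or
  where a cycle is cut. Between those points, the attainable values along
  a chain are the full nested sum and its zero-truncations.
* **The oracle must share these semantics.** `brute_force_score()`, the
  independent check used throughout the tests, enumerates sink-terminated
  simple paths (plus simple cycles) and evaluates each with the same
  backward, sign-dependent zero-clamp recurrence (`path_value()`). On
  acyclic graphs this matches the recursion exactly — a property the test
  suite asserts on 1000 random DAGs. A naive oracle that evaluates the
  *plain* nested sum over *every* simple path is not equivalent: on the
  chain A→B→C with E = (5, −0.5, 0.2) the plain best sub-path (A→B,
  score 4.5) differs from the statistic (5, the clamped evaluation that
  drops the suffix at B). The clamped statistic is never smaller than the
  plain one on the same sink-terminated paths, which the suite also
  checks.

**Cycles.** Edges already on the recursion stack are not re-entered, and
memoized values are reused even though cycle scores depend on entry order.
This makes the cyclic case a *heuristic*: reproducible (entry order is
fixed by sorted `edge_id`), but not guaranteed optimal, and it can close a
chain back onto its start node (the closing node's value counts at both
ends). Exactness is therefore claimed — and tested — on acyclic graphs
only; cyclic fixtures are covered by determinism and hand-worked examples
instead.

**Ties.** Children with equal scores are resolved toward the smallest
`edge_id`; equal-magnitude max/min branches resolve toward the max branch
of the earliest edge. With continuous expression values ties occur with
probability zero; the rules exist so that reruns and platforms agree
bit-for-bit.

**Degenerate inputs.** A pathway with no edges scores 0 with an empty
path and a `degenerate` flag; an all-zero summary scores 0 with an empty
path. A best path may in principle be a single node (its whole
continuation clamped away); the reconstruction then reports that node
alone.

## Rotation inference

Pathway scores are not comparable across pathways of different size and
shape, so each pathway is tested against its own null — a self-contained
test. The null distribution is built by random rotation: multiply every
protein's sample vector by one shared random orthogonal matrix Q,
recompute the statistic, repeat R times (default 1000), and report the
add-one Monte-Carlo p-value `p = (1 + #{s_i ≥ s*}) / (R + 1)`. The
add-one form never returns exactly zero and is the standard choice for
randomization tests; the plain proportion is available behind a flag.
Rotation rather than permutation because n is small (ten samples is
typical) and expression within a pathway is correlated: rotations draw
from a continuous group rather than n! rearrangements, and the same Q is
applied to all proteins, preserving their correlation. One rotation
stream serves all pathways of a dataset, so cross-pathway correlation of
p-values mirrors permutation practice; the per-pathway p-value is
unaffected by which other pathways are analysed.

Q is generated as the QR factor of a standard normal matrix with the
R-diagonal signs fixed positive — without the sign fix the raw QR factor
is *not* Haar (uniformly) distributed. Orthogonality is exact to 1e−10
and the test suite checks first and second moments of Qv against the
uniform-sphere values.

For the paired one-sample null (zero mean log-ratio) the raw sample
vectors are rotated. Nuisance structure — an overall mean for unpaired
designs, covariates, blocking factors — is handled by rotating only the
projection onto the nuisance model's residual space and re-adding the
fitted component. Because every summary used here depends on the data
only through weighted sample means, a rotation's effect is captured by a
single weight vector (`rowMeans(Y Qᵀ) = Y Qᵀ1/n`), and all R rotated
summaries are obtained in one matrix product; this is an exact identity,
not an approximation, and the suite verifies it against full-matrix
rotation. For unpaired data, rotated group means can stray non-positive
(the log summary is then undefined); this is reported as an error with
advice to shift or use ratios, rather than silently patched.

Across pathways, p-values become q-values by the Storey–Tibshirani
procedure: pi0 estimated on the lambda grid 0.05–0.95 with a df = 3
cubic-spline smoother evaluated at the largest lambda, floored at 1/m and
capped at 1. The smoother is unstable on short p-vectors, so below 50
tests the single-point estimate at lambda = 0.5 is used instead. Q-values
are the usual monotone minimum of `pi0 · m · p / rank`.

## The simulation model and the five fixtures

Simulated expression for protein i in sample j is

    y_ij = d_i (mu + g_i) + e_ij,

with d the fixture's per-protein indicator (+1 up-regulated, −1
down-regulated, 0 unaffected), mu ≥ 0 the pathway effect (mean absolute
expression of 'on' proteins), g_i ~ N(0, sigma2_g) drawn once per protein
and shared across replicate samples (a stable gene-specific deviation),
and e_ij ~ N(0, 1) per protein and sample. Values are treated as paired
log-ratios — the model produces signed, zero-centred nulls for which the
unpaired log-of-means summary would be undefined. Gene effects are not
clipped: large sigma2_g can push an individual protein's sign against d,
which is deliberate.

Five fixture pathways ship as plain data files (pathway TSV, effects
TSV, true-path TSV under `inst/extdata/fixtures`), so corrections are
reviewable diffs rather than code changes:

* `catalytic_string` — five nodes chained by catalysis, all d = +1; the
  true path is the whole string.
* `inhibitory_string` — five nodes chained by inhibition with
  alternating d = +1, −1, ..., the coherent pattern for an inhibitory
  cascade; true path the whole string.
* `branch_point` — seven nodes: a four-node 'on' route and a three-node
  unaffected route from the same source to the same sink.
* `mixed_regulation` — eight nodes mixing catalytic and inhibitory edges;
  the four-node true path is M1 → M2 ⊣ M3 ⊣ M4 with d = (+1, +1, −1, +1),
  plus an unaffected alternate route and side branch.
* `long_alternate_route` — fourteen proteins of which only four (the true
  path, source to sink) are 'on'; the other ten form a long unaffected
  alternate route with side chains. This fixture expresses the
  search-space-reduction claim: the method should point at 4 of 14
  proteins.

Only part of this geometry is pinned down by published constraints (an
inhibitory string exists; the long alternate route has 14 proteins and a
4-protein true path; at least one fixture mixes edge kinds); the
remaining topology is this package's reconstruction, chosen once by two
structural rules. First, every true path runs source to sink: because
truncation drops the stopping node and extension through any adjacent
noise node succeeds half the time under symmetric noise, a true path that
started or ended mid-graph could not be recovered *exactly* at any
realistic effect size — exact node-set recovery is only a fair target for
source-to-sink paths. Second, decoy routes differ from the true path by
at least two 'on'-node substitutions, so that beating the true path
requires a ≳2·mu noise excursion rather than a knife-edge single-node
race. Within those rules the shapes follow the standard repertoire of
pathway motifs (strings, a fork, mixed regulation, a long detour).

What the simulations do *not* emulate: real pathway topologies (hundreds
of nodes, dense cross-talk, cycles), heavy-tailed or heteroscedastic
noise, correlated noise between proteins, and partial measurement
(coverage < 1). Passing the bundled experiments therefore demonstrates
correctness of the machinery and calibration under the stated model, not
performance on any particular biological dataset. User-supplied fixtures
(`load_fixtures()`) accept arbitrary topologies and d assignments for
scenario studies on curated graphs.

## Benchmark harness and problem sizes

`run_power_experiment()`, `run_type1_experiment()`, and
`run_path_recovery()` iterate fixtures × parameter grids with
per-cell seeds derived from one base seed, so any cell is reproducible in
isolation. Power cells report the fraction of replicates with p ≤ alpha
and its binomial standard error. Statistics are plug-ins sharing one
matrix interface, so the four variants (`length_normalized`, `unsigned`,
`whole_pathway_sum`, `set_based`) and user statistics ride the same
rotation draws as the main score; externally computed p-value tables
(e.g. from GSEA or SPIA runs) can be compared side by side without
re-implementing those methods here.

The package's own validation uses desk-scale sizes chosen to keep the
full suite in the minutes range while leaving Monte-Carlo error well
below the margins being asserted: path recovery at 200 replicates per
fixture (mu = 1) and 100 (mu = 2); type-I error at 1000 null datasets per
fixture with R = 200 rotations and levels 0.01/0.05/0.10; null p-value
uniformity at 1000 datasets; oracle equivalence at 1000 random DAGs of up
to 10 nodes; power monotonicity on 3-point mu and n grids at 150
replicates and R = 150. The add-one p-value at R rotations is granular at
1/(R+1), which slightly *under*-shoots nominal rejection rates — at
R = 200 and alpha = 0.05 the exact null rejection probability is
10/201 ≈ 0.0498 — a conservative bias, never an anti-conservative one.

## Known limitations

* Cyclic pathway scores are order-dependent heuristics (documented
  above); bidirectional edges inherit the limitation.
* The recursion cannot end a path with its final node counted at a node
  that still has outgoing edges; the statistic is defined by the clamped
  recursion, and the bundled oracle mirrors exactly that definition.
* Unpaired mode requires strictly positive group means, both observed
  and under rotation.
* Storey's smoother needs a reasonable number of tests; below 50 the
  fixed-lambda fallback is coarser.
* GSEA and SPIA are not reimplemented here; comparative columns in the
  harness are populated only from externally supplied results.
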
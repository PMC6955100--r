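---
title: "Dendritic morphometry, 3D Sholl profiles and stereological counts with neuroarbor"
author: "neuroarbor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic morphometry, 3D Sholl profiles and stereological counts with neuroarbor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroarbor)
```

# Scope and data model

neuroarbor analyses digitally traced neurons — typically Golgi-stained
pyramidal cells reconstructed from high-resolution brain volumes — and
compares dendritic complexity between two cohorts (for example two age
groups of a disease-model mouse, per brain region). The substrate of every
computation is the `NeuronTree`: a rooted tree of 3D tracing points in
micrometres, with a single soma node as root and dendrite nodes connected
by parent links. Multi-point soma contours in input files are collapsed to
their centroid, because every downstream quantity (and in particular the
Sholl analysis) treats the soma as a single centre point. A per-node
radius is carried through input and output but ignored by all metrics,
which are skeleton-based.

Structural validation is deliberately a *diagnostic* operation
(`validateNeuronTree`) rather than only a constructor gate: it returns a
description of every violation (duplicate ids, multiple roots, dangling
parents, cycles, unreachable nodes) so that a malformed export can be
inspected. Constructors validate by default; methods assume a validated
object, as is usual for S4 containers.

Zero-length parent–child pairs — duplicated tracing points, which common
tracing tools export freely — are merged at construction with a warning.
They carry no geometric information and would otherwise produce degenerate
segments in the crossing counter. A node whose *parent pointer* is
malformed (for example a self-loop) is never "repaired" by this merge; it
is left for validation to report.

# Morphometrics

Three per-neuron scalars summarise complexity:

* **Total dendritic length** `L` (µm): the sum of Euclidean lengths of all
  parent-to-child segments. A soma-only tree has `L = 0`.
* **Terminal-dendrite count** `T`: the number of last-stage branches,
  counted as leaf nodes; the soma is excluded even when childless.
* **Spatial volume** `V` (µm³): the smallest cubic volume accommodating
  the neuron. "Cubic volume" admits two readings and the package supports
  both, always reporting which one produced a number: the default
  `"box"` mode is the axis-aligned bounding-box volume
  (Δx · Δy · Δz); `"cube"` mode is the literal cube, the largest
  coordinate extent cubed. We default to the box because regional volumes
  in this literature differ in all three dimensions; the mode is echoed in
  every output row rather than silently assumed.

`L` and `T` are invariant under translation, relabelling and rigid
rotation. The axis-aligned box volume is *not* rotation-invariant; the
test suite asserts this explicitly so the limitation is documented by a
failing counter-example rather than folklore. Branch order is defined
centripetally (stems are order 1), but only leaf counting is needed for
`T`, so orders are never materialised.

# 3D Sholl analysis

Profiles count intersections of the dendritic arbor with concentric
spheres centred at the soma, at radii Δr, 2Δr, … The default spacing is
Δr = 30 µm, the conventional increment for cortical pyramidal neurons.
Spheres — not planar circles — are used because the reconstructions are
three-dimensional; a 2D projected Sholl is out of scope. The outermost
shell defaults to the first multiple of Δr at or beyond the most distant
node, so every profile ends in a shell the arbor can still reach; cohort
comparisons zero-pad shorter profiles onto the longest grid.

## Exact crossing counting

For one segment the crossing count with a sphere is determined by the
quadratic |a + t(b−a) − c|² = r². Rather than counting roots on the
half-open interval [0, 1) literally, the implementation classifies the two
endpoints (a point is *inside* iff its distance from the centre is ≤ r)
and counts:

* one crossing when exactly one endpoint is inside;
* two crossings when both endpoints are outside and the interior closest
  approach dips strictly inside the sphere (the chord case);
* zero otherwise.

In exact arithmetic this is the same convention as half-open root
counting: a node lying exactly on a shell, shared by two consecutive
segments, is attributed to exactly one of them; a dendrite whose *tip*
merely reaches a shell does not cross it. Numerically, however, endpoint
classification is strictly more robust: it uses the same computed distance
for the shared node in both segments, so roundoff can never split one
crossing into two. This matters in practice — synthetic arbors place chain
nodes at exact step multiples, which land exactly on shells whenever the
step divides Δr. Tangential touches (closest approach exactly r) count
zero by default; they are measure-zero events, and this choice keeps the
exact counter equal to a sign-change count along a densely sampled path,
which is the independent oracle the suite compares against (segments
sampled every 0.01 µm, on hundreds of random arbors, with exact
agreement required).

Range aggregation (`aggregateRange`) snaps misaligned bounds *outward* to
shell multiples with a warning, so a requested band can only gain shells,
never silently lose one.

# Two-group statistics

Group summaries are mean ± SEM (sd with the n−1 denominator, over √n);
the unit of analysis is the neuron, which matches how per-metric sample
sizes are reported in regional morphometry studies (per-animal analyses
would need mixed models, an acknowledged non-goal). The two-sample t-test
defaults to Student's pooled-variance variant — the historical default of
common statistics software when only "t-test" is specified — with Welch
selectable; every report row names the variant. Degenerate zero-variance
samples follow a limiting convention (equal constants: t = 0, p = 1;
unequal constants: infinite t, p = 0) instead of erroring, because
identical synthetic cohorts are a meaningful null fixture.

Sholl comparisons run either per shell (one test per radius) or per
range. Range tests first reduce each *neuron* to a single summed count
over the range and test those sums — one value per neuron — which avoids
pseudo-replication across shells. No multiple-testing correction is
applied by default, mirroring common practice in this literature;
because per-shell testing is many comparisons, the function emits a note
with the comparison count and offers Holm adjustment behind a flag.

# Stereological density

Neuron density is estimated from pre-classified soma centroids counted in
cubic blocks placed systematically along the longest axis of the region:
by default five 300 µm cubes at 3 mm intervals, starting at a seeded
uniformly random offset within one spacing interval (the systematically
random, unbiased design). Membership is half-open on every axis
(origin ≤ x < origin + edge), so a centroid exactly on the face shared by
two adjacent blocks is counted once, in the higher block. The estimator is
total count over total block volume; both per-block counts and their mean
are reported, so either blocks or animals can serve as the replication
unit. Distinguishing large (neuronal) from small somata is perceptual
work done upstream; the module consumes already-classified centroid
lists. Unbiasedness is verified by Monte Carlo against homogeneous
Poisson fields: across 100 seeded random-start replicates the mean
estimate must sit within three standard errors of the generating
intensity.

# The synthetic cohort generator

Real tracing archives are large, manual and not redistributable, so
validation runs on a seeded stochastic generator that emulates their
*structure*: per-region cohorts of rooted dendritic trees with
controllable scale and planted between-group effects.

Growth is a bounded branching process. From the soma, `nStems` primary
dendrites leave in random directions; each branch is a straight polyline
of nodes `stepUm` apart whose total length is gamma-distributed
(right-skewed and strictly positive, with coefficient of variation
`branchLenCv`); at a branch end the process bifurcates with probability
`branchProb` while the centripetal order is below `maxOrder`; child
directions perturb the parent direction by a random polar angle up to
`angleSpreadDeg` about a random perpendicular axis. Closed forms follow
directly: the expected branch count per stem is Σₖ (2p)^(k−1) over orders
k = 1…m, so E[L] = nStems · Σₖ (2p)^(k−1) · meanBranchLen, and expected
terminals satisfy the leaf recursion Tₘ = 1, Tₖ = (1−p) + 2p·Tₖ₊₁.
`expectedMorphometry()` exposes these, and cohort means are tested
against them.

The defaults — 3 stems, mean branch 47 µm (CV 0.4), bifurcation
probability 0.8, order cap 3, 35° spread, 10 µm steps — were chosen once
to place the generator at the scale of traced cortical pyramidal neurons
(mean L ≈ 720 µm, T ≈ 9–10, box volume a few 10⁶ µm³, arbor radius
≈ 150–250 µm) while keeping per-neuron variability (length CV ≈ 0.27) low
enough that a planted 20 % mean-branch-length contrast is reliably
detectable at 60 neurons per group — the regime the package is meant to
validate. A high bifurcation probability with a low order cap yields the
same expected branch count as a lower probability with a deeper cap, but
with much less topological variance; we prefer it because the generator
is a test harness whose planted effects must be recoverable, not a
biophysical growth model.

Planted effects are multipliers on the baseline: `lengthEffect` scales
mean branch length (moving L and V), `branchProbEffect` scales the
bifurcation probability (moving T and arbor density). Because extra
branches of orders 2–3 live within roughly 180 µm of the soma under the
default geometry, a branching effect is a *proximal* Sholl effect: the
validation suite requires significant shells to appear within 30–150 µm
and not beyond 180 µm in the majority of replicates. Reproducibility uses
one master seed with per-neuron child seeds derived by counter, so a
cohort is identical regardless of generation order.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: apical/basal dendrite dichotomy, tropism toward
the pial surface, branch-length/order correlations, tortuous branch
paths (branches are straight between bifurcations), spines, and
per-animal clustering of neurons. Statistical calibration results
transfer to real tracings only insofar as per-neuron metrics are
approximately independent and their distributions not more pathological
than the generator's right-skewed ones.

# Numerical choices and degenerate inputs

* SWC output prints coordinates with `%.17g`, so write–read round-trips
  preserve doubles, and therefore all metrics, bit for bit.
* Soma-only trees: L = 0 and T = 0 (with a warning — a traced neuron is
  expected to carry dendrites); collinear or coplanar trees have box
  volume 0.
* Amira SpatialGraph edge point lists conventionally repeat the endpoint
  vertices; those duplicates are dropped on read. Only the ASCII dialect
  is supported; binary files are rejected naming the detected format.
  Disconnected graphs are an error listing the components, and the root
  vertex is the file's first vertex unless overridden.
* Filename metadata follows a configurable ordered-token convention
  (default `cohort_region_hemisphere_layer_index.swc`) with controlled
  vocabularies; unknown cohort or region tokens are errors, never
  guesses.
* Counting-block spacing shrinks with a warning when a region's long axis
  cannot hold the requested series; an extent smaller than one block is a
  configuration error.

# Validation problem sizes

The shipped suite checks: exact-vs-dense Sholl agreement on 200 random
arbors (plus 25 in the unit tests at coarser sampling); brute-force
metric oracles and bit-exact SWC round-trips on mixed random trees; null
calibration of the full generate-and-compare pipeline over 1000
replicates at 60 neurons per group, requiring each metric's rejection
rate inside the binomial 99 % interval [0.033, 0.069] around α = 0.05;
planted-effect recovery over 50 replicates (length effect: ≥ 90 %
detection with the planted direction; branching effect: proximal
localization in the majority); and density unbiasedness over 100
replicates. These sizes keep the whole suite in the few-minute range on a
single core while leaving the Monte-Carlo intervals tight enough to be
informative.

# Known limitations

Axons are not distinguished from dendrites beyond the SWC type label; all
non-soma nodes are treated as dendritic, matching archives that trace
dendrites only. Convex-hull volume, Sholl regression coefficients,
Strahler orders and branch-angle statistics are out of scope. The
comparison layer is strictly two-group; more groups need an omnibus
design the source studies did not use. Per-animal clustering is ignored
(neurons are the unit), which can understate uncertainty when few animals
contribute many neurons.

# A worked example

```{r example, eval = FALSE}
library(neuroarbor)

# simulate a two-cohort study with a planted 15% length deficit
dirIn <- tempfile(); dirOut <- tempfile()
runSimulation(list(
  cohortSpec("AD06", 60, region = "PFC"),
  cohortSpec("AD12", 60, region = "PFC", lengthEffect = 0.85)),
  dirIn, seed = 1)

res <- runAnalysis(dirIn, dirOut, shollRanges = list(c(30, 90)))
subset(res$comparisons, metric == "length")
```
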
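---
title: "Methods: network analysis of 3D SMLM point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network analysis of 3D SMLM point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmnet)
```

## The model

SMLM data are modeled as a 3D point cloud in nanometres: each acquisition
blink is a point, and each predicted molecule is a point after multi-blink
correction. Structure is quantified through *proximity graphs*: nodes are
points, and an undirected edge joins `i` and `j` whenever the Euclidean
distance `d_ij` is at most a threshold `T`. The weighted variant assigns
`w_ij = 1/d_ij`, so closer molecules interact more strongly. Because no
single `T` is privileged, analyses sweep `T` from 20 nm (the lateral
resolution limit) to 250 nm in 10 nm steps, and features are read as
functions of scale.

### Multi-blink correction

A fluorophore blinks several times; several fluorophores can decorate one
antibody; several antibodies can bind one molecule. All of these inflate
point counts within the resolution limit. The merge treats any group of
blinks within `T = 20` nm as unresolvable: repeatedly, the blink with the
most neighbors inside a 20 nm sphere absorbs them into a single point at
their (original-blink) average position, until the minimum pairwise
distance exceeds `T`. Neighbor counts are refreshed locally (within `2T` of
each new centroid) after every merge, so the processing order always
reflects the current configuration — the only order consistent with the
stated convergence criterion. Ties are broken by lowest point index, making
the output deterministic. Each merge strictly reduces the point count, so
termination is structural, and the output stores `merged_from`, the number
of raw blinks behind each localization (conserved: it sums to the input
count).

The merge is purely spatial. Frame indices are carried through but ignored:
temporal grouping would require photokinetic rate models that the supported
acquisitions do not provide. The threshold is isotropic even though axial
precision is roughly twice as poor as lateral; this is deliberate
faithfulness to the established procedure, and an anisotropic merge is a
known improvement left out of scope.

### ROI tiling

Cells (nominally 18×18×1 µm³) are divided into 3×3×1 µm³ tiles — 36 per
nominal cell — processed independently. Intervals are half-open and closed
at the lower edge; the global maximum faces are closed so boundary points
are never lost; empty tiles are retained and flagged. The tile size is much
larger than any structure of interest, so edge effects are accepted rather
than corrected. When no extent is given, the data's bounding box is rounded
outward to a multiple of the tile size.

### The ROI measure registry

Each ROI yields 32 measures × 24 thresholds = 768 features. The registry
(`measure_registry()`, version `roi-registry-1`) comprises:

* node statistics in both modes — mean/median (and SD/max) of degree,
  neighbor degree, and clustering coefficient: `uwAvgDeg`, `wAvgDeg`,
  `uwAvgNDeg`, `wAvgNDeg`, `uwAvgCC`, `wMedCC`, and relatives;
* graph-level measures — characteristic path length (mean shortest path
  over *connected* pairs; weighted paths use `d` as length), global
  efficiency, degree assortativity, Newman modularity `Q` and module count
  (both modes), component count and sizes, density, node count, and the
  isolated-node fraction.

Only six of these names are fixed by the published analysis; the remainder
of the registry is this package's explicit, versioned choice, selected to
cover the same node-statistic scheme plus the standard graph-level
repertoire, and swappable without touching the pipeline contracts.
Clustering coefficients use the closed-triangle definition, the Barrat
weight-averaged form for the weighted variant (the published analysis names
`wAvgCC`/`wMedCC` without defining the weighted form; Barrat is the common
convention), and 0 by convention for nodes of degree < 2. Degenerate
quantities (assortativity of a regular graph, path length of a singleton)
are `NA`-flagged and excluded from downstream statistics, never
NaN-propagated.

### Population statistics

Two populations of ROIs are compared per feature-threshold cell with the
two-sided Mann–Whitney test (exact for small untied samples, normal
approximation with tie correction otherwise). Replicate experiments are
combined by the entrywise L2-norm of their p-value matrices — a
deliberately conservative rule, since any single non-significant p-value
dominates the norm — and significance requires the combined value to fall
below `0.05 / 768` (Bonferroni over all feature-threshold pairs).

The feature ranking is validated by a random-forest classifier with
leave-one-cell-out cross-validation: all ROIs of one cell are held out,
prediction is per-ROI, and the cell label is the majority vote. The forest
(bagged CART, Gini splits, `sqrt(p)` feature sampling, 500 trees by
default) is implemented in-package because no forest library ships in the
target environment; at these data sizes that is no limitation.

### Noise filtering against a random-graph null

Background labeling is spatially random, so its network properties match a
random cloud. For each ROI, matched null clouds are drawn (X and Y uniform
over the ROI bounds; Z normal with the ROI's own mean and SD, reflecting
the bell-shaped axial acceptance of the instrument) and a node is retained
iff its degree at `T = 80` nm (the midpoint of the degree-discriminative
threshold band) exceeds `α × mean(δ_rand)`, with `α = 4`. The null mean is
pooled over 10 replicate draws to reduce its variance — the published
procedure used a single draw; pooling changes nothing at equilibrium and
costs little. Weighted neighbor degree (stricter; removes tiny clusters)
and weighted clustering coefficient are available alternatives. Isolated,
monomer-like nodes are removed by construction: the filter keeps clustered
signal only, which is its purpose.

### Blobs: segmentation and the 28-feature signature

Retained localizations are segmented by flat-kernel mean shift. Every point
seeds an iteration toward the mean of its neighbors within the bandwidth;
converged modes are de-duplicated in order of basin population (a mode
within one bandwidth of a stronger accepted mode is suppressed) and points
follow their own converged positions to the nearest accepted mode. The
bandwidth default is 80 nm — the analysis threshold; no bandwidth is stated
by the source procedure, and matching the network scale keeps one spatial
scale across stages. Blobs below 3 members go to an unassigned pool.

Each blob gets 28 features (`blob_descriptor_names()`, version
`blob-registry-1`): convex-hull volume and per-axis ranges (size);
min/mean/max/SD of member–centroid distance (hollowness — a hollow shell
has a large minimum, a filled body a minimum near zero); sphericity
`λ3/λ1`, fractional anisotropy, linearity `(λ1−λ2)/λ1`, planarity
`(λ2−λ3)/λ1` and further eigenvalue-derived shape terms (principal-axis
SDs, eigenvalue ratios, omnivariance, eigenentropy, surface variation,
radius of gyration); and network terms at 80 nm (node count = predicted
molecules, mean degree, mean clustering coefficient, characteristic path,
modularity `Q`, module count, component count). The 3D hull is computed by
an in-package incremental algorithm (verified against an independent
computational-geometry implementation on seeded fixtures); rank-deficient
blobs get volume 0 and a degeneracy flag rather than an error, since small
scaffolds are legitimate outputs. When a blob is disconnected at 80 nm,
modularity is computed on the largest component; `n_components > 1` flags
this in the descriptor.

The predicted molecule count is the post-merge node count — no
photophysical correction is applied, so it is an undercount at high
molecular densities, matching the known behavior of the procedure.

### Modularity

Newman's leading-eigenvector method: connected components are the initial
communities; each is recursively bisected along the sign pattern of the
leading eigenvector of its generalized modularity matrix
`B_ij = A_ij − k_i k_j / 2m` (strengths in weighted mode), refined by
greedy vertex flips, and a split is kept only while it increases `Q`.
Graphs with nodes but no edges have undefined `Q`; they are returned as
singleton modules with `Q = 0`, flagged. Tests hold the implementation to
at least 90% of the exhaustive-search maximum modularity on all small test
graphs and exact module counts on clique constructions. The dense
eigensolver is used up to 400 nodes, a shifted power iteration beyond.

### Blob identification

Blob descriptors are standardized per feature (the registry mixes nm, nm³
and dimensionless ratios; raw Euclidean distances would be
volume-dominated), then clustered by X-means: clusters are recursively
2-means-split while the split improves a BIC score, up to `k_max = 10`,
followed by a global refinement. The BIC uses a *diagonal* Gaussian model
(per-dimension variances); the textbook shared spherical variance
over-splits standardized data, which is anisotropic within clusters —
this substitution was made after observing tenfold over-splitting on
two-group synthetic data.

Groups from two populations are matched on the Euclidean distance between
group centroids: group `i` matches the closest counterpart if that
distance is below `β = 30`, otherwise it is reported unmatched — the
unmatched group is the interesting outcome, marking a structure class
present in only one population. The published formula wraps the distance
in a similarity `exp(−d)`, but its own matching rule (argmin, threshold 30)
only makes sense on the distance, and the figure caption confirms distance
semantics; the exponential similarity is reported as an audit column only.
Matching defaults to the raw feature space, where `β = 30` is calibrated;
a scaled-space mode exists. A built-in sensitivity mode repeats matching
without the molecule-count feature, which should not (and in tests does
not) change the matching.

Test-phase blobs are labeled by the nearest centroid in the model's scaled
space; exact ties go to the lowest group index and are flagged.

### Single-antibody calibration

Cover slips coated with labeled secondary antibodies give ground truth for
single-molecule blink clouds. The chain: mean-shift segmentation of *raw*
blinks (merging at 20 nm would collapse exactly the spread being measured),
removal of blobs that are both small (< 6 blinks) *and* tiny
(XY hull area ≤ 100 nm²) — a conjunction; failing one clause is not enough
— then a K-means (K = 2) split of the blob descriptors into single- vs
multi-antibody classes, labeling the class with the smaller mean XY area
"single". Per-blob spreads are the per-axis SDs of raw blink coordinates,
corrected for small-sample bias by the classic `c4` factor
(`E[S] = c4(n)·σ`); with geometric blink counts of mean 5, the raw sample
SD underestimates the precision by 6–12%, and an unbiased estimate is the
point of a calibration.

The K = 2 split presumes both classes are present. On a homogeneous
population K-means still returns a bisection — necessarily cutting through
the middle of one class — and the "single" class then under-reports the
spread. Several one-vs-two-class tests were evaluated (spherical and
diagonal BIC, Duda–Hart, Monte-Carlo-calibrated split strength against a
matched-covariance Gaussian null, projected mixture LRT); none separates a
homogeneous blob population from a genuinely mixed one on these
heavy-tailed, discrete-count features without an arbitrary threshold, so no
such test ships. Users analyzing data known to contain one class should
read the population-level spread, not the class-level one.

## The simulator and what a green test establishes

The generator emulates the acquisition chain of the calibration and
validation experiments: ground-truth structures (10 nm rod ≈ one antibody;
60 nm sphere ≈ one caveola; arbitrary custom point sets), epitopes placed
uniformly on the geometry — the sphere default density 0.012821 nm⁻² puts
exactly 145 epitopes on the 60 nm sphere in fixed-count mode, matching the
reported molecule count per caveola — each epitope labeled with probability
1.0 by default, each label displaced by a uniformly oriented linker of
uniform length up to 20 nm, each label emitting `k ≥ 1` blinks with
shifted-geometric multiplicity of mean 5, each blink Gaussian-displaced
with σ = 20 nm per lateral axis and 38 nm axially, and a uniform frame in
1…40,000. Rods default to a single label site: an antibody's several
fluorophores are absorbed into the blink-count distribution rather than
modeled as separate emitters, which is the simplest model whose only
consumer — the merge — cannot tell the difference.

What the simulator does **not** emulate: dye photokinetics (dark states,
bleaching), camera noise and PSF fitting, drift, multi-layer antibody
linkage (primary + secondary), or astigmatic Z-dependent precision. Green
end-to-end tests therefore establish that the pipeline recovers planted
geometry under the stated noise model — not that it reproduces every
artifact of a physical microscope.

One consequence is documented as a limitation: with 38 nm axial noise on a
30 nm-radius sphere, the simulated caveola's hollow core is *not*
resolvable end to end — a matched filled ball yields the same mean
distance-to-centroid (~72 nm) after merging. The hollow-vs-filled
discrimination of the descriptor itself is real and tested on clean
geometry (500-point shells vs balls separate by many sampling SDs in
minimum distance-to-centroid); the real-data hollowness signal additionally
rides on antibody linkage inflating the effective shell radius, which the
single-linker simulator deliberately does not reproduce.

## Numerical choices

* Weight cap: `w = 1/max(d, 1 nm)` — defensive only; post-merge data has no
  pairs below 20 nm.
* Characteristic path length on disconnected graphs averages over connected
  pairs only; single-node graphs report 0 and a degenerate flag.
* Mean shift: convergence tolerance 10⁻³ nm, 300 iterations max; modes
  closer than the numeric tolerance are pooled before suppression.
* Hull: epsilon `10⁻⁹ ×` the point-cloud extent for visibility tests;
  degenerate (collinear/coplanar) inputs return volume 0, flagged.
* Mann–Whitney: `stats::wilcox.test` conventions (exact for small untied
  samples); a constant pooled sample returns `p = 1`.
* All randomized stages take explicit integer seeds and restore the
  caller's RNG state; pipeline sub-seeds are derived deterministically from
  the master seed.
* Tiling boundary points: lower-closed half-open intervals, global maximum
  faces closed.

## Known limitations

* The merge cannot distinguish one multiply-blinking dye from several dyes
  on one antibody, and undercounts at high density; both are inherited from
  the procedure it reimplements.
* The 32- and 28-name registries beyond the printed names are this
  package's versioned choices; analyses depending on exact registry
  composition should pin the registry version recorded in every output.
* `β = 30` lives in the raw feature space and is not scale-free; use the
  scaled matching mode when populations were measured under different
  conditions.
* Mean shift can over- or under-segment when structures approach within one
  bandwidth, and the K = 2 calibration split is only meaningful on data
  containing both classes (see above).
* Per-ROI parallelism is process-based (`parallel::mclapply`); on Windows
  the pipeline falls back to serial execution.
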
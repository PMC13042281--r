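---
title: "Methods: vector fields, field lines, volumes and trends in 3D single-cell embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vector fields, field lines, volumes and trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellstream)
```

This vignette documents the models and numerical procedures behind
`cellstream`, the assumptions they rest on, the parameters that matter,
and the choices made where the design was genuinely open. It states no
empirical result that the package's tests and `scripts/acceptance.R` do
not themselves compute.

## Data model and assumptions

The central container, `cell_embedding`, holds per-cell 3D coordinates
(any low-dimensional embedding — 3-component UMAP, FLE, etc.), optional
3-component velocity vectors *already projected into that embedding*,
categorical/continuous annotations, one feature matrix per modality (RNA
expression, ADT epitope levels, ...), and optional clone barcodes.
Everything upstream — count preprocessing, velocity estimation, the
high-dimensional-to-3D projection — is assumed done by the usual
AnnData/Scanpy-style toolchains; this package consumes their outputs
(`h5ad`, `h5mu`, delimited text) and never re-estimates velocities.

Embeddings with more than three components are truncated to the first
three with a notice: the analysis is strictly 3D and component order in
the standard toolchains puts the leading structure first. Matrices are
densified on load; at the dataset scales this package targets (10⁴–10⁵
cells) dense storage is unproblematic and simplifies every downstream
step. Cell identity comes from the container's index strings, or is
synthesized as `cell_0..cell_{n-1}` for plain tables.

## Grid construction

`build_grid(coords, resolution, padding, scale)` lays a regular grid over
the (optionally padded) bounding box. `resolution` counts nodes along the
longest axis; a shorter axis of extent `e` gets
`ceil((resolution − 1) · e / e_max) + 1` nodes (floor 2), so voxels stay
near-cubic and integration is isotropic. A degenerate axis (zero extent)
gets exactly 2 nodes one unit apart, centred on the data. `scale` is a
scalar multiplier applied to stored node vectors whenever the field is
sampled — it stretches integration displacements and cone-glyph lengths
without moving nodes, which is how a "grid scale" control behaves in
interactive use.

## Velocity averaging

Per-cell velocities become node vectors in one of two ways, both exposed
because the averaging rule is a genuine modelling choice:

- **bin-mean** (default): each cell contributes to its nearest node; the
  node vector is the plain arithmetic mean. Transparent, fast, and
  exactly testable against a brute-force grouping.
- **gaussian-kernel**: every cell contributes to every node with weight
  `exp(−d²/2σ²)`; σ defaults to half the largest voxel edge, the widest
  kernel that still resolves single voxels. Occupancy counts cells within
  3σ. This trades locality for smoothness and is preferable on sparse
  datasets where many voxels hold few cells.

Empty nodes hold the zero vector. No post-hoc smoothing of node vectors is
applied: smoothing beyond the kernel option would be a second, hidden
bandwidth.

Between nodes the field is evaluated by trilinear interpolation of the 8
surrounding node vectors — exact for affine fields, which is the basis of
the sampling tests. Outside the grid the sampler returns the zero vector
plus an out-of-domain flag rather than extrapolating, so field lines
terminate cleanly at the hull instead of shooting off the manifold.

## Field-line integration

Trajectories solve `dx/dt = u(x)` from a seed (a cell position or grid
node) with either explicit Euler or classical RK4, under an
`integration_config` of `method`, `step_size` (pseudo-time units),
`n_steps`, and `diff_threshold`. Stopping rules, in order of evaluation
per step:

1. the tentative next point leaves the grid bounding box →
   `out-of-domain`, last in-domain point kept;
2. the step displaces less than `diff_threshold` (Euclidean) →
   `below-threshold`. A zero-displacement step always stops, whatever the
   threshold — otherwise a zero field with threshold 0 would append
   duplicate points forever;
3. `n_steps` steps taken → `completed`.

RK4's intermediate evaluations may probe outside the hull; they use the
sampler's zero-vector convention rather than aborting, matching the
sampler's contract. The displacement metric for `diff_threshold` is the
single-step Euclidean norm — the simplest monotone stopping statistic.
Integration is forward-time only by default; a negative `step_size` is
permitted for backward exploration.

On a grid whose node vectors are set exactly from `v(x) = −(x − c)`
(trilinear is exact for affine fields, so the sampled field equals the
ODE's right-hand side), the test suite verifies first-order error decay
for Euler and fourth-order for RK4 against the closed form
`c + (x₀ − c)e^{−t}`, and a 100-step RK4 endpoint within 10⁻⁶ of it.

Streamline bundles seed every grid node with occupancy ≥
`min_occupancy`; `density` ∈ (0, 1] integrates a seeded uniform
subsample of `floor(density · n_eligible)` nodes without replacement,
so identical seeds reproduce identical bundles. Streamlets are forward
prefixes (`streamlet_steps + 1` points) of full streamlines — prefixes
rather than centred windows because they preserve the flow directionality
that colour gradients encode.

## RBF feature volumes

`fit_rbf` interpolates scattered per-cell values with

  f(x) = Σᵢ wᵢ φ(‖x − xᵢ‖) + c₀ + c · x

solving the standard saddle-point system `[A + λI, P; Pᵀ, 0]` where
`A_ij = φ(r_ij)` and `P = [1 | x | y | z]`. Kernels: Gaussian
`exp(−(εr)²)`, linear `r`, quadratic `r² log r` (thin-plate family,
`φ(0) = 0` — the standard quadratic-order RBF; the pure `r²` reading is
not an interpolant, as `r²` kernels make the system rank-deficient), and
multiquadric `√(1 + (εr)²)`. Three numerical choices deserve note:

- **Degree-1 polynomial tail.** Required for well-posedness of the
  conditionally positive definite kernels and makes every kernel
  reproduce constant and affine fields exactly; with it, a feature that
  is a linear function of the coordinates is recovered to rounding error.
- **Kernel sign.** The linear and multiquadric families are conditionally
  *negative* definite; they enter the system negated (−r,
  −√(1 + (εr)²)), the convention under which the smoothing term λI is a
  true roughness penalty. Zero-smoothing predictions are unchanged, and
  the training residual is non-decreasing in λ (property-tested).
- **Conditioning.** ε defaults to the reciprocal mean pairwise distance
  of the fitted points. Duplicate coordinates are averaged before the
  solve (they make the λ = 0 system singular). Datasets beyond
  `max_points` (default 2000) are reduced by a seeded uniform subsample —
  the dense solve is O(n³) and 2000 points keep it in seconds. If the
  λ = 0 system is still numerically singular (a wide Gaussian on many
  points), a minimal ridge of `10⁻¹⁰ · max|A|` is added with a notice.

`evaluate_volume` evaluates the interpolant on every node of a grid built
independently of the vector-field grid (its own `resolution`), and clamps
to `value_range` if one is set — a display clamp applied after
evaluation; fitted values are never renormalised. Isosurface extraction
is delegated to the plotting layer (plotly `volume` traces); no marching
cubes is implemented.

## Trajectory trend analysis

`assign_segments` maps every cell within `radius` of the trajectory to
the segment `floor(nearest_point_index · n_segments / n_points)` (0-based
point index, clipped to the last segment). Segment identity thus derives
from the *step index* of the nearest trajectory point, not from
arclength: steps shrink where the flow slows, so step-indexed segments
give finer resolution exactly where the dynamics change — and the rule is
robust to uneven step displacement. Distance is measured to trajectory
points, not to interpolated line segments; at the step sizes in use the
polyline is dense relative to `radius`, so the difference is below the
noise floor of any real dataset.

`segment_means` averages each feature over the cells of each segment.
Empty segments are filled by linear interpolation from the flanking
non-empty segments (ends take the nearest non-empty value) so that
downstream clustering never sees missing columns. Normalisations:
`raw` (activity units), `zscore` (per-feature standardisation across
segments; constant features become all-zero rows rather than 0/0), and
`relative` (difference from the first segment — the "relative to the
trajectory start" reading of relative activity).

`cluster_trends` shortlists to the `top_n` features by variance (or
range) across segments — variance is the default statistic because the
heatmap should spend its rows on features that actually change — then
runs seeded k-means with at least 10 restarts (`stats::kmeans`,
deterministic under the seed). Defaults `k = 6`, `top_n = 200` match
typical heatmap capacities. `order_clusters` classifies each centroid as
up-regulated when its last value minus first value is ≥ 0 (the sign of
the net change; a fitted slope was considered and rejected as
less interpretable for non-monotone profiles), puts up-regulated
clusters first ordered by the segment position of the centroid maximum,
then down-regulated ordered by minimum position, ties by cluster index.
Rows inside a cluster sort by their own extremum position, giving the
staircase layout expected of trajectory heatmaps.

## Clonal queries

A "click" is modelled as a sphere (`select_sphere`, centre + radius;
default radius one voxel edge in the pipeline). `expand_clones` collects
the clone labels of the query cells (ignoring the missing-label sentinel,
which can never relate cells) and returns all other carriers of those
labels. The relation is symmetric and its expansion idempotent —
both property-tested. Each cell carries at most one barcode (the
Weinreb-style model); delimiter-joined multi-labels would be a
configuration extension. `clone_density_volume` interpolates the 0/1
membership indicator with the RBF machinery, giving a smooth
clonal-enrichment volume that remains readable when related cells are
rare or dispersed. Exports keep background cells with a `background`
class so global context is preserved.

## Synthetic fixtures: what they emulate, and what not

`make_field_dataset` samples cells uniformly in a box and sets velocities
from an analytic field plus isotropic Gaussian noise: `uniform` (pure
translation), `linear-sink` (contraction onto an attractor — the cleanest
stand-in for terminal differentiation, with a closed-form flow for
oracles), and `bifurcation` (+x flow diverging in ±z beyond a branch
point — a two-fate decision). `make_trend_features` plants per-cell
feature values as profiles of path progress (`s`, `1 − s`,
`4s(1 − s)`) plus noise; `make_clonal_dataset` assigns clones as
contiguous blobs (cells nearest a clone centre) with a dispersed minority
(15% reassigned) and a 10% unlabelled fraction, returning the ground-truth
membership table. Default noise (velocity sd 0.05 on unit-scale
velocities, feature sd 0.05 on unit-range profiles) is of the order of
the residual scatter seen in smoothed velocity embeddings — enough to
exercise averaging without burying the signal.

These fixtures are deterministic under their seeds, which is what makes
byte-level reproducibility testable. They do *not* emulate dropout
sparsity, embedding distortion, density gradients along lineages, batch
structure, or velocity-estimation artefacts. Passing tests therefore
demonstrate numerical and algorithmic correctness of the machinery, not
biological validity of any particular velocity estimate.

## Problem sizes and determinism

The test suite runs instances of up to 10³ cells × 50 features, 200-point
dense RBF oracles and 9³–13³ grids — sizes chosen so every brute-force
oracle (all-pairs distances, loop-built dense solves) stays exact and the
whole suite completes in well under a minute of compute per file; the
methods themselves scale to the full datasets the package targets.
All stochastic steps (fixture generation, streamline subsampling, RBF
subsampling, k-means restarts) consume explicit seeds and restore the
caller's RNG state, so `run_pipeline` reruns with the same `run_config`
produce byte-identical CSV outputs (checksummed in the run manifest).
HTML scenes are excluded from byte-exact guarantees — the widget
framework embeds nondeterministic element ids — which is why CSV/JSON
tables are the canonical outputs under test.

## Known limitations

- No adaptive step-size control; step count and size are fixed by
  configuration.
- No transition-probability (Markov) trajectory models; the projected
  field is integrated directly.
- No backward-plus-forward streamline stitching; integration is forward
  from each seed (a negative step size explores backward flow).
- Trend analysis offers no between-branch differential statistics.
- Volumes are evaluated on the full grid including regions far from any
  cell, where the interpolant is extrapolating its polynomial tail;
  interpret isosurfaces within the occupied hull.
- Loaders densify; datasets far beyond ~10⁵ cells × 10⁴ features may not
  fit in memory.
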
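---
title: "Quantifying K-fiber mesh ultrastructure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying K-fiber mesh ultrastructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfibermesh)
```

## The biological problem

Kinetochore fibers (K-fibers) are bundles of roughly 20–40 parallel
microtubules (MTs) that connect kinetochores to spindle poles and power
chromosome movement in mitosis. Electron tomography of orthogonal sections
through K-fibers shows that the MTs are not free rods: they are linked by a
network of electron-dense connectors — "the mesh" — in which a single
uninterrupted density can contact two, three or four MTs (bipolar, tripolar,
quadrupolar connectors). Perturbing a mesh component (overexpression of
TACC3, part of the TACC3–ch-TOG–clathrin MT crosslinker) tightens local MT
packing, enlarges mesh-mediated MT chains, and skews MT trajectories away
from parallel.

`kfibermesh` implements the full quantitative pipeline for this kind of
data: mesh segmentation from a density volume given per-MT label masks,
connector classification and volume statistics, cross-sectional packing
statistics, chain connectivity with rank-sum and randomization tests, and
trajectory-deviation analysis via rotational normalization. Because no
tomograms are publicly deposited for this problem, the package also contains
a first-class synthetic K-fiber generator that produces coordinate tables,
connector hypergraphs and rendered density volumes with known ground truth;
every analysis stage is validated against that ground truth.

## Coordinate and unit conventions

One convention is used everywhere: right-handed axes, lengths in nm, angles
in radians, `z` along the slab depth (the tomogram thickness, 28.8–66.4 nm
in the source imaging literature). Voxel grids are 0-based with half-open
voxels: a world coordinate maps to voxel index `floor(coord / voxel_nm)`,
and a voxel's center sits at `(index + 0.5) * voxel_nm`. Distance thresholds
("within r nm") are closed (`<=`) except for the trajectory radial fraction,
which is strict (`< 10 nm`) to match the convention of the quantity it
mirrors.

## The synthetic K-fiber generator

`fiber_spec()` collects every generator parameter; `simulate_fiber()` draws
one fiber. The generator is deliberately simple — it emulates the
*statistical structure* of tomogram-derived inputs, not the physics of
spindle assembly:

* **Packing.** MT centers are placed by sequential dart-throwing on a
  jittered hexagonal lattice scaled to `mean_nn_spacing_nm`. This
  reproduces near-regular packing plus doublet/triplet clusters without a
  physics simulation, and guarantees no two centers are closer than one MT
  diameter (25 nm). Positional jitter shrinks the median nearest-neighbour
  (NN) distance below the lattice constant because the nearest of ~6
  jittered neighbours is a minimum statistic; the shrinkage is ≈1.6 σ for
  jitter σ well below the spacing, so the lattice constant is scaled up by
  `1.6 * spacing_jitter_nm` and the empirical median lands on the requested
  spacing (verified in the test suite at ±σ for bundles of ≥ 20 MTs).
* **Trajectories.** Every MT direction is the bundle tilt axis perturbed by
  an isotropic tangent-plane Gaussian wobble (`wobble_polar_sd`; polar
  deviations then follow a Rayleigh law), and a planted `deviant_fraction`
  subset receives an extra polar deviation drawn uniformly in
  `(0, deviant_polar_max_rad]` at uniform azimuth. With both set to zero
  the fiber is perfectly parallel — the fixture for the normalization
  recovery tests.
* **Connectors.** Hyperedges over MTs with polarity 2/3/4 drawn from
  `connector_polarity_mix`; member sets are sampled uniformly from sets of
  MTs that are mutually within `proximity_bound_nm` (105 nm center-to-center,
  the longest inter-MT bridges observed in 2D EM), each distinct set used at
  most once. Setting the bound to `Inf` gives a *no-association* regime —
  connectors independent of position — used to check type-I error control of
  the downstream proximity test.
* **Rendering.** MTs become hollow tubes (outer Ø 25 nm, 5 nm wall),
  connectors become ~5 nm-thick struts joining member-MT surfaces (meeting
  at the member centroid for polarity ≥ 3), with fixed pre-noise densities
  background 0, wall 1, lumen 0.2, connector 0.8 — an arbitrary but fixed
  contrast chosen so that MT-anchored thresholding is exercised
  nontrivially (the threshold, the mean MT gray value ≈ 0.71 for these
  tubes, separates connectors from background but not trivially from
  walls). Additive Gaussian noise is applied last. Every planted connector
  is validated at render time: one 26-connected component, touching exactly
  its declared MTs, not adjacent to any other connector; a connector that
  cannot be placed is dropped from both the volume and the ground truth, so
  the planted truth is always realizable.

### Calibrated study regimes

`fiber_regime()` packages two parameter sets emulating the study's
conditions. Published summary statistics are used as *calibration
references* for the generator (they are not re-derivable from raw data,
which is not deposited):

| parameter | control | TACC3-OE | calibrated against |
|---|---|---|---|
| median NN spacing (nm) | 56.1 | 48.1 | printed medians (edge-to-edge 31.1 / 23.1) |
| deviant fraction | 0.10 | 0.40 | qualitative "minority vs frequent" deviants |
| deviant polar max (rad) | 0.15 | 0.35 | trajectory-deviation contrast |
| wobble σ (rad) | 0.096 | 0.118 | near-parallel fractions 0.39 / 0.18 at z = 100 nm |
| connectors per MT | 0.28 | 0.50 | chain-size maxima ~6 vs ~12 |
| bundle size (MTs) | 24 | 32 | "more MTs per fiber" after overexpression |

The wobble values invert the Rayleigh law: with the 10 nm radial cutoff on
the z = 100 nm plane corresponding to polar angle `atan(10/100) ≈ 0.0997`,
σ is chosen so the non-deviant population alone yields approximately the
printed near-parallel fraction. The connector rates were calibrated by
simulation against the printed chain-size maxima: rates much above 0.5 per
MT percolate the hypergraph and produce fiber-spanning chains unlike the
published histograms.

### What the generator does not emulate

No missing wedge, no contrast transfer function, no segmentation
imperfections in the MT masks, no MT curvature within the slab, no spatial
correlation in the noise, and no relationship between local packing density
and connector placement in the *control* regime (connectors prefer proximal
MTs in both regimes). Consequently, passing tests demonstrate correctness
of the measurement pipeline on data with known truth — not that the
pipeline would be robust to every artifact of real tomograms, nor that the
control regime reproduces the published *absence* of a chained-vs-single
proximity difference.

## Mesh segmentation

`segment_mesh()` implements MT-anchored thresholding: the threshold is the
mean gray value over MT-labeled voxels (the labels cover the whole tube,
wall plus lumen) scaled by `threshold_factor` (default 1, the stated rule
of the source method; the refinement the original authors may have applied
is not documented, so the factor is exposed). Mesh voxels are those at or
above threshold, outside the MT masks, in connected components that touch
at least one MT surface; unattached components are cytoplasmic density, not
mesh, and are discarded, as are components below `min_voxels` (default 8,
roughly one (5 nm)³ strut element at 2 nm voxels — the source method states
no minimum). A volume with constant density yields an empty mesh rather
than an all-mesh degenerate answer.

Numerical choices:

* **26-connectivity** for components and for surface contact. Thin ~5 nm
  struts sampled at 1–2 nm voxels break apart under 6-connectivity.
* Components are treated independently; no attempt is made to merge
  components across slab boundaries.
* Optional separable Gaussian pre-smoothing (`smooth_sd_voxels`, default
  off) for very noisy volumes; all defaults are used in the validation
  suite, where polarity recovery under noise at 20% of the wall density
  exceeds 95% at 1 nm voxels without smoothing.

`classify_connectors()` reports one connector per component touching ≥ 2
MTs (polarity = number of touched MTs, volume = voxel count × voxel³);
components touching exactly one MT are *pendants*, reported separately —
within a single slab a pendant is likely a connector whose partner MT lies
outside the section. `mesh_volume_ratios()` reports mesh volume relative to
MT walls (analytic hollow cylinders, outer Ø 25 nm, 5 nm wall), to
"filled-in" MTs (solid cylinders), and to the fiber volume as a percentage.
The fiber volume has no standard definition in the imaging literature; here
it is the convex hull of MT centers dilated by one MT radius (Minkowski
sum, `area + perimeter·r + πr²`), times the slab thickness, and the choice
is recorded in the returned object.

## Packing analysis

All operations work on MT center coordinates at the slab midplane.
`define_bundles()` partitions MTs into proximity components (center
distance ≤ 105 nm by default, i.e. an 80 nm edge-to-edge boundary) and
flags components of ≥ 10 MTs as K-fibers. `hull_area()` takes the convex
hull of the centers themselves (not dilated disks — the quantity mirrors a
hull "enclosing the coordinates"); density is reported in MTs/µm².
`nearest_neighbor_stats()` reports per-MT NN distances and converts the
median to edge-to-edge spacing by subtracting one MT diameter.
`neighbor_counts()` counts other MTs within a radius (closed threshold,
self excluded); the radius is always an explicit parameter because the
source analyses alternate between 105 nm and 100 nm conventions.
`packing_heatmap()` performs nearest-seed (Voronoi) interpolation of the
per-MT neighbour counts on a regular grid — exact at the seeds by
construction.

## Chain connectivity and the proximity test

`chains_from_connectors()` computes connected components of the connector
hypergraph's 2-section (via igraph; an independent union-find oracle backs
the tests). Chain-size histograms exclude singles. The chained-vs-single
analysis (`chained_vs_single_test()`) compares neighbour counts of chained
vs single MTs at each search radius (default 20–120 nm in 10 nm steps —
endpoints from the source analysis, the step its only free choice) with a
two-sample Wilcoxon–Mann–Whitney rank-sum test, pooling MTs across fibers
of a condition. `randomize_membership()` permutes the chained/single labels
(within fibers, preserving group sizes) and repeats the analysis — the
negative control that any proximity difference should vanish under label
exchange.

The rank-sum test itself (`rank_sum_test()`) uses exact enumeration over
all `choose(n, n1)` midrank assignments for total n ≤ 20 (two-sided
doubling rule, capped at 1) and a normal approximation with tie and
continuity corrections above; the source names the test but not the
variant, and neighbour counts are small tied integers for which the exact
path matters. `stats::wilcox.test` is used in the test suite as an
independent cross-check of both paths, never as the implementation.

## Trajectory analysis

Each MT's direction is the unit vector from its bottom (z = 0) to top
(z = slab) coordinate, translated to a common origin. The pipeline:

1. **Bundle center** — the 1-center (minimax) point of the cross-section,
   the solved objective of farthest-point clustering with k = 1, computed
   exactly as the smallest enclosing circle (incremental Welzl
   construction). Per-MT distances from this center feed the regressions.
2. **Zenith normalization** — exhaustive grid search over Euler rotations,
   α ∈ [0, 2π] about z applied first, then β ∈ [0, π/2] about y, γ = 0,
   at 1° (π/180) steps, minimizing the summed magnitude of the x–y
   projections of the rotated unit directions. Ties break towards the
   smallest β then α, so an already-normalized fiber maps to the identity.
   The z-then-y application order is the only functional reading of a
   z/y/x Euler triplet here: if the z-rotation acted last, the x–y
   projection objective would be independent of α and the search could
   never align a fiber tilted out of the x–z plane; with z first, the
   z-rotation carries the fiber azimuth into the x–z plane and the y-tilt
   lifts the axis to the zenith, so any tilt in range is recoverable (the
   test suite verifies recovery within one grid step over 100 random
   tilts). The "vector" reading of the projection objective (unit
   directions, not endpoints) is adopted; for equal-length slab segments
   both readings have the same argmin.
3. **Spherical angles** — θ = arccos(z/r) (deviation from the fiber axis),
   φ = atan2(y, x) (quadrant-aware; defined 0 at the zenith).
4. **Plane intersections** — each direction is extended from the origin to
   the plane z = 100 nm (an arbitrary but conventional height);
   the *near-parallel fraction* is the proportion landing at radius
   strictly < 10 nm. Directions with non-positive z (impossible for β-range
   bundles, possible for pathological inputs) are excluded and counted.
5. **Angle-vs-distance regression** — ordinary least squares of θ (and φ)
   on distance from the bundle center, with r², slope standard error and
   95% CI; a constant angle reports r² = 0 and zero distance variance is
   flagged degenerate rather than fit.

## Pipeline orchestration and reproducibility

`pipeline_config()` + `run_pipeline()` drive generation and all analysis
stages for any number of named conditions; `compare_conditions()` applies
the rank-sum test to per-fiber medians (median θ, median NN distance,
near-parallel fraction, MT count, hull area) across the first two
conditions. All randomness derives from one master seed through
`derive_seed()` (a deterministic string hash), so per-fiber results do not
depend on evaluation order and a re-run with the same configuration is
byte-identical, which the report writer supports by emitting canonical,
timestamp-free JSON. A failing fiber is logged in the report's `errors`
field without aborting the remaining fibers.

## Problem sizes

The validation suite and the analysis scripts run at desk scale: bundles
of 5–40 MTs; rendered volumes of ~1–4 million voxels at 1–2 nm voxels
(8–10 MT bundles); 100-instance oracle comparisons for the geometric
primitives; 500 simulations for the type-I error check; 100 seeded trials
for tilt recovery and for the two-regime directional contrast; 200
permutations for randomization controls. These sizes are stated here as the
package's reference configuration; all of them scale up linearly through
the same interfaces.

## Known limitations

* MT masks are inputs (as in the hand-rendered source workflow); the
  package does not trace MTs from raw density.
* Mesh statistics are computed per slab; no stitching across serial
  sections.
* The generator's connector volumes are emergent from strut geometry
  (~5 nm struts spanning 23–31 nm gaps, i.e. a few hundred to a couple of
  thousand nm³) and are intentionally *not* fitted to published per-class
  mean volumes, whose distributional form is unknown; mesh-to-MT volume
  ratios from synthetic volumes are correspondingly smaller than published
  tomogram values and serve as pipeline checks, not biological estimates.
* Alternative trajectory-deviation strategies (variance of angles, all-pairs
  comparison, reference-MT comparison) are not implemented; the
  rotational-normalization method was already selected as the most robust
  in the source analyses.
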
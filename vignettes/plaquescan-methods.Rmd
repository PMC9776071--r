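---
title: "Carotid plaque structural assessment: models, surrogates and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carotid plaque structural assessment: models, surrogates and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquescan)
```

## Scope and motivation

Carotid plaque vulnerability is poorly predicted by the degree of luminal
stenosis alone: patients within a narrow stenosis range (around 80%) can
differ widely in plaque composition, in time-averaged wall shear stress
(TAWSS), and in peak wall stress. `plaquescan` implements the image-analysis
side of a structural assessment workflow — multi-contrast segmentation,
tissue clustering, plaque morphology, material mapping — together with
transparent *surrogates* for the hemodynamic and structural solvers, and a
synthetic phantom generator that makes the entire chain testable without
patient data.

Two things the package deliberately does **not** do: it does not solve the
Navier–Stokes equations or a finite-element wall model (the surrogates below
stand in, and every output that depends on them is flagged
`surrogate = TRUE`), and it does not attempt to reproduce patient-specific
FSI magnitudes. The published three-patient comparison ratios are validated
purely as arithmetic on the packaged summary table (see
`validate_against_reference()`).

## The synthetic phantom

`make_bifurcation_geometry()` sweeps circular cross-sections along
straight-plus-arc axes: a CCA along +z, and an ICA/ECA pair leaving the apex
at ±22°/−28° with a short (0.3 mm) turn so the bifurcation has a crisp wedge,
as real carotids do. Lumen radii follow adult calibres (CCA 3.1 mm, distal
ICA 2.5 mm, ECA 2.0 mm); a compactly supported cosine carotid-sinus bulb (0.6 mm high,
4 mm half-width) widens the proximal ICA without touching the stenosis
throat. The stenosis is a cosine-tapered radius reduction
`r(s) = base(s) (1 − f·taper(s))` whose minimum is exactly
`r_ica (1 − f)`; the outer wall keeps the healthy calibre plus a 1.5 mm
expansive-remodelling bulge over the taper, so the band between lumen and
outer wall thickens into a plaque-bearing region of realistic volume
(tens of mm³).

Three built-in cases (`phantom_case(1:3)`) emulate the study conditions of a
three-patient comparison: stenosis 81 / 83 / 82 %, with case 1 a moderate
lipid pool and a small calcification, case 2 calcification-dominant with a
thick fibrous cap, and case 3 lipid-dominant. Inclusions are ellipsoids
oriented along the local vessel tangent and verified analytically to lie
strictly inside the wall band under the same swept-sphere metric the
rasterizer uses, so rasterization can never place an inclusion voxel outside
the wall.

Rendering (`render_contrasts()`) assigns each tissue a per-channel mean
(T1W/T2W/PDW/TOF) following standard multi-contrast plaque-MRI conventions —
TOF flow enhancement makes the lumen the brightest class, lipid is bright on
T1W/PDW and dark on T2W, calcification is dark on every channel but clearly
above the near-zero background — plus additive Gaussian noise (default SD
0.05 on a 0–1 intensity scale, i.e. wall SNR ≈ 11; Rician noise is a
non-goal). Flow is a two-bump template (systolic peak plus dicrotic bump)
affinely scaled so the trapezoidal cycle mean and the maximum hit `q_mean`
and `q_peak` exactly on the 40-frame grid; pressure is the affine map of the
flow onto [diastolic, systolic].

What the phantom does *not* emulate: bias fields, motion, partial-volume
mixing, eccentric or ulcerated lumens (eccentricity is available but off by
default), and vessel wall anisotropy. Passing tests therefore demonstrate
algorithmic correctness on clean geometry, not clinical-grade robustness.

## Centerlines

Costs are `1/(ε + normalized intensity)` on the TOF channel with ε = 0.05,
so bright voxels are cheap and every cost is bounded by 1/ε. Dijkstra runs
on the 26-connected grid with metric edge weights (mean endpoint cost ×
Euclidean step) and lexicographic tie-breaking; both branch paths are read
off a single shortest-path tree rooted at the CCA seed, so they share a
prefix by construction, and the apex is their last common point.

A uniformly bright lumen makes in-lumen costs nearly tied, so raw
least-cost paths cut corners and wander under noise. The pipeline therefore
enables two config-exposed refinements: Gaussian pre-smoothing (σ = 1 voxel)
and a *medialness* weight — intensity multiplied by the saturating
distance-to-boundary factor `d/(d+1 mm)` of the thresholded bright region —
which pulls the path onto the vessel axis (on noise-free phantoms the path
stays within ~0.2 mm of the true axis). Apex recovery carries an intrinsic
distal bias of roughly 0.5–1 mm: the medial ridges of two merging tubes
stay indistinguishable until the branch axes separate by about a voxel.
At the 0.5 mm default test resolution this is within two voxels.

## Segmentation

Lumen contours evolve per axial slice from circles seeded on the centerline
(`r0` must be below the narrowest lumen; default 0.4 mm) under a classical
explicit snake: tension α, rigidity β, gradient-magnitude image force κ, and
an outward balloon pressure that lets the contour inflate to the boundary.
Iteration stops when the largest vertex move falls below 0.01 mm; contours
are periodically resampled to uniform vertex spacing and repaired
star-shapewise if they self-intersect.

The outer wall uses the circle-model polar formulation: rays from the lumen
centroid, radial samples from just outside the lumen to `r_max_offset`
(default 5 mm in the pipeline — it must exceed the thickest plaque band),
node cost equal to the outward radial gradient (so falling wall→background
edges are cheapest; the polarity is exposed because the lumen-side edge is
rising), plus λ|Δr| smoothness with |Δr| ≤ 2 radial samples per ray. The
cyclic optimum is found exactly by fixing the first ray's radius over all
choices and running dynamic programming; a min-plus matrix-product oracle
(and literal enumeration at small sizes) verifies exactness in the tests.
As λ → ∞ the solution degenerates to the best single circle, which is the
useful limiting behaviour of the circle model.

## Tissue clustering

Wall-band voxels (between lumen and outer wall) are z-scored per channel
and clustered with Lloyd's k-means: k-means++ seeding, best of 10 restarts,
inertia asserted non-increasing at every iteration, empty clusters re-seeded
at the farthest point, fixed seed 17. The implementation is in-package
because these reproducibility guarantees (and the seeding/empty-cluster
rules) are part of the contract; `stats::kmeans` serves as an independent
cross-check in the tests.

Centroids are mapped to named tissues by nearest z-scored signature.
`kmeans_cluster()` defaults to k = 4 (wall, lipid, calcification, mixed);
the pipeline raises this to k = 5 and, when the band comes from
segmentation rather than ground truth, adds `background` to the candidate
classes and then splits dark voxels individually between background and
calcification — both are hypointense everywhere and routinely share a
cluster, but at the default noise level their signatures are ~4.8σ apart
per voxel, so the per-voxel split is essentially error-free. Finally,
single-voxel inclusion speckle (fewer than two same-class 6-neighbours) is
folded back into wall tissue, because one mislabeled voxel adjacent to the
lumen would otherwise destroy the minimum-distance cap estimate.

## Morphology

Component volumes are voxel counts × voxel volume. The thinnest fibrous cap
is the exact 3-D minimum distance between the lumen surface and the lipid
surface (Felzenszwalb distance transform sampled on lipid-surface voxels;
all-pairs brute force reproduces it in tests); a cap at or below one voxel
spacing is flagged as a breach, and "no lipid" yields an absent result, not
an error. The 3-D minimum is stricter than the per-slice 2-D convention
some groups use.

NASCET stenosis is `100 (1 − d_min/d_distal)` with the distal reference
taken as the mean diameter over the last 5 mm of the ICA profile. Radii are
measured by casting 32 rays per section on the trilinearly interpolated
lumen mask with bisection to the 0.5 level, after recentring each section
point by three chord-midpoint iterations (for a circular section the mean of
opposite-ray chord midpoints moves halfway to the true centre each
iteration). The mean ray length is used rather than the inscribed-circle
minimum: for the phantom's circular sections it is unbiased, whereas the
minimum is biased low by voxel noise. The centerline is resampled to 0.15 mm
before profiling so the 5-sample smoothing window spans well under a
millimetre and does not flatten the throat minimum. With these choices the
81/82/83 % cases round-trip within ±2 points at 0.25 mm; a 90 % stenosis
(throat diameter 0.5 mm) needs a proportionally finer grid (0.2 mm) for the
same accuracy, which is a statement about voxelization, not the estimator.

## Material mapping

Tissue elastic constants are the standard linear-elastic set: arterial
tissue 0.6 MPa, calcification 10 MPa, lipid 0.02 MPa, Poisson ratio 0.48
throughout. Mapping is centroid-based (the label at the element centroid's
voxel), which makes it deterministic and idempotent; lumen/background
centroids fall back to arterial tissue with a reported count. The
transitional region between components is produced by inverse-distance
weighting of log-moduli within a 0.6 mm radius — log space because the
500-fold lipid–calcification contrast would otherwise dominate any linear
average; the result is always bounded by the input range (geometric-mean
bound) and radius 0 is the identity.

Wall meshing is a structured Kuhn subdivision: the wall band is voxelized at
pitch `target_edge / 1.2` and each occupied cell is split into six
positively oriented tetrahedra sharing the cell diagonal. Edge lengths come
in ratios 1 : √2 : √3 of the pitch, so the median edge tracks the requested
0.3 mm element-size convention, each cell is filled exactly (mesh volume =
voxelized band volume), and no external tetrahedralization library is
needed. The cost is boundary staircasing, acceptable because the mesh only
carries material fields, not a solve.

## Hemodynamic and wall-stress surrogates

The CFD participant is replaced by a quasi-steady Poiseuille surrogate:
`τ(s,t) = 4 μ Q_branch(t) / (π r(s)³)` along the local tangent, with blood
viscosity μ = 0.00345 Pa·s and the inlet flow split between ICA and ECA in
proportion to the fourth power of the distal branch radii (the
parallel-resistance rule for uniform branches; splitting by full integrated
resistance would starve an 81 %-stenosed ICA almost completely, which is not
how the cerebral circulation autoregulates). Descriptors follow the standard
definitions: TAWSS is the cycle mean of |τ| by trapezoidal quadrature on the
40-frame grid (which includes both cycle endpoints, making the quadrature
periodic-consistent); OSI is the vector form ½(1 − |∫τ dt| / ∫|τ| dt),
clamped to [0, 0.5], with zero-shear points masked as undefined rather than
set to 0 — the scalar form in which the integrals are written with bare τ is
ambiguous as typeset and universally read this way. The peak-systole map
evaluates |τ| at the earliest flow maximum. Note the surrogate's direction
never reverses, so its own OSI is identically 0; OSI behaviour is exercised
on synthetic oscillatory fields, and externally computed WSS tables can be
read back (`read_wss_field()`) and pushed through all descriptors unchanged.

Wall stress uses the thin-wall Laplace hoop stress `σ = p r / h` (kPa), a
labelled stand-in for the finite-element maximum principal stress. It does
not reproduce patient kPa magnitudes and, because `h` grows where plaque
thickens, it is lowest exactly where a thin-cap FEA would peak — the
surrogate validates the ROI machinery (peak-plane location, 13 mm window,
mean ± SD, max), not stress physiology.

ROI statistics are unweighted point statistics (the violin-style
distributions the field reports), with area weighting deliberately off by
default; the TAWSS ROI is the apex-anchored 17 mm of the ICA and the stress
ROI a 13 mm window centred on the peak-stress plane (earliest plane on
ties).

## Reporting and validation

`run_pipeline()` chains the stages deterministically (every random step is
seeded from the case seed), caches intermediates keyed by a hash of the
configuration, collects warnings, and stamps every report with units,
package version and surrogate flags. `compare_patients()` produces all
ordered pairwise fold ratios and percent differences (percent differences
relative to the smaller-valued case).

`validate_against_reference()` recomputes the eight published cross-case
comparisons from the packaged three-patient summary table. Published ratios
mix rounding and truncation in their final digit (e.g. 77.38/3.44 = 22.49
is printed 22.4, while 14.62/5.45 = 2.68 is printed 2.7), so a comparison
passes when it agrees with the printed value within one unit in the last
printed decimal — the tightest criterion consistent with both conventions.

## Problem sizes

Unit tests run phantoms at 0.25–0.5 mm spacing over an ~18 × 50 mm field of
view (10⁵–10⁶ voxels); the full-pipeline fixtures use 0.35 mm and the
acceptance script 0.3 mm, sizes at which every stage completes in seconds to
a couple of minutes on a single core. These are the package's reference
problem sizes; all spacings are config-exposed.

## Known limitations

* The apex estimate is biased ~0.5–1 mm distally by construction of the
  "last common path point" definition.
* Slices are axial (image z), not centerline-orthogonal; strongly curved
  vessels would need reformatting, which is out of scope.
* Sub-voxel throats (stenosis ≳ 90 % at 0.25 mm) are not gradable within
  ±2 NASCET points without finer sampling.
* Both biomechanical surrogates are deliberately simple and clearly
  flagged; only their descriptor/ROI/comparison machinery is validated
  against published values.
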
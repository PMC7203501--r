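---
title: "Bifurcation morphometry and risk scoring: models, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifurcation morphometry and risk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pabifurc` measures the main pulmonary artery (MPA) bifurcation on a
triangle surface and turns the measurements into a sparse linear risk
score for short-term adverse events in non-high-risk acute pulmonary
embolism. This vignette is the package's methods account: the geometric
and statistical models, the tunable parameters and why their defaults are
what they are, the numerical choices, and what the synthetic test world
does — and does not — establish.

## The measurement model

The vessel is represented as a manifold triangle mesh in millimetres,
open only at the three vessel ends (MPA inlet, RPA and LPA outlets). All
metrics are defined on planes perpendicular to the vessel centerline:

* **CSA** — the shoelace area of the closed plane-mesh intersection loop.
* **Perimeter** — the summed edge length of that loop.
* **Hydraulic diameter** — $D_h = 4A/P$. For a circle it equals the true
  diameter; any non-circular deformation lowers it below the
  equivalent-area circular diameter $\sqrt{4A/\pi}$, which is what makes
  it a deformation marker under pulmonary hypertension.
* **Maximal diameter** — the maximum Feret diameter (largest vertex-pair
  distance, computed on the convex hull). "Maximal diameter" is not given
  a formal definition in the clinical literature we mirror; Feret is the
  standard reading and reduces to the true diameter on circles.
* **Bifurcation triangle** — the three plane center points (MPA outlet,
  RPA inlet, LPA inlet section centroids) span a 3-D triangle; its area
  (100 mm²) and the interior angle at the MPA-outlet vertex (the vertex
  "toward the MPA"; the alternative reading — the angle between the
  triangle plane and the trunk axis — was considered and rejected as the
  less literal one) are reported.
* **Bifurcation volume** — the lumen volume bounded proximally by the MPA
  outlet plane and distally by the two branch inlet planes: the surface
  is clipped by the three halfspaces (clips self-orient so the kept side
  contains the carina), the cuts are capped with planar fans, and the
  volume follows from the divergence theorem.
* **Dilation flag** — trunk diameter strictly greater than 29 mm,
  measured as the maximal diameter of an axial ($z$-normal) section at
  the trunk midpoint. Clinically this is a CT transverse-plane
  measurement; a free-floating mesh has no patient axes, so the
  generator's world axis stands in. It is the one metric that is
  deliberately not rotation-covariant.

Reported units are the clinical scaled ones — areas in 100 mm², lengths
in 10 mm, volumes in 1000 mm³ — because the published score weights
assume them. Internally everything is millimetres; conversion happens
only at the reporting boundary (`scale_area()`, `scale_length()`,
`scale_volume()`).

### Centerline and plane placement

The centerline is tracked by centroid marching: seed at the area centroid
of an opening rim, step 1 mm along the current tangent, re-slice
perpendicular to it, re-center on the section centroid. The tangent is
exponentially smoothed (weight 0.4 on the new direction) and frozen for
the first three steps, where even a fraction of a degree of tilt would
make the slicing plane cross the wide inlet rim. Full skeletonization was
rejected as unnecessary for single-bifurcation tubular topologies; the
marcher is deterministic and validated against the generator's analytic
centerlines (sub-0.2 mm Hausdorff in the tests).

Carina detection drives plane placement. A station is a *clean tube cut*
when the section is a single closed loop and stays round about its
centroid: maximum radius at most 1.4 × minimum radius. The MPA outlet is
the most distal clean trunk station, the branch inlets the most proximal
clean branch stations, refined by bisection to 0.1 mm. A plain
single-loop/multi-loop transition cannot define these stations: along a
branch the slicing plane cuts the neighbouring lumen almost
longitudinally (one merged loop, never two), and along the trunk the
two-loop transition only occurs distal of the branch-inlet stations,
which would make the three planes bound an empty region. The roundness
bound 1.4 must exceed the inverse of the lowest supported trunk
ellipticity (1/0.72) with headroom for mesh discretization while still
excluding the carina blend; the same rule, evaluated on the exact
implicit field, defines the generator's ground-truth stations, so the
two paths are comparable (the tests require agreement within 2 mm). The
centerline marcher itself stops at a stricter bound (1.25) because
section centroids drift off-axis inside the early blend; plane placement
then scans forward to the 1.4 transition.

## The synthetic geometry

`bifurcation_spec()` describes an idealized bifurcation: a tapered
elliptical trunk along $+z$ and two straight circular branches in the
$xz$-plane, blended by a polynomial smooth-minimum of their signed
distance fields with a fillet radius (default 1 mm — the blend is present
so plane-placement heuristics face a realistic carina, but small enough
that ground-truth stations stay near the analytic split). The surface is
extracted by marching tetrahedra on a Freudenthal-decomposed grid (a
translation-consistent 6-tetrahedra cube split, so the mesh is watertight
and manifold by construction, with combinatorial outward orientation);
the walls are extended past the end planes in the field and the openings
are then cut by exact mesh clipping, leaving exactly planar, analytic
rims. `mesh_resolution` (segments per ring, default 64, minimum 16) maps
to the grid spacing $h = 2\pi r_{\min}/\text{resolution}$; at 64 the
cylinder-CSA error is below 0.5% and the enclosed-volume error below 2%,
and both shrink with refinement.

Defaults approximate an adult MPA with the calibre of the
adverse-event-free reference group: trunk semi-axis 15.6→16.3 mm over
50 mm, ellipticity 0.9, branch radii 12.6/12.2 mm, lengths 35 mm, angles
50°/45° off the trunk axis. Specs whose branch tubes have not separated
by their end planes are rejected as a geometric conflict. Generation is
fully deterministic; the spec's seed is recorded for provenance.

Ground truth is computed from the implicit field, never from the mesh:
closed forms away from the blend (ellipse sections, quadrature ellipse
perimeter), radial contouring of the exact field at the blend-zone
stations, and fine voxel counting (0.4 mm) for the inter-plane volume.
That keeps the oracle independent of the triangulation it checks.

The synthetic geometry reproduces the *measurement problem*, not the
patient distribution: its bifurcation triangle is more compact (angle
near 90°, area near 0.6 × 100 mm²) than the clinical ranges (angles above
130°), because real branch-inlet planes sit further from the carina than
any single-bifurcation tube model puts them. Geometric tests therefore
check mesh-vs-ground-truth consistency, not clinical ranges.

## The synthetic cohort

`cohort_spec()` states the cohort world: 296 patients, 34 adverse events,
group-conditional normal features truncated at zero with the reference
group means/SDs in scaled units, per-group dilation rates (13/34 vs
31/262), sex and age distributions, and a random 50:50
training/validation split. Truncation matters: naive zero-truncation at
mean 1.32 and SD 0.95 (the positive-group bifurcation area) would inflate
the realized mean by almost 0.12, so the generator moment-matches the
pre-truncation parameters (closed-form truncated-normal moments,
Nelder-Mead) and the realized group moments equal the configured ones.
Features are independent within group unless a correlation matrix is
supplied (Gaussian copula; the reference study reports only marginals —
the independence default is a stated simplification, not an estimate).
Redrawn truncated values lose the copula correlation, which is negligible
at the default SDs.

The cohort emits the 15 continuous morphometric parameters (4 CSA, 4
hydraulic, 4 maximal diameters, bifurcation area/angle/volume) plus age,
sex and the dilation flag — the reference table's set; the source
material is internally inconsistent about the model's feature count (21
vs 16 are both printed), and this package resolves it to the tabulated
set.

## Risk model

The LASSO-logistic path and the cross-validated binomial deviance are
computed by glmnet — the reference implementation whose conventions the
model mirrors: internal standardization to unit variance (selection must
not depend on feature scales), coefficients back-transformed to the
original scaled units, a 100-point log-spaced lambda grid from the
all-zero-slopes maximum down to $10^{-3}$ of it. Fold assignment is
event-stratified and seeded in this package (at 11.5% prevalence,
unstratified folds regularly lose all events), and the min/1-SE lambda
scan is implemented and tested independently against glmnet's own —
keeping the dual route between implementation and oracle.

The published three-term score ships as `paper_formula()`, a fixture with
no intercept: the six published worked examples verify exactly without
one, so none is carried. Refitting on synthetic cohorts is *not* expected
to reproduce the published coefficients (different data); only the
fixture reproduces the worked-example scores, and the acceptance report
is built on it.

## Evaluation

AUC uses midranks (tie-aware Mann–Whitney); its variance and the paired
test use the DeLong structural components, with Wald 95% intervals
truncated to [0, 1]. The Youden cut-off maximizes sensitivity +
specificity − 1 over observed thresholds, ties broken toward higher
specificity (unstated in the source; a deterministic documented choice).
The cross-validated precision-recall summary is the unweighted mean of
per-fold average precision (step-interpolated), the most literal reading
of "PR curve with 10-fold cross-validation"; folds without events are
skipped with a warning and counted. Decision curves need probabilities:
a raw linear score is mapped through a one-variable logistic
recalibration fitted on the set being evaluated, while a binary flag
enters as a treat-if-positive policy — the source plots both without
stating its mapping, so the recalibration is this package's documented
choice. The chi-square test is Pearson without continuity correction
(`correct = TRUE` is available); the t-test offers pooled and Welch
variants and accepts `(n, mean, sd)` summaries, which follow the same
formulas exactly.

The published clinical performance figures (training/validation AUCs
0.860/0.943, PR means 0.71/0.23 and 0.55/0.23, DCA ranges) are not
reproduction targets — the clinical dataset is unavailable. The synthetic
demonstration is held to the qualitative claim only: on cohorts generated
with the reference effect sizes, the three-term score dominates the
dilation flag in AUC, mean precision and net benefit, in both sets.

## Numerical choices and degenerate inputs

* Plane-mesh sectioning chains crossing segments through shared mesh
  edges; chains that dead-end cross a vessel opening and are discarded.
  More than one closed loop near the origin raises a typed multi-loop
  condition that plane placement treats as "dirty station".
* Zero field samples are nudged by $10^{-12}$ so the level set never
  passes through grid points; degenerate (zero-area) triangles are
  dropped after welding.
* Station bisections refine to 0.1 mm; the marcher's step is 1 mm.
* A two-opening tube (both branch angles zero — the calibration cylinder)
  is legal everywhere except `select_measurement_planes()`, which reports
  "no carina found".
* Collinear triangle points give area 0; coincident points are an error
  for the angle. Prevalence 0 yields an all-negative cohort and
  group-difference tests refuse it by name.
* Scores are full precision internally; the two-decimal display matches
  the published examples and applies only at serialization.

## Known limitations

* One bifurcation, straight branches, no pulsatile deformation, no image
  synthesis: the generator stresses the measurement pipeline, not
  hemodynamics.
* The transverse dilation plane is tied to the generator's world axes.
* The roundness rule supports trunk ellipticities down to ~0.72; flatter
  vessels would need a different carina criterion.
* The synthetic cohort is a marginal-moment world; joint structure beyond
  an optional copula, measurement error, and site effects are out of
  scope, so a green evaluation suite establishes correctness of the
  statistics, not clinical transportability.
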
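---
title: "Tooth and jaw biomechanics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tooth and jaw biomechanics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentition)
```

## The static lever model

`dentition` treats the lower jaw as a static third-class lever rotating
about the jaw joint.  A closing muscle inserting at distance
*in lever* from the joint delivers, at a tooth whose tip lies at
distance *out lever* from the joint,

$$F_{tooth} = F_{in} \cdot \sin(\alpha) \cdot \frac{in\ lever}{out\ lever},$$

and the stress the tooth can transmit to prey is

$$\sigma = \frac{F_{tooth}}{SA_{tooth}}.$$

All distances are straight-line 3D Euclidean distances in millimeters
(not arc lengths along the jaw, and not projections into a sagittal
plane); forces are in newtons and stresses in N/mm².  Contributions of
up to three muscles are summed before dividing by the surface area.
The model is intentionally minimal: it describes a static bite at
occlusion and ignores jaw angle, closing speed, and lateral or
antero-posterior displacement of the jaw.  It also assumes each tooth
concentrates its load at a single point — for multi-cuspid teeth one
consensus tip must be chosen, and the stress estimate degrades
accordingly.

### The insertion angle

The angle $\alpha$ is measured *at the insertion point*, between the
muscle's line of action (insertion → origin) and the in-lever
(insertion → jaw joint).  This choice — the design was genuinely open,
since only "angle of insertion" is standard vocabulary — makes
$\sin\alpha = 1$ correspond to a perpendicular pull, which is the
orientation of maximal torque and is consistent with the 90° default
producing the plain mechanical-advantage model.  When an origin
landmark is present and no explicit angle is given, the angle is
measured from the geometry; an explicitly supplied angle always wins.

### Muscle input force

Two pathways provide $F_{in}$, with the following defaults:

| parameter | default | unit | meaning |
|---|---|---|---|
| `input_force` | 1 | N | assumed static bite force |
| `insertion_angle_deg` | 90 | ° | perpendicular pull |
| `pennation_angle_deg` | 0 | ° | parallel-fibered muscle |
| `f_max` | 0.2 | N/mm² | maximal isometric muscle stress |

With volume data the physiological estimate
$F_{in} = volume \cdot \cos(pennation) / fiber\ length \cdot F_{max}$
is used, taking the origin–insertion distance as a proxy for fiber
length unless `fiber_length` is given.  When a user supplies both a
direct force and volume parameters, the volume estimate wins (with a
message): a measured anatomical quantity should beat an assumed
constant.

## Automatic tip and base detection

Teeth are approximately surfaces of revolution, so the covariance of
their surface has one rotationally distinct eigenvalue (the anatomical
long axis) and two nearly equal ones (the cross-sectional plane).  The
package computes the area-weighted covariance of the face centroids —
an approximation of the uniform surface measure that is robust to
uneven triangulations, unlike raw vertex covariance, which a dense
basal ring would dominate — and selects the *distinct* eigenvector:
with eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$, the first
eigenvector if $\lambda_1 - \lambda_2 \ge \lambda_2 - \lambda_3$ and
the third otherwise.  For slender teeth this is simply the dominant
direction of variance; for squat crowns (height below about twice the
basal radius) the long axis is the *minor* eigenvector, and picking the
dominant one would return a direction in the base plane.  Only when all
three eigenvalues coincide within a relative 1e-9 (a sphere-like mesh)
is the axis ambiguous; the package then warns and applies a
deterministic tie-break (largest alignment with the jaw-plane normal
when available, else a lexicographic preference).

Orientation along the axis uses the jaw landmarks: of the two axis
endpoints at the extremes of the vertex projections, the one nearer the
jaw-joint → jaw-tip segment is the base side.  "Nearer" is measured to
the clamped orthogonal projection of the tooth centroid onto that
segment, which is pose-independent and encodes the anatomical fact that
tooth bases face the jaw ramus.  The base landmark is then slid along
the axis from outside the tooth until it first intersects the surface
(a ray–mesh intersection yielding the center of the base; if a
pathological concavity makes the ray miss, the extreme vertex is used
and a warning logged).  The tip landmark is raised beyond the apical
extreme by 10% of the axial extent — far enough to clear the crown,
close enough not to favor a flank — and snapped to the exact nearest
point on the surface.  Both the raise fraction and the basal-slab
fraction below are exposed as arguments.

Automatic orientation can still be wrong (e.g. strongly recurved teeth
whose apex leans toward the jaw line); `flip_tip_base()` exchanges tip
and base for all or selected teeth, exactly and involutively, after
which mechanics are recomputed.

### Height, width, aspect ratio, surface area

Height is the straight tip–base distance (not arc length along a curved
crown — consistent with the conical idealization underlying the stress
model).  "Width" has no standard operational definition; the package
uses the maximum caliper extent of the vertices in the basal 10% axial
slab, projected onto the plane normal to the tip–base direction.  For a
cone this equals the basal diameter $2r$ exactly, and the basal slab
keeps the measure meaningful for recurved crowns whose widest shadow
would otherwise reflect curvature rather than girth.  Aspect ratio is
height/width by construction.  Surface area is the exact sum of
triangle areas, so it depends only on the mesh, not on any landmark.

## The functional-homodonty statistics

Per jaw side (left and right are analyzed separately when `side` is
present):

1. **Residuals.**  Each stress is divided by the jaw's median stress.
   A ratio, not a difference: dentition stress distributions are
   right-skewed and the natural comparison ("this tooth bears 5× the
   typical stress") is multiplicative, which also makes every
   downstream quantity invariant to rescaling all stresses.
2. **Bootstrap null.**  10,000 replicates each draw half the teeth
   (⌊n/2⌋, without replacement) and renormalize them by the subsample
   median; all subsampled residuals are pooled.  Jaws with fewer than
   4 teeth are skipped (a half-subsample of one tooth is degenerate).
3. **Threshold.**  100 repeats each draw 5,000 pooled residuals
   (without replacement, clipped to the pool size) and split them by
   exact one-dimensional 2-medoids; the threshold is the mean of the
   two medoids, averaged over repeats.  In one dimension the optimal
   2-medoid partition is contiguous in sorted order and the optimal
   medoid of a sorted run is its (lower) median element, so a single
   scan over split points finds the global optimum — there is no PAM
   restart sensitivity, and ties break deterministically on the
   smallest split.  Medoid values (data points) are used as the
   cluster centers, since medoids *are* the centers of k-medoids.
4. **Classification.**  Teeth with residuals above the upper threshold
   are functional heterodonts.  Because unusually *low*-stress teeth
   are also biologically meaningful, a lower threshold is derived by
   default by running the identical clustering on the reciprocals of
   the pool and inverting the cutoff (`two_sided = "reciprocal"`);
   alternatives are `"mirror_log"` (lower = 1/upper) and `"off"`
   (upper threshold only).  This two-sided band is an interpretation:
   the single-threshold formulation leaves low outliers undefined.
5. **Summaries.**  The average squared residual (functional divergence
   of the battery) and the proportion of heterodont teeth (a few
   unique teeth vs regionalization).  The average squared residual is
   literally `mean(residual^2)`; `center = "one"` gives
   `mean((residual - 1)^2)` for users who prefer a deviation-from-
   typical reading.

An all-identical pool (perfectly homodont jaw) is flagged degenerate:
both thresholds collapse to the common value and every tooth is
homodont — the procedure never manufactures heterodonty from zero
variance.

**Seeding.**  One master seed governs everything.  Each jaw side gets a
substream seed derived from the master seed and a hash of its group
identifier, so results for one jaw never change when another jaw is
added to the table.  All randomized functions restore the caller's RNG
state.

A caution observed in practice: on strongly graded dentitions (identical
cones along a jaw produce a smooth, large-range stress gradient) the
residual distribution is so dispersed that the reciprocal-mode lower
threshold can exceed 1, and most teeth classify as heterodont.  That is
a faithful description of such a jaw — a stress gradient *is* functional
heterodonty — but users comparing species should interpret the two
summary metrics rather than the raw tooth counts.

## The synthetic-data generator

`jaw_spec()`/`make_jaw()` build parametric cone-tooth jaws: the joint at
the origin, the jaw tip on the x-axis, upright (optionally tilted) cone
teeth with base centers on the joint–tip line, and coronoid-like muscle
insertion points.  Defaults describe a plausible small-vertebrate jaw:
20 mm jaw, 10 teeth between 20% and 90% of its length, 2 mm crowns of
0.5 mm radius (shrunk when dentitions are dense so crowns never
overlap), insertion at (3, 0, 2) mm.  Optional lognormal jitter of
heights and radii (`height_cv`, `radius_cv`) emulates natural size
variation.  The generator returns analytic ground truth (cone area in
closed form, exact lever distances, the lever model under default
muscle assumptions) computed from plain formulas coded independently of
the measurement pipeline, so end-to-end tests are not circular.
`inject_outlier()` rescales one tooth's radius — height fixed, so its
force is untouched — to place its modeled stress at any chosen multiple
of the jaw's median, driving the heterodonty-recovery experiments.

What the generator does *not* emulate: recurved or bladed crowns,
surface roughness, segmentation noise, replacement teeth, or real
muscle architecture.  Passing tests therefore demonstrate correctness
of the implemented model and statistics, not field validity on every
real dentition; noisy CT segmentations will add measurement error the
cone fixtures do not contain.

## Numerical choices and degenerate inputs

- Meshes must have ≥ 4 vertices and faces, finite coordinates, valid
  indices; units are taken as millimeters with no inference.
- Labelmap surfaces are exact voxel-boundary triangulations of the
  binary mask at threshold 0.5, with no smoothing: deterministic and
  unit-exact (a single voxel at unit spacing has area exactly 6) at the
  cost of a blocky surface.
- FCSV coordinate systems are honored (LPS assumed when absent, as in
  recent Slicer) and normalized to one internal right-handed frame.
- Ray–triangle tests use a 1e-12 determinant cutoff and 1e-9
  barycentric slack; nearest-surface snapping uses exact point–triangle
  projection, so cone apices are recovered to machine precision.
- Zero-length levers, non-positive areas/stresses, missing landmarks
  and overlapping synthetic teeth are validation errors; a failing
  tooth inside `compute_dentition()` is isolated into an `ok = FALSE`
  row so one bad segment cannot abort a dentition.

## Problem sizes used in the test battery

The shipped tests run the full-scale statistics where the guarantees
are stated at full scale (10,000 bootstrap replicates, 5,000-residual
subsamples, 100 clustering repeats; 100-seed recovery experiments and
100 random-pose cones) and reduced but statistically adequate sizes
(≈ 2,000 replicates, 20–25 repeats) for the supporting property checks;
cone fixtures use 32–128 segments except where convergence itself is
under test (up to 1,024).

## Known limitations

Static bites only; single-point (conical) stress transmission; no mesh
repair, smoothing or decimation; no DICOM or Slicer-scene input; the
two-sided threshold is an interpretation layered on a one-threshold
formulation; and the homodonty thresholds are computed per dentition,
never pooled across jaws.
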
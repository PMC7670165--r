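---
title: "Bilateral coronoid-process morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral coronoid-process morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the anatomical coordinate system, the target-fragment measurements, the
mirror-image matching statistic, the synthetic data that stands in for
patient CT scans, and the numerical decisions taken where the method
description leaves room.

## The analysis in one paragraph

For each subject the two proximal ulnas are analysed independently. A
local anatomical frame is built per side: Z is the shaft central long
axis, P is the coronoid tip found where the plane through the
sigmoid-notch ridge meets the coronoid, O is the foot of the
perpendicular from P to Z, Y runs O→P, and X completes a right-handed
triad. A cutting plane parallel to the posterior flat spot of the
olecranon trims the upper 40% of coronoid height (the classic type-II
fragment boundary); the fragment's height, proximal–distal length,
medial–lateral width and the radii of the concave medial and convex
lateral articular bands are measured. The left side, mirrored across
X = 0 of its own frame, then shares the right side's frame by
construction; articular-surface similarity is the covering percentage
2·S/(S1+S2)·100, where S1 and S2 are the Delaunay areas of the two
articular point sets (triangulated on their local-XY projection, summed
with 3D vertex coordinates) and S is the area of the region where the
two surfaces approach within 2 mm.

## Tunable parameters

All defaults live in `pipeline_config()` and are serialised into every
report.

| parameter | default | unit | meaning |
|---|---|---|---|
| `fraction` | 0.40 | – | fragment fraction of total coronoid height |
| `proximity_mm` | 2.0 | mm | proximity distance of the covering statistic |
| `k_neighbors` | 20 | – | kNN neighbourhood for curvature/normals |
| `n_shaft_sections` | 3 | – | shaft cross-sections for the axis fit |
| `n_ridge_sections` | 5 | – | notch-ridge cross-sections |
| `shaft_fraction` | 0.5 | – | distal fraction of the model treated as shaft |
| `slab_halfwidth` | 0.5 | mm | cross-section slab half-width |
| `cone_deg` | 60 | deg | articular extraction cone half-angle |
| `tie_tol` | 4.0 | mm | near-tie band for the tip search |

The 0.40 fraction and the 2 mm proximity distance are the method's
substantive constants; the rest are detector resolutions chosen at the
scale of the input sampling (≈0.5 mm point spacing at the default
synthetic density).

## Detector design

The stated method says *what* to construct (axis through section
centres, maximal-curvature ridge points, a tip on the ridge plane, a
flat-spot-parallel cutting plane) but not *how* to make those constructs
robust on a discrete noisy point cloud. The package's choices:

* **Shaft axis.** Section "centres" are trimmed algebraic (Taubin)
  circle centres in the section plane, not point centroids: the anterior
  coronoid column overlaps the shaft axially and drags a centroid
  several millimetres anteriorly, whereas it appears to a circle fit as
  an interior cluster that smooth IRLS weights reject. A radius prior
  from the most distal (clean) section anchors the contaminated ones.
  The provisional direction comes from the cloud's first principal axis,
  oriented distal→proximal by end-section circularity (the shaft end is
  nearly circular, the articular head is not), and the fit is iterated
  five times so sections stay perpendicular to the current axis.
* **Ridge of the greater sigmoid notch.** Per cross-section the
  candidate is the point of maximal |K| from a two-pass estimate:
  moving-least-squares denoising of the slab followed by a quadric fit
  over a widened neighbourhood. Sign note: at the guiding ridge — a
  convex crease on a concave trough — the Gaussian curvature is
  *negative* (a saddle), so the detector ranks by magnitude. Candidates
  are restricted to the anterior near-axis region (within 1.35 shaft
  radii; the dorsal cortex, the fragment margin and the olecranon
  corners carry their own creases but lie far off-axis or posteriorly),
  filtered by quadric residual (non-manifold neighbourhoods where two
  cortical sheets pass close produce spurious maxima), validated by a
  crest-parabola check, and refined to the crease apex with sub-sample
  precision.
* **Ridge plane and tip.** A total-least-squares plane through five
  points on a shallow arc is ill-conditioned about the arc's chord:
  sub-millimetre jitter rotates it by tens of degrees. The pipeline
  instead fits an axis-parallel plane with a Theil–Sen (median-slope)
  lateral tilt, which tolerates one spurious ridge point. The tip is
  then the most protruding anterior point near that plane, found by a
  multi-start hill climb on (noise-smoothed) axis distance with the raw
  apex sample as the final pick.
* **Base plane.** The tip-to-base coronoid height must be measured along
  the flat-spot normal, so the base plane is anchored parallel to the
  flat spot through the deepest detected ridge point (locally refined
  within a narrow depth band so the dorsal cortex cannot capture the
  anchor). `fit_base_plane()` retains the generic total-least-squares
  branch for externally supplied notch points. A plane fitted directly
  through the five crest points cannot serve here: those points are
  near-sagittal, and a sagittal plane is perpendicular to the flat-spot
  normal, leaving the height undefined.
* **Facet radii.** The articular sheet sweeps proximally at tilt τ, so a
  thin transverse slab smears the facet arc by (slab/τ), which is
  comparable to the whole sagitta of the short medial band. Instead the
  full band is collapsed: in-plane position obeys y ≈ c + z/τ − Γ(x)
  with Γ the transverse profile, τ is estimated from the surface normals
  (independent of the circle parameters — estimating the shear from the
  circle residual is ill-posed because a shear of a half-width arc is
  largely absorbed by a radius change), and a Taubin fit on the
  de-sheared band gives the radius. Clean-band-gated refinements remove
  the residual tilt error and the frame's lateral (yaw) slope, measured
  where it is identifiable: both facet arcs meet the apex with zero
  transverse slope. A leading-order correction removes the classic
  noisy-arc radius inflation (sagitta enters the radius reciprocally, so
  sagitta variance biases the fit upward). The medial/lateral split at
  the midline is soft over ±0.5 mm — the apex is genuinely shared.

## Numerical stability and rigid-motion equivariance

Every step uses only relative geometry, so in exact arithmetic the
pipeline commutes with rigid motion of the input. In floating point,
discrete selections (landmark argmaxima, kNN sets, slab memberships)
can flip between near-tied samples when the same cloud arrives in a
different pose, changing measurements at the sampling-resolution scale.
The pipeline therefore (a) canonicalises pose first — principal axes
with skewness-fixed signs — so every rigid placement maps to the same
canonical cloud, (b) uses smooth IRLS weights instead of hard trims
inside the fitted primitives, and (c) quantises canonical coordinates at
1e-6 mm, far below any physical resolution, making the detector chain
bit-reproducible across poses. The test suite asserts that a rotated and
translated copy of an input changes no reported measurement by more than
1e-6 mm.

Other conventions: covering is clipped to [0, 100] with a flag; the
proximity area S is the mean of the two masked-subset areas, which makes
the identity case exactly 100% and the statistic symmetric under side
swap; triangle areas use 3D vertex coordinates with 2D-projection
connectivity (the articular surface is curved); duplicate XY projections
keep the vertex nearest the viewer; degenerate inputs (collinear plane
or circle fits, empty fragments, missing sides) raise classed
conditions rather than propagating NaN.

## The synthetic generator

`generate_ulna()` builds a parametric proximal ulna from analytic
patches: a cylindrical shaft (the local frame's ground-truth Z), a
dorsal heel rising to a planar posterior facet (the flat spot), a
concave notch channel of radius 13 mm carrying a Gaussian-bump guiding
ridge (height 1.6 mm, width 1.6 mm) through the sagittal midline, an
olecranon with side walls, dome and a beak that continues the channel
tangentially, and a coronoid whose superior articular face is an
extruded profile with a concave medial arc and convex lateral arc of the
requested radii. The default dimensions sit at the adult population
means the package's cohort simulator also uses (fragment height 12.4 mm
under the 40% rule, length 23.8 mm, width 23.1 mm, radii 6.44 and
11.84 mm). The right side is sampled to `n_points` (default 8000; real
CT exports are one to two orders denser — the default trades fidelity
for run time and is documented per result); the left side is the exact
mirror image, optionally scaled (`asymmetry_scale`), warped by a
low-frequency displacement field (`asymmetry_warp`), and independently
noised along the surface normals (`noise_sigma`, emulating segmentation
jitter at sub-voxel scale).

What the generator does *not* emulate: cortical thickness and interior
structure (surfaces only), cartilage (the method is osseous by design),
anatomically detailed muscle ridges, and inter-subject shape variation
beyond the five measurement parameters and the asymmetry controls.
Passing tests on synthetic pairs therefore demonstrate that the
*detectors recover known geometry under noise and pose*, not that the
population numbers of any clinical cohort are reproduced — the cohort
module is validated instead by its statistical calibration (type-I error
and power under the measurement-level simulator).

## Estimator limits worth knowing

* The medial facet band spans roughly a 0.8-radius chord. At 0.2 mm
  surface noise the sagitta of that arc carries about 15% per-draw
  standard deviation *for any estimator* (verified on exact synthetic
  bands), so single-subject medial radii at heavy noise are intrinsically
  uncertain; the pipeline's accuracy at that noise level is therefore
  characterised by its Monte-Carlo mean over replicate surfaces, which
  is within a few percent of truth. At realistic segmentation noise
  (≤0.15 mm) per-subject recovery is within a few percent throughout.
* Covering percentage saturates: small bilateral asymmetries keep every
  articular point within the 2 mm proximity band and return exactly
  100%. Degradation begins once local mismatch crosses 2 mm and is
  monotone in the asymmetry magnitude thereafter.
* Measurement windows (0.5 mm slabs, 2 mm proximity) are absolute
  mm quantities from the method, so scaling a bone by s reproduces
  measurements times s only up to the window granularity (tested at
  0.5–1%), not exactly.
* The age dichotomy is >40 vs ≤40 years; no multiple-testing correction
  is applied, matching the single-comparison reporting style of the
  underlying procedure.

## Problem sizes used by the test suite

Unit tests run the pipeline at 4000–5000 points per side; the
recovery, monotonicity and calibration checks use the defaults (8000
points, 20 replicate seeds, asymmetry grid 1.00–1.30, 1000 replicate
cohorts of n = 60 for the type-I study). These sizes were chosen so the
whole suite characterises every stage with comfortable statistical
margins.
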
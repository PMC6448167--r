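---
title: "Multiparametric assessment of deformable image registration with digital phantoms"
author: "dirqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric assessment of deformable image registration with digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirqa)
```

## The problem

Deformable image registration (DIR) underpins adaptive radiotherapy:
contour propagation and dose accumulation both assume that the estimated
displacement vector field (DVF) maps each anatomical point of one CT study
onto the corresponding point of another. Commercial engines expose neither
their cost function nor their optimizer, so their accuracy has to be
characterized from the outside, by registering test objects with known
deformations and scoring how well positions, volumes and shapes are
recovered. No single score suffices: an index sensitive to translations
(marker distances) can look perfect while shapes are mangled, and an
overlap index can look perfect while internal landmarks drift. `dirqa`
implements a multiparametric assessment built around two digital phantoms
that mimic the deformations most relevant to head-and-neck treatments —
anatomical *bending* and tumour *shrinking* — plus the full similarity-index
suite, a self-registration sensitivity protocol, and study orchestration
with statistical comparison of refined vs unrefined registrations.

The toolkit is self-contained: it generates its own CT-like volumes
(Hounsfield-unit voxel grids with anisotropic spacing, NIfTI-1 on disk),
structure masks, landmark sets and ground-truth DVFs. A stand-in DIR engine
is included so every protocol runs end to end, but any third-party
algorithm can be scored instead by importing its DVF (`read_field()`),
which is the toolkit's primary intended use.

## Conventions

World coordinates are millimetres; voxel indices are 0-based with the point
at the voxel center; axes are (x in-plane, y in-plane, z slice). A
`deformation_field` is stored in the *pull-back* convention on the
reference grid: the registered (warped) image at reference position $p$
samples the target image at $p + u(p)$. This matches how registered
datasets are produced, and it is the convention assumed for imported DVFs;
push-forward fields are inverted on import by fixed-point iteration (20
iterations, 0.01 mm tolerance). Out-of-bounds samples take $-1000$ HU
(air).

## Phantom 1: the bending stick

A clay-like stick (default length 150 mm, radius 15 mm) contains three
glass-like spheres (diameter 16 mm, centers at 25/75/125 mm along the axis)
and seven 2 mm grains; spheres and grains act as reference structures and
markers. The paper-scale dimensions of the physical object are not printed
anywhere, so the defaults above are declared, configurable choices, not
inferences.

The ground-truth deformation is a constant-curvature bend about an axis
perpendicular to the stick, anchored at one end (the fixed extremity), with
arc length preserved on the neutral axis. Both the forward and inverse
mappings are closed-form, so the ground truth is exactly invertible and the
bent image is rendered by evaluating materials at inverse-mapped positions
— there is no resampling error in the ground truth itself.

**Operational definition of the bend level.** The level of a bending
experiment is the angle *measured between the principal axes of the two
stick extremities on the images*, exactly as one would measure it on a CT
of the physical object. `measure_bend_angle()` reconstructs the stick
centerline as the chain of cross-section slab centroids (slabs
perpendicular to the global principal axis; incomplete end cross-sections
discarded) and fits an axis to each terminal 20%. For a uniform-curvature
arc the terminal-segment axis is the segment chord, so the measured angle
is about 0.8 of the arc's total turning angle, with a further thick-stick
correction from the discarded end cross-sections. The generator therefore
*calibrates* the curvature — starting from a closed-form thin-stick model
and refining numerically against the rendered volume — so that the measured
angle equals the configured level. This mirrors the study design, where
bending levels are defined a posteriori by the image measurement; it also
means `measure_bend_angle(build_bending_phantom(theta))` returns `theta` by
construction, which the test suite verifies to within 1 degree at every
study level.

Voxels are rendered by material (background/clay/glass) with partial-volume
anti-aliasing: boundary voxels (any face neighbour in a different material)
are supersampled 8x and averaged. Masks returned by the builder are the
discretized analytic sphere interiors; landmarks are the exact mapped
centers.

## Phantom 2: the shrinking mass

A head/neck-like body of stacked ellipses (in-plane semi-axes growing from
55x45 mm at the neck to 65x55 mm at the head over 80 mm) carries a
mandible-like bone arc (anterior elliptical-arc tube, 5 mm tube radius) and
eight 3 mm air-pocket defects used as markers. A water-filled mass is
attached to the anterior surface at mid-height and *grown voxel by voxel* —
exterior voxels sorted by distance to the attachment point — until its
voxel volume first reaches the requested fill (0/25/50 ml study levels), so
the realized volume is correct to within half a voxel by construction. A 2
mm gel-like shell (30 HU) surrounds the water (0 HU), mimicking the gel
used to couple the physical mass to the body. Body, bone and markers are
bit-identical across fill levels; only the mass changes. Analyses are
restricted to a 62 mm axial region of interest centered on the mass (31
slices at 2 mm).

With these defaults the external contour encloses roughly 700 ml over the
ROI, so the largest fill difference is a small relative volume change — the
regime in which overlap indices saturate and only shape-sensitive indices
(Hausdorff distance) react, which is precisely what the shrinking study
probes.

## Contrast remapping and noise

The raw phantoms are written at scanner-like material values (clay 150 HU,
glass 2300 HU, background -1000 HU). `remap_contrast()` replaces every
voxel value $v$ by $q(v)$, where $q$ is the unique degree-$\le 2$
polynomial (Lagrange interpolation) through three anchor pairs: the
background (a fixed point) and the two materials. The three study levels
map clay/glass to 30/1000 HU (muscle/bone), -100/40 HU (fat/muscle) and
10/50 HU (two soft tissues). The first level doubles as the baseline
contrast of the bending study.

Gaussian noise (`add_noise()`, default sigma 10 HU, seeded and
reproducible) is added to the *raw* volumes, before remapping. This
ordering matters: a post-hoc HU rescale of scanner data compresses the
noise together with the contrast, so the soft-tissue level ends up with a
contrast-to-noise ratio an order of magnitude below the bone level. That is
the mechanism by which low contrast degrades intensity-driven registration,
and it is what the variable-contrast trend tests exercise. Sigma 10 HU is a
typical soft-tissue noise level for a head CT protocol at the toolkit's
default voxel size.

## The stand-in DIR engine

The engine under test in the bundled studies is a multi-resolution
demons-type free-form registration — a deliberate stand-in for the
behaviour class of commercial free-form intensity-based engines, whose
actual cost functions are unpublished. It is labelled as such everywhere;
none of its numerical outputs are claims about any commercial product.

Per iteration, the intensity-difference force
$-(T_w - F)\,\nabla F / (|\nabla F|^2 + (T_w - F)^2/\delta^2)$ (fixed-image
gradient, $\delta$ = largest voxel size) is capped at `step_max` (0.8) of
the smallest voxel size, smoothed with `sigma_fluid` (2.5 mm, fluid-like
regularization), added to the field, and the accumulated field is smoothed
with `sigma_elastic` (2.5 mm, elastic-like regularization realizing the
transformation-likelihood term). Three pyramid levels (downsampling 4/2/1)
with 60/40/15 iterations and a 0.02 mm mean-update stopping tolerance are
the defaults. Two numerical choices deserve note:

* `sigma_elastic` must be comparable to `sigma_fluid`; much weaker elastic
  smoothing lets the coarsest level accumulate a rough, runaway field that
  the finer levels cannot undo.
* `force_floor` (30 HU, about three times the default noise) zeroes the
  force where the intensity difference is within noise. Without it, noise
  in homogeneous and air regions random-walks into several-millimetre
  spurious displacements over tens of iterations, which corrupts
  surface-sensitive indices. Set it to 0 for noise-free synthetic tests.

The rigid pre-alignment stage offers a closed-form landmark mode
(orthogonal Procrustes without scaling; with only two — or collinear —
pairs the twist about the common axis is unconstrained and the minimal
geodesic rotation is taken) and an intensity mode (Nelder-Mead direct
search on 3 translations + 3 rotations over a mean-squares metric,
optionally restricted to a mask such as bone). The deformable stage starts
from the rigid fusion and the returned field is the composition
`rigid(p + u(p))`.

`reg_refine()` implements box-based local-rigid refinement: inside each
user-placed box a local rigid registration is run, warm-started at the
field's mean displacement there; accepted rigids are blended into a
correction by normalized Gaussian distance weighting from the box centers
(sigma = half the box diagonal, support truncated at 4 sigma), and a short
closing deformable pass runs with locked boxes frozen and updates confined
to the blend region. A local rigid is accepted only if it improves the
box's mean-squares metric — the automatic analogue of an operator
inspecting a box before locking it. The field is guaranteed untouched
beyond 4 blend sigmas from every box. Default box layouts follow the study
protocols: nine boxes equally spaced along the stick for the bending study,
and a 5x5 grid of boxes over the mass-facing surface (25 boxes) for the
shrinking study; both are documented helpers, not enforced placements.

## Similarity indices and sensitivity

For corresponding structures $A$ (reference) and $B$ (registered):

* **DSC** $= 2|A \cap B| / (|A| + |B|)$ on voxelized (filled) masks.
* **HD**: classical symmetric Hausdorff distance between the surface-voxel
  sets (surface = member voxel with a face neighbour outside), in mm. The
  maximum — not a percentile — is used, as the unqualified definition.
* **DD** $= |d_{max}(A) - d_{max}(B)|$ where $d_{max}$ is the maximum
  Feret diameter (largest pairwise surface-voxel distance, orientation
  independent).
* **R** / **RM**: Euclidean distance between corresponding sphere centroids
  / marker positions.

Structure correspondence is by axial ordering for the bending phantom
(components sorted by centroid z, ties by y then x) and by label for the
shrinking phantom. Spheres are segmented at 50% of the global maximum with
26-connected components and a minimum size that excludes the grains. In the
digital pipeline, marker positions of the target study are carried into the
reference frame through the point-wise fixed-point inverse of the estimated
DVF rather than by re-segmenting blobs in the registered image; the two are
equivalent well below every reported sensitivity, and the inverse is exact
for rigid transforms.

`sensitivity_protocol()` registers a dataset with itself through the full
pipeline and reports the maximum of each index (and of $1 -$ DSC) over
structures and markers — the floor below which index differences between
registrations carry no information. Because the digital pipeline is
deterministic and identical inputs produce an exactly zero intensity force,
these floors are essentially zero here (machine epsilon); physical floors
are dominated by re-scan variability and slice thickness instead. The
acceptance checks therefore treat the physical values as ceilings that the
digital pipeline must not exceed. Study reports flag index differences
between refined and unrefined runs only when they exceed the
phantom-matched sensitivity, reproducing the printed-table convention.

## Study protocols and statistics

* **Variable bending**: bent variants at the configured levels (defaults
  8/16/25 degrees) are registered onto the straight reference;
  pre-alignment uses spheres 1 and 3 (landmark mode); all five indices per
  sphere/marker.
* **Variable contrast**: identical chain after remapping the raw noisy
  volumes with each contrast level; by construction the first level
  reproduces the bending study bit for bit under the same seed.
* **Shrinking volume**: the 50 ml study is registered onto the 25 ml and
  empty references (reg1/reg2, volume differences 25 and 50 ml, recorded in
  the metadata); pre-alignment optimizes the bone match; DSC/HD on external
  contour and mandible over the ROI, RM on the eight markers.
* **Refinement comparison**: every registration is repeated with
  `reg_refine()`; pooled per-(structure-or-marker, condition) pairs feed a
  paired two-sided Wilcoxon signed-rank test per index common to both
  phantoms (DSC, HD, RM). The pooling rule — one paired observation per
  item and condition present in both runs — is the only reading that
  yields matched pairs, and it is recorded in the output metadata.

`wilcoxon_paired()` drops zero differences, mid-ranks ties, and uses the
exact permutation null (generating-function convolution over doubled ranks,
so mid-ranks stay integral) up to n = 25, a tie-corrected normal
approximation with continuity correction above; fewer than 5 nonzero pairs
is an error, not a p-value.

Spider (radar) summaries place the mean HD, DD, R and RM — in that fixed
axis order, raw millimetres without per-axis rescaling — on four equally
spaced axes; the shoelace polygon area is the single-number summary
(smaller = more accurate).

## What the generator does and does not emulate

The phantoms reproduce the *geometry* of the assessment: known deformations
with exact ground truth, realistic HU assignments, partial-volume
anti-aliasing, anisotropic voxels and additive noise. They do not emulate
scanner physics (beam hardening, reconstruction kernels, noise texture),
anthropomorphic tissue texture, pose differences between scans, or
re-scan/segmentation variability. Consequently, passing trend tests shows
that the assessment machinery orders conditions correctly for an engine of
the demons class on clean data; it does not certify any engine's clinical
accuracy, and the bundled engine's absolute index values are expected to be
better than those of any engine facing real scans. The self-registration
sensitivities are likewise near zero digitally, where physical studies
report fractions of a millimetre to millimetres.

## Numerical choices and degenerate inputs

Trilinear interpolation throughout, with air fill outside the target;
resampling with the identity field on a coincident grid is bit-exact.
Threshold segmentation of a uniform volume is flagged as degenerate rather
than returning an arbitrary component. Empty masks are errors for every
index (DSC of two empty masks is undefined, not 1). Field inversion uses 20
fixed-point iterations with a 0.01 mm tolerance. The bend self-intersects
when the arc turns more than 180 degrees, which with the end-axes
calibration corresponds to configured levels above 144 degrees; this is a
parameter error. All randomness (noise, stochastic fixtures) flows through
per-volume seeds derived from one master seed, and the engine itself is
deterministic, so identical configurations reproduce studies bit for bit.

Problem sizes: the packaged studies default to the CT-resolution grid
(1 x 1 x 2 mm; about 0.3M voxels for the bending phantom and 1M for the
shrinking phantom). The test suite runs the same code on 2-2.5 mm grids,
which preserves every geometric property (sphere segmentability, mass
volume bookkeeping, trend directions) at a fraction of the cost; the
choice of grid is stated in each test. Trend properties of the stand-in
engine are asserted over three seeds by majority rule, not per-run,
because a stochastic noise realization can tip an individual comparison.

## Known limitations

* The stand-in engine is not any commercial algorithm; numeric index
  values from the bundled studies characterize the assessment method, not
  a product.
* HD is the strict maximum; engines reported with percentile Hausdorff
  variants will look worse here at equal quality.
* DD uses the 3D Feret diameter; a measurement along a fixed anatomical
  axis would differ for strongly anisotropic structures.
* The refinement's blending weights and acceptance rule are toolkit
  choices; the behaviour class ("local rigids combined into a new DIR") is
  preserved but not any particular implementation.
* Only axis-aligned NIfTI geometries are supported; DICOM series and 4D
  studies are out of scope.
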
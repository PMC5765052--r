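---
title: "3D skeletal morphometry with skelemorph: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D skeletal morphometry with skelemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelemorph)
```

## What this package measures and why

Mouse models of achondroplasia (activating *Fgfr3* mutations) show a
disproportionate skeletal phenotype — shortened, bowed long bones, a
domed skull with a narrowed foramen magnum, kyphosis, shortened
vertebrae and pedicles, and an abnormal growth plate. Classical
phenotyping reduces these to 2D calliper-style distances on radiographs.
skelemorph implements the 3D alternative: measurements taken directly on
micro-CT and MRI volumes, where curvature, plate topography and aperture
geometry are first-class. Because real studies of this kind rarely
deposit raw scans, every measurement here is validated against synthetic
phantoms whose ground truth is known in closed form; the phantom
generators are part of the package, not test scaffolding.

Conventions: volumes are arrays with axis 1 the longitudinal (scan)
axis; world coordinates are voxel centres; every physical output is in
mm, mm^2 or mm^3. Slice ranges are half-open `[start, stop)`; mm
offsets convert to slice counts by round-half-away-from-zero, which must
be fixed explicitly because the protocol states distances in mm on an
8.6 um grid.

## Segmentation and the trabecular VOI

Bone is segmented by a global threshold, foreground = gray value >=
level, with a default level of 40 on 8-bit CT reconstructions (the
operating point of the trabecular protocol; levels 30-50 behave
monotonically, which the tests assert). The inclusivity of the threshold
is a documented convention — either choice is defensible, but only a
fixed one is reproducible.

The trabecular volume of interest is anchored on the growth plate: it
starts `offset_mm` (default 0.1 mm) from a reference slice toward the
diaphysis and extends `extent_mm` (default 0.5 mm) along the bone axis.
The reference slice is an input, not detected from the image: in
practice it is located by a human, and the phantoms carry it as
metadata. On the 8.6 um grid the defaults translate to offsets of 12 and
58 slices.

## Curved length

`curved_length()` is deliberately the simplest defensible model: the
length of the piecewise-linear polyline through the seed points, exactly
what an interactive "3D length tool" computes. No spline is fitted by
default (an optional one exists), because polyline length is
deterministic, rigid-motion invariant, and converges monotonically from
below to the true arc length as seeds are refined — all three properties
are asserted in the tests. With 200 seeds on a one-turn helix of radius
3 mm and pitch 1 mm/rad the relative error against the analytic length
$\theta\sqrt{R^2+c^2} = 2\pi\sqrt{10}$ is under 0.05%.

`centerline_from_mask()` automates seed placement for tubular masks. It
does not run a topological thinning; instead it (1) computes the
Euclidean distance transform in physical mm, (2) finds the two
foreground voxels farthest apart in grid-geodesic distance, restricted
to near-maximal-radius (medial) voxels so the tips sit on the axis
rather than on the cap surface, (3) traces the geodesic between them
with edge costs that penalise leaving the medial axis
(`medial_penalty`, default 20 — large enough that the path cannot cut
the inside of a curve whose radius is an order of magnitude above the
tube radius), and (4) resamples the voxel path at uniform arc length and
applies a short moving average (11 points over a 4x-oversampled path) to
remove lattice zigzag, which would otherwise bias the length upward by
several percent. A mask whose tip separation is less than `min_aspect`
(6) times the maximal inscribed radius has no meaningful axis (a sphere,
a plate) and is rejected. On phantoms the recovered length is exact to
one voxel for a straight tube and within 2% on the helix.

## Trabecular microarchitecture

BV/TV is bone voxels over sample-volume voxels — pure counting, exact by
construction. Tb.Th uses the model-independent maximal-inscribed-sphere
definition: for every bone voxel, the diameter of the largest sphere
containing it that fits in the structure, averaged over bone. Sphere
radii are Euclidean distances to the nearest background voxel centre
(computed by a separable anisotropic distance transform in mm, so 8.6
and 17.2 um grids are handled identically); a redundancy test skips
spheres wholly contained in a neighbour's sphere before the coverage
pass. The half-voxel overshoot of distance-to-centre compensates the
half-voxel erosion of the voxel model, which is why a 10-voxel plate
reads exactly 10 voxels of thickness; the implementation is asserted to
agree *exactly* with a brute-force sphere-growing oracle on small grids.
Tb.N uses the parallel-plate model, Tb.N = (BV/TV)/Tb.Th, recorded as
such in the result metadata. The plate model is exact on plate
phantoms (it equals 1/period); a direct mid-axis Tb.N is deliberately
out of scope because its discretisation is under-documented and it
cannot be distinguished from the plate model on this package's
validation surface.

On plate lattices (thickness 0.1 mm, period 0.3-0.6 mm, 10 um voxels)
the triple (BV/TV, Tb.Th, Tb.N) is recovered to half a voxel.

## Growth plate

The growth plate is treated as a segmented plate-like mask (the
outlining itself is manual in practice and is an input here). Volume is
voxel counting. Thickness uses a two-surface model: the isosurface of
the mask is split by the sign of each face normal's component along the
plate axis into a proximal and a distal sheet, discarding rim faces
whose |normal component| is below `rim_tolerance` (default 0.5, i.e. a
45 degree face/rim split — steep enough to keep the faces of a curved
plate tilted up to 60 degrees, while excluding the rim wall). A mask
whose rim would carry more than 35% of the surface area has no plate
orientation and is rejected (a sphere fails exactly this way). Each
proximal vertex contributes the distance to the nearest point of the
distal sheet; the summary is the **area-weighted mean** (the
histogram-tool statistic is ambiguous between mean and mode — the mean
is stable and is what the ratio below needs), and the full histogram
plus a topographic in-plane map (bin size twice the median edge length)
are kept in the result. Thickness is symmetric in the two sheets to
within 2% on phantoms.

The volume/thickness ratio is reported as a surrogate for the plate's
footprint area: exact for constant thickness ($V = A\,\bar t$ implies
$V/\bar t = A$), and accurate to the thickness coefficient of variation
otherwise — the wedge phantom (0.1 to 0.3 mm linear gradient) stays
within 5% of its true footprint.

Isosurfaces are extracted by marching tetrahedra (six tetrahedra per
cell, vertices interpolated on edges, orientation fixed by the field
gradient) over the binary indicator smoothed with a 1-voxel Gaussian.
The smoothing matters: contouring raw binary data at 0.5 produces
staircase facets whose area and rim length are biased by several
percent; the smoothed field puts the surface at the half-voxel boundary
with sub-voxel accuracy. Marching tetrahedra was chosen over marching
cubes because it needs no case table, has no ambiguous configurations,
and its output is watertight on closed structures.

## Craniofacial measurements

Skull bone volume is threshold -> largest connected component (26-
connectivity, ties broken toward the smallest voxel index) -> voxel
counting; on a hollow-shell phantom of outer radius 5 mm and inner 4.8
mm it is within 2% of $\frac{4}{3}\pi(R^3-r^3)$. Brain volume follows
the MRI protocol literally: per-coronal-slice segmented areas summed and
multiplied by the 0.5 mm slice thickness; the ellipsoid phantom (8, 6,
5 mm semi-axes) is recovered within 2% of $\frac{4}{3}\pi abc$
(mid-slice sampling of a quadratic area profile is nearly exact).

The foramen magnum is measured on the 3D skull surface. Its
circumference is interpreted as the length of the aperture's rim — the
longest closed loop of boundary edges (edges used by exactly one face)
of an open surface mesh; a watertight mesh has no rim and is an error.
This rim-loop reading of "geodesic boundary length" is the natural one:
the rim *is* a closed curve on the surface, and its length is what a
surface geodesic tool traces along it. Transverse and sagittal
diameters are the rim's extents along two configurable orthogonal axes
(anatomical axes are fixed by inspection in practice; phantoms use world
axes), and the area is the ellipse formula $\frac{\pi}{4} D_t D_s$,
which is exact for planar elliptical apertures. Validation meshes are
built parametrically with exact circular or elliptical rims (a UV sphere
with polar caps removed; an elliptical tube closed at one end), so rim
extraction can be tested against $2\pi r$ and against Ramanujan's
ellipse perimeter to 2%.

## Spine

The kyphosis index is the two-landmark form KI = AB/CD: chord length
between the profile landmarks over the maximum perpendicular distance
from the chord to the dorsal profile between them. Lower KI = more
kyphotic; a semicircular column gives exactly 2, and KI is strictly
decreasing in sagitta at fixed chord (asserted). The source formulation
of the index does not pin down the landmark pair, so the landmarks are
parameters (defaulting to the profile ends), not hard-coded anatomy. A
perfectly straight profile has CD = 0 and returns +Inf with a warning
rather than an error, since it is a legitimate (if idealised) spine.
Body length, pedicle length (mean of left and right apex-to-base) and
the curved L4-L6 canal length are landmark/seed distances reusing the
curved-length machinery.

## Statistics

The study layer mirrors a two-genotype (WT vs Ach), two-age (3 and 6
weeks) cross-sectional design: per-cell Welch two-tailed t-tests
(unrounded Welch-Satterthwaite df), mean +/- SEM summaries, star codes
with strict open bands (`*` 0.01<p<0.05 up to `****` p<0.0001; boundary
values fall to the weaker band), Holm-Sidak step-down adjustment across
timepoints for timeline measurements, and a chi-square goodness-of-fit
(no continuity correction) for litter sex/genotype ratios. Welch and
chi-square delegate to R's `t.test()`/`chisq.test()`; the tests compare
both against hand-written textbook oracles to 1e-10, and Holm-Sidak —
written out explicitly, since no step-down Sidak exists in base R — is
checked against a direct-definition oracle. Calibration is asserted
empirically: under the null the group summary stars ~5% of comparisons
at alpha = 0.05 across 1000 simulated studies.

One power note, because it affects how the two-age pattern should be
read: with a 2 SD effect at 3 weeks only and n = 10/group, the
per-study probability of the clean qualitative pattern (significant at 3
weeks *and* non-significant at 6) is bounded by power x (1 - alpha)
~= 0.985 x 0.95 ~= 0.94 — it cannot reach 95% for any finite effect,
because the 6-week null itself produces false positives at rate alpha.
Empirically the rate sits at 0.93-0.95 over 200-run batches.

## The phantom generators

Phantoms voxelize shapes with closed-form measurables: helical and
straight tubes (arc length), voxel-aligned plate lattices (BV/TV =
t/period, Tb.Th = t, Tb.N = 1/period hold exactly on the grid), constant
slabs, linear wedges and spherical-cap shells with a quadratic
centre-to-margin thickness profile (volume and mean thickness by
quadrature of the exact integrands), hollow-shell skulls with optional
conical apertures, coronal ellipsoid slice stacks, and circular-arc
vertebral columns (KI = chord/sagitta). Gray levels follow a two-class
model — foreground N(100, sd), background N(20, sd), clipped to
[0, 255] — so the standard threshold of 40 is the correct operating
point and segments *exactly* at zero noise; `noise_sd = 15` is used as
the robustness condition, under which recovery degrades gracefully
(errors stay within twice the noise-free tolerance at 0.05 mm voxels —
note that threshold-only segmentation of sd-15 noise misclassifies ~9%
of background, which is visible as a positive BV/TV bias; real protocols
would despeckle, which is out of scope here). All randomness passes
through a single seed; identical specs and seeds produce bit-identical
volumes.

`generate_study()` emulates the cross-sectional animal study: Gaussian
measurement values, independent animals per age, effects specified per
measurement in SD units at each age. Its defaults (n = 10/group, unit
SD, a -2 SD 3-week-only effect) are the conditions used throughout the
validation suite.

What the phantoms do *not* emulate: CT physics (beam hardening, ring
artefacts, partial volume beyond the voxel model), anatomically
realistic bone, within-animal correlation between measurements, or
sex effects. Passing tests therefore demonstrate that the measurement
chain is correct on geometry it can resolve — not that segmentation of
real, artefact-laden scans is solved, which in the emulated protocol
remains a human step.

## Problem sizes and numerical choices

The validation suite runs phantoms at 10 um voxels for the trabecular
lattice (the scale of the real protocol), 40-50 um for the larger
slab/shell/skull geometries, and 0.5 mm MRI slices — sizes chosen so
every analytic comparison is resolution-limited rather than
implementation-limited. Degenerate inputs fail loudly and early: empty
masks, VOIs leaving the volume, watertight meshes where a rim is
required, spheres where a plate or tube is required, missing spacing in
headerless TIFF stacks (never silently assumed 1.0), and NaN values in
study tables at write time. Known limitations: Tb.Sp/SMI/anisotropy and
BMD calibration are not implemented; the growth-plate rim-exclusion
tolerance is a convention (0.5) that a different mesh tool could set
differently; and the foramen rim of a voxelized (rather than
parametric) skull inherits mesh-scale jitter from the isosurface, so
rims measured on real segmentations should use the smoothed surface.

## A worked example

```{r example}
ph <- phantom_curved_tube(helix_radius = 3, pitch = 1, theta_max = 2 * pi,
                          tube_radius = 0.3, spacing = 0.05, seed = 7)
c(seed_polyline = curved_length(ph$seeds),
  auto_centerline = curved_length(centerline_from_mask(ph$mask)),
  analytic = 2 * pi * sqrt(10))

pl <- phantom_plate_lattice(thickness = 0.1, period = 0.4, spacing = 0.01)
trabecular_metrics(threshold_mask(pl$volume, 40), voi = pl$voi)
```
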
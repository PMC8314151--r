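---
title: "Surface DSC: model, implementation choices, and what the phantoms show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface DSC: model, implementation choices, and what the phantoms show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfdice)
```

## The problem and the metric

Automatic organ-at-risk (OAR) segmentations on radiotherapy planning CT are
reviewed and corrected by a clinician before use. The cost of that review is
driven by how much of the *contour surface* is misplaced beyond an
acceptable margin, not by how much volume overlaps: a contour that is wrong
by a millimeter everywhere takes far longer to fix than one with a single
large but localized error, yet volumetric Dice can score them identically.

The surface Dice similarity coefficient at tolerance τ addresses this. For
masks $M_1, M_2$ with surfaces $S_1, S_2$ (areas $|S_1|, |S_2|$) and border
regions $B_i^\tau$ (all points within distance τ of $S_i$):

$$\mathrm{SDSC}(\tau) \;=\;
  \frac{|S_1 \cap B_2^\tau| + |S_2 \cap B_1^\tau|}{|S_1| + |S_2|}.$$

Both directed comparisons appear in the numerator, so false-positive and
false-negative surface parts are both penalized; normalizing by the combined
area keeps the value in $[0,1]$. τ carries the clinical meaning: it is the
deviation experts themselves exhibit when contouring the same organ, so a
score of 0.95 reads as "95% of the surface is within expert-level agreement;
5% needs correction".

## Surface representation

Representing the surface by voxels biases the area estimate: foreground
voxels underestimate, background voxels overestimate, and counting voxels
ignores anisotropic spacing entirely. The package instead places surface
points *between* voxels, on a raster shifted by half the voxel spacing on
each axis: raster point $(i,j,k)$ sits at world position
$((i-\tfrac12)d_1, (j-\tfrac12)d_2, (k-\tfrac12)d_3)$ and is surrounded by
exactly 8 voxels. Voxels outside the volume count as background, so every
foreground component — including those touching the volume border — has a
closed, measurable surface.

With binary masks there are only $2^8 = 256$ possible neighbor
constellations. Each constellation is triangulated once by marching cubes
with vertices at exact edge midpoints (the only consistent placement for
binary data at isolevel ½), triangle areas are scaled by the physical
spacing and summed, and the result is stored in a 256-entry look-up table.
Surface extraction is then a single pass assigning each raster point its
constellation's area; the total over the raster is the surface area
$|S_i|$, and the assignment is what makes the whole pipeline $O(N)$.

Two numerical conventions are frozen here:

* **Case table.** The classic marching-cubes triangulation is used, with
  ambiguous (diagonal) constellations resolved deterministically per that
  fixed table. Other published resolutions are equally legitimate and can
  change per-constellation areas slightly; a checksum test over all 256
  areas pins the convention so results cannot drift silently. (On the unit
  grid the single-corner constellation is one equilateral triangle of area
  $\sqrt3/8 \approx 0.2165\,\mathrm{mm}^2$; a lone voxel's closed surface
  is the octahedron of 8 such triangles, area $\sqrt3$.)
* **No gradient interpolation.** Vertices sit exactly at edge midpoints;
  masks are binary, so there is no intensity gradient to interpolate.

The representation is approximately unbiased but not exact: a digitized
sphere's measured area exceeds the analytic $4\pi r^2$ by a few percent at
these resolutions, while area *ratios* behave correctly (doubling the radius
quadruples the area within the test band 3.8–4.2).

## Distances and tolerance rounding

Border-region membership is decided by an exact Euclidean distance
transform computed on the surface raster with physical (anisotropic)
sampling — the separable lower-envelope algorithm, generalized to per-axis
spacing. Chamfer approximations were deliberately avoided: their error is
of the same magnitude as the tolerances being tested (1–3 mm on a 2.5 mm
slice spacing) and would leak directly into membership decisions. Sources
are exactly the raster points with strictly positive local area. The
transform is validated against an $O(n^2)$ brute-force oracle on random
masks up to $16^3$, where it agrees to $10^{-6}$ mm.

Distances between raster points are quantized: only
$D = \{\sqrt{(i d_1)^2 + (j d_2)^2 + (k d_3)^2}\}$ can occur. A requested
tolerance is therefore snapped to the nearest element of $D$ before any
comparison (exact midpoints resolve *down*, the conservative direction that
never enlarges the acceptance band). $D$ is enumerated only up to the
clamped tolerance plus one voxel step; tolerances at or beyond the grid
diagonal saturate the metric at 1 for any two non-empty masks.

Degenerate inputs follow explicit conventions rather than silent defaults:
two empty masks give an *undefined* flag (the formula is 0/0), one empty
mask gives 0, and downstream summaries exclude undefined values and count
them separately — silently mapping them to 0 or 1 would bias cohort
medians for small organs that are legitimately absent from a scan.
Floating-point membership at the tolerance boundary uses a relative guard
of $10^{-9}$ so that distances that are mathematically equal to τ count as
inside.

## Tolerance calibration

The organ-specific τ is derived from inter-observer variation: for every
pair of observers contouring the same organ on the same calibration scan,
the package collects (distance to the other surface, surface-element area)
pairs bidirectionally, pools them across pairs and scans, and takes an
area-weighted percentile — by default the 95th. Area weighting matters on
anisotropic grids, where counting raster points would over-weight in-plane
detail relative to through-plane faces.

Choices that were genuinely open, and how they were settled:

* **The statistic.** The mapping from pooled distances to τ is taken as the
  area-weighted 95th percentile, exposed as a parameter. It penalizes only
  the tail beyond typical expert disagreement; the percentile is
  configurable because other operating points are defensible.
* **Pooling vs per-scan averaging.** Distances are pooled across scans and
  observer pairs before the percentile is taken. Pooling weights each unit
  of surface area equally, is order-invariant, and degrades gracefully when
  scans contribute very different surface areas; averaging per-scan
  percentiles would let a small-area scan dominate.
* **Percentile convention.** The weighted percentile uses the cumulative
  step rule with the "lower" convention at exact boundaries: τ is the
  smallest sampled distance whose cumulative area fraction reaches the
  target. This is deterministic and never interpolates to distances that
  no surface element actually attained. Slab phantoms with flat faces
  offset by δ ∈ {1, 2, 3} mm recover τ̂ = δ exactly under this rule.
* **Calibration and evaluation separation.** Tolerance files carry a
  provenance block (percentile, sample counts); keeping calibration scans
  disjoint from evaluation scans is the caller's responsibility and the
  manifest layout encourages it by role labels.

## Cohort reporting

`summarize_cohort()` produces the statistics of a notched box plot per
organ: type-7 linear-interpolation quartiles (the convention was open; it
is documented and frozen), whiskers at the most extreme values within
1.5 IQR of the quartiles with everything beyond listed as outliers, and a
notch half-width of $1.57\,\mathrm{IQR}/\sqrt{n}$ as the approximate 95%
CI of the median. Model-vs-observer comparisons pair records by
(case, organ), report the mean difference in percentage points, and
classify it against a ±5-point band of non-substantial difference;
unpaired or undefined records are excluded and tallied rather than
dropped silently.

## What the phantoms emulate — and what they do not

All inputs to the tests and examples are synthetic: digitized spheres,
cuboids, full-width slabs, unions of disjoint cubes, sparse slice
labelings, and seeded perturbations (whole-voxel shifts, random voxel
flips). They are generated on a default $64^3$, 1 mm isotropic grid, with
an anisotropic variant at $0.976 \times 0.976 \times 2.5$ mm mirroring
standard planning-CT spacing, so both code paths are exercised at realistic
geometry. Their value is that every expected number is analytic: a
4×4×4 cuboid has 64 voxels; displacing 1 of 20 congruent components moves
the surface DSC to exactly 0.95; slabs offset by δ have an area-weighted
distance distribution concentrated at δ.

What passing these tests does *not* show: phantoms are piecewise-smooth,
single-scale shapes. Clinical contours have thin elongated structures
(optic nerves), multi-lobed and concave shapes (parotids), inter-observer
disagreement that is spatially structured rather than uniform, and
slice-wise contouring artifacts. The metric's *correctness* (areas,
distances, rounding, aggregation) transfers; conclusions about what
numeric surface-DSC value corresponds to "clinically acceptable" for a
given organ do not — they require calibration on real expert contours.

## Problem sizes and runtime

The pipeline is linear in voxel count: table construction is $O(256)$,
surface extraction and the distance transform are single passes over the
$(n_1{+}1)(n_2{+}1)(n_3{+}1)$ raster. The test suite checks this
empirically on sphere pairs of $80^3$ and $101^3$ voxels (a 2× count
ratio) and asserts the runtime ratio stays below 2.5. Property suites use
$20^3$ phantom pairs (50 random pairs across four tolerances) and
brute-force oracle comparisons up to $16^3$, keeping the full suite under
half a minute on one CPU while still crossing every implementation
boundary (anisotropy, border-touching masks, empty masks, randomized
geometry).
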
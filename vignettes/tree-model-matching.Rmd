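---
title: "Tree-model matching of retinal vasculature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-model matching of retinal vasculature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vasctree` matches two retinal images through a hierarchical representation
of their vasculature. This vignette is the package's own account of the
model, the measurement choices behind each feature, the design of the
synthetic scene generator, and the limits of what the shipped tests
demonstrate.

## The tree model

A retinal image, reduced to a binary vessel-centerline raster, a binary
vessel mask, a table of landmark points (bifurcations, branches,
crossovers) and the optic-disc (OD) circle, becomes a *tree model*:

* The OD is the root. Vessel starting pixels are found where the
  centerline crosses the annulus `[r, r + 3]` around the OD center;
  8-connected hits are clustered and the representatives ordered clockwise
  from 12 o'clock.
* Each vessel is one binary tree. A *segment* runs from the OD boundary or
  a splitting landmark to the next splitting landmark (or to a terminal
  tip). At a bifurcation or branch the two daughters become the node's
  children; the left child is the wider daughter. A *crossover* is not a
  split: the trace continues through the crossing along the direction that
  deviates least from its incoming direction, and the crossing's position
  is recorded on the segment.
* Tracing is region growing on the fragmented centerline: landmark pixels
  and their 8-neighbourhoods are boundary zones; the walk flags visited
  pixels, takes the neighbour that minimizes the direction change when
  several are open, and stops at a boundary zone or a dead end. Traced
  paths are bridged through the zone to the landmark pixel itself, so
  segments run landmark-to-landmark and consecutive path pixels are always
  8-adjacent. Daughters are discovered by tracing every untraced pixel
  adjacent to the zone (with a Chebyshev-radius-2 fallback for the rare
  case where two arms funnel through one shared neck pixel).

## The five invariant features

Every node carries `(L/W, Bi/Br, Crossover, Cross pos., Acute angle)`.

**Length** is the Euclidean arc length of the traced path after smoothing
with a 9-pixel moving average (symmetric shrinking windows, so endpoints
are not dragged inward), plus one pixel of end-correction so an
axis-aligned straight run of *n* pixels measures *n*. Raw pixel count is
kept on the segment (`lengthPx`) but is not used for `L/W`: the pixel count
of a digital line varies with orientation by up to √2, which would swamp a
±5 % tolerance under rotation, whereas smoothed arc length is
orientation-stable to ~1 %.

**Width** is measured from the binary mask by perpendicular profiles. A
lightly Gaussian-smoothed copy of the mask (σ = 1) is sampled with bilinear
interpolation along the ray perpendicular to the local (smoothed) path
direction; the per-point width is the distance between the 0.5-level
crossings on the two sides. Per-point widths are then aggregated with three
safeguards, each answering a specific raster artifact:

* the first/last ~11 path pixels are not measured (junction ink — the union
  of the parent, sibling and daughter bands — widens every profile there);
* profiles more than 1.2 px above the lower 35 % quantile are dropped
  (junction or crossing ink only ever *widens* a profile, so contamination
  is strictly upward, while the clean profiles form a tight lower cluster);
* the remaining profiles are averaged with weights proportional to the
  sub-pixel *phase speed* of the band (the smaller tangent component,
  floored at 0.02): where the vessel runs axis-aligned the rendered ink
  width locks to an integer for the whole stretch and carries no
  independent information, and an unweighted mean would inherit that bias.

**`Bi/Br`** is 1 for a bifurcation and 0 for a branch; terminal segments
get 0. **`Crossover`** is 1 iff a crossing lies on the path, and
**`Cross pos.`** is the crossing's path index over the segment's pixel
count (both are pixel counts along the same digital path, so the
orientation dependence cancels in the ratio); segments without a crossing
get 0 for both. A segment of 100 pixels crossed at pixel 70 scores 0.7.

**Acute angle**: the parent and its daughters are sorted by average width;
the angle is the acute angle (in `[0, π/2]`) between the principal
directions of the widest and the narrowest of them, each direction fitted
by least squares over the 36 path pixels nearest the landmark. In the
synthetic scenes the parent is always the widest, so this coincides with
the parent-versus-smallest-daughter reading. The 36-pixel window (rather
than a shorter one) halves the staircase-phase noise of direction fits on
digital lines; with it, angle drift under rotation stays below 0.06 rad
against a tolerance of 0.05·π/2 ≈ 0.079 rad.

Branch points store an angle too: any splitting landmark gets one.

## Matching

`preorderNodes()` linearizes a tree over the *complete* binary tree of the
candidate depth (default 2: levels 0–2, seven positions), with explicit
gaps, so trees of different shapes align position by position.
`nodeMatch()` accepts a position iff the discrete features are equal and
the continuous ones agree within tolerance: `|Δ(L/W)| ≤ 0.05·(L/W)` (the
±5 % rule), `|Δpos| ≤ 0.05`, and `|Δangle| ≤ 0.05·π/2`. The angle tolerance
is an extension — the raster angle also shifts under rotation — and setting
`angleTolerance = 0` recovers the stricter rule. A gap matches only a gap.
`treeDistance()` counts the failing positions: 0 for identity, at most 7 at
depth 2.

`findCorrespondence()` pairs trees greedily in model order: each tree of
model A takes the unmatched tree of B at minimum distance (ties to the
lowest index), even when that minimum is positive — the best match is
relied upon and its distance reported. `modelDistance()` and
`modelDistanceMatrix()` sum the pair distances, adding a full-tree penalty
(7 nodes at depth 2) per unmatched tree; the matrix mirrors its upper
triangle, so it is symmetric by construction.

Normalization (`normalizeModel()`) divides `L/W` by the model-wide maximum
and angles by π/2. It is off by default; a normalized model stores its
parameters and the matcher undoes them before comparing, so matching
results are identical whether or not models are normalized.

## The synthetic scene generator

`generateScene()` emulates the input world with exact ground truth. Its
defaults are the package's study conditions:

* 1024 × 1024 image, OD radius 88 px at the center, five vessels, two
  levels of branching (7 segments per vessel), segment lengths 100–132 px,
  root width 8 px decaying by 0.9 per level with an extra 0.87 on the
  narrower daughter (so the smallest daughter at a junction is always
  unique, and the thinnest rendered vessels stay ≈ 5 px);
* each vessel owns an angular sector; within a vessel every subtree owns a
  disjoint angular wedge, split at each junction with a small buffer —
  this guarantees by construction that sibling *and cousin* branches never
  intersect, which matters because an unmarked intra-vessel crossing would
  silently corrupt tracing;
* segments are gentle quadratic Bézier arcs (sagitta 2–3.5 px) carrying a
  small chirped undulation (amplitude ~0.6 px, period 26–36 px, tapered to
  zero at the endpoints). Perfectly straight strokes are a raster
  degeneracy — their sub-pixel phase is constant, so rendered ink width
  locks to an integer and *no* estimator can recover the true width; the
  curvature and undulation keep the phase sweeping everywhere, as the
  small-scale waviness of real vessels does. This is rendering realism,
  not tortuosity modelling: no tortuosity statistic is emulated or
  measured;
* the mask is the band of pixels within width/2 of the curve; the
  centerline is the rounded, thinned 1-px chain of the same curve;
* crossings are short independent strokes (stand-ins for a segment of a
  vessel not rooted in the modelled field of view) that intersect a
  vessel's root segment at ≥ 0.75 rad, with probability 0.5 per vessel.
  They are rendered and fragment the raster at the crossover but remain
  untraced, so ground-truth tree topology is independent of crossings;
* split landmarks are labelled bifurcation with probability 0.5, branch
  otherwise (label only; the geometry is the same).

The working resolution is deliberately the scale at which the matched
quantities live: published per-segment `L/W` ratios reach ~90, i.e.
segments of order 100+ pixels. At half this scale the binary-raster noise
floor on 5-px-wide vessels exceeds the ±5 % tolerance in the worst case, so
the rotation-invariance property would fail for reasons that say nothing
about the matcher.

`rotateScene()` rotates the ground-truth geometry analytically about the
image center and re-rasterizes both rasters with the generator's renderer;
landmarks and the OD center are rotated analytically and rounded to the
nearest pixel. Resampling the 1-px centerline raster directly
(nearest-neighbour) was rejected because it provably breaks 8-connectivity
on diagonal runs; re-rasterization preserves connectivity while still
introducing exactly the pixel-discretization error that the rotation
experiment studies.

### What the synthetic scenes do not emulate

No gray levels, illumination or noise; no segmentation errors (the rasters
are clean by construction); no pathology; no vessel-width irregularity
along a segment; crossings only over root segments and never between
branches of the same vessel. Passing tests therefore demonstrate the
correctness and rotation robustness of the *representation and matching*
given clean inputs — not robustness to segmentation noise in real fundus
photographs.

## Numerical choices and degenerate inputs

* Landmarks within 2 px of the centerline snap silently, within 5 px with
  a warning, beyond 5 px raise an error.
* Ambiguous trace steps take the neighbour minimizing the direction change
  against the direction averaged over the last 5 pixels, with a 15-pixel
  average as tie-break (single-step directions quantize to 45°).
* The crossover continuation compares candidates by a 10-step probe walk
  against the incoming direction averaged over 20 pixels; the short
  5-pixel average aliases to 45° multiples on shallow lines and can pick
  the crossing vessel instead.
* A crossover with no continuation candidate ends the segment (logged).
* A split with fewer or more than two discoverable daughters attaches what
  was found (logged); recursion stops at 10 levels; traces stop after
  10 × image-width iterations.
* Daughter order: larger width left; ties (practically impossible on
  synthetic scenes) fall back to the smaller angle to the parent, then the
  lexicographically smaller start pixel.
* Profile widths are floored at 1 px (an inked path pixel implies a band
  of at least one pixel; relevant for 1-px test masks, not for generated
  scenes).

## Problem sizes used by the shipped tests

Unit tests run on half-scale scenes (512 px, segments 50–66 px), where
every structural property (topology recovery, determinism, serialization,
matching algebra) already holds. The end-to-end checks run at the default
study scale: rotation invariance over 5 seeds × 6 angles × 5 vessels
× 7 nodes, topology recovery over 10 seeds, the brute-force distance oracle
over 1000 random tree pairs, and pseudometric properties over 500 random
triples.

## Known limitations

* The matcher assumes both images are segmented and landmarked upstream;
  no raw-image processing is included.
* Greedy pairing is order-dependent when several pairs tie; a global
  assignment would be a drop-in replacement but is not what the sequential
  matching procedure describes.
* The inter-image distance sums matched-pair distances plus a penalty per
  unmatched tree; alternative conventions (summing over all pairs) would
  scale differently.
* Scale invariance of `L/W` holds for uniform scaling only, and within a
  few percent once rasterization enters.
* With tolerances > 0 the node-match relation is not transitive, so the
  tolerance-based distance is not a metric; at tolerance 0 it is a
  pseudometric (tested).
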
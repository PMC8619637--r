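---
title: "Methods: stereo endoscope reconstruction and feature tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo endoscope reconstruction and feature tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `endorecon`, and states what the synthetic evaluation does and does
not demonstrate about real endoscope data.

## Camera model and conventions

The package implements the *rectified parallel* binocular model only: both
optical axes parallel, baseline `b` joining the optical centres, equal
focal lengths `f`. A point `P = (X, Y, Z)` in the left camera frame
projects to metric camera-plane coordinates

    xl = f X / Z,   xr = f (X - b) / Z,   yl = yr = f Y / Z

and is recovered from a matched pair through the disparity `d = xl - xr`:

    X = b xl / d,   Y = b y / d,   Z = b f / d.

Conventions fixed once and used everywhere:

* Pixel coordinates `(u, v)` are 0-based, `u` right, `v` down; an image is
  the matrix `img[v + 1, u + 1]` with intensities in `[0, 1]`. Camera-plane
  coordinates are metric (millimetres), obtained via the pixel size, origin
  at the principal point; the 3D frame is left-handed with `Z` forward,
  consistent with the projection's signs.
* The recovery formula is stated with `y = yl = yr`. Detected pairs have
  `yl ≈ yr`, so the implementation uses `y = (yl + yr) / 2`: exact when
  rectified, and a symmetric average of residual vertical noise otherwise.
* The rectified epipolar constraint degenerates to "equal vertical
  coordinates"; the gate accepts `|yl - yr| <= vertical_tolerance`
  *inclusively*. No numeric tolerance is prescribed by the model, so the
  default is two pixels (`2 * pixel_size`), generous enough for
  integer-pixel detections and tight enough to reject cross-row confusions.
* Disparity is always computed from the stored pair, never cached, so it
  cannot drift out of step with the coordinates.
* Convergent (verged) rigs, lens distortion and rectification from raw
  video are out of scope; inputs are assumed rectified.

## Feature detection and patches

The matcher is detector-agnostic (it never uses descriptors), so the
standard FAST-9 segment test with greedy non-maximum suppression stands in
for any corner detector. Corners are scored by summed ring contrast beyond
the threshold (default 0.08 on unit-range intensities). The suppression
radius defaults to 8 px — the half-width of the classification patch — so
at most one feature survives per patch footprint, which keeps one feature
per textured marker in the synthetic scenes.

"A 16×16 patch centred on the feature" is ambiguous for an even size; the
package fixes the feature pixel at patch index `(8, 8)` (0-based) with the
half-open window `[-8, +8)` in both axes. Features closer than 8 px to a
border are discarded so the patch always fits.

## The patch classifier

Matching is classification: a compact convolutional network maps each
16×16 patch to one of `n` feature categories. The architecture is fixed in
shape — two 3×3 stride-1 same-padded convolution layers (64 and 128 kernels
by default), each followed by ReLU and 2×2 max pooling (16 → 8 → 4), then
a 1024-node fully connected ReLU layer with dropout (rate 0.5) and a final
fully connected softmax layer with `n` outputs. The kernel size, padding,
dropout rate and optimizer are not dictated by the model itself; 3×3
same-padding is the minimal standard choice that makes the two pools give
a 4·4·128 flatten, and Adam (default 1e-3, 30 epochs, batch 64) is the
standard small-data optimizer. All randomness (initialization, shuffling,
dropout) is driven by one seed, so training is exactly reproducible;
inference disables dropout and is deterministic. The network is implemented
as dense BLAS matrix products (shift-gather convolutions), sized to train
on a CPU in minutes.

Per image, a *match matrix* keeps for every category the single feature
with the highest classification probability. The update rule uses a strict
inequality, so the earliest-seen feature wins exact ties, and traversal
order is the (deterministic) detector output order. Categories retained in
both views, and passing the epipolar and positive-disparity gates, become
match pairs.

### Category selection

The training protocol labels patches by cross-frame identity, which the
source material leaves unspecified. The package derives identities by
greedy nearest-neighbour chaining of detections across consecutive frames
(link radius 5 px by default, globally-closest pairs first); chains present
in at least `lambda * K` of the `K` training frames become categories. The
selection threshold `lambda` (default 30 %) is therefore interpreted as a
*persistence fraction* — the plainest reading consistent with one fixed
threshold producing a stable category count.

## Delaunay triangulation

The triangulator is written from scratch. Construction is Bowyer–Watson
point-by-point cavity insertion: all triangles whose circumcircle strictly
contains the new point are deleted and the cavity boundary is reconnected
to the point. Lawson's local optimization procedure (LOP) is provided as a
separate pass that swaps the diagonal of any adjacent pair whose opposite
vertex invades the circumcircle; on a Delaunay input it performs zero
flips, and it restores the Delaunay triangle set from flip-perturbed
inputs. Cavity insertion is the default construction path because pure
flip-based construction misbehaves on ring-shaped point sets; constrained
or ring-shaped domains are out of scope and the output is always the
convex-hull triangulation.

Numerical choices:

* Predicates (orientation, incircle) use floating point with relative
  tolerance bands (1e-12, scaled by coordinate magnitude), not exact
  arithmetic. Image-scale inputs are well conditioned; genuinely adversarial
  near-degenerate inputs are a documented limitation.
* Cocircular quadruples: the incircle band reports `cocircular`, the cavity
  treats cocircular as *outside*, so insertion order decides the diagonal.
  Uniqueness holds only in the absence of four cocircular points.
* The bootstrap super triangle is sized 10× the bounding-box diagonal and
  its three synthetic vertices carry negative indices during construction,
  making their removal unambiguous. Crucially, incircle tests on triangles
  containing super vertices are evaluated *symbolically at infinity* (the
  exact limit of the determinant as those vertices recede along fixed
  directions). A finite super triangle, however large, truncates the
  enormous circumcircles of near-collinear hull triples and can leave
  notches in the hull; the symbolic limit removes that failure mode
  entirely, which property tests over hundreds of random sets confirm.
* Duplicate points are rejected (distance below 1e-9), not merged; callers
  deduplicate first. Fewer than 3 points or an all-collinear set is an
  error.

3D point clouds are triangulated by *plane projection*: project onto the
left imaging plane via the camera model, triangulate the projections,
lift the connectivity unchanged. Direct 3D dissection is deliberately not
implemented (cost, and endoscope scenes show little occlusion that would
defeat projection).

## Surface mesh

Matched pairs that survive the gates are recovered to 3D, triangulated by
plane projection, and textured with per-vertex UV coordinates taken from
the left pixel position (pixel centres, vertical axis flipped for the OBJ
convention). The mesh smoothing step is described in the source material
only as smoothing "the joint of the triangle area"; the package implements
the simplest standard operator matching that intent — uniform-weight
Laplacian smoothing of interior vertices (default 2 iterations, weight 0.5,
off by default), boundary vertices fixed, connectivity and UVs untouched.
Extending the border of the restored surface is a rendering cosmetic and is
not implemented. Writers: text OBJ (+ MTL + PNG texture) and
binary-little-endian PLY with double-precision x, y, z, u, v, so a PLY
round trip is bit-exact.

## Tracking

Tracking is *sample-free*: every frame is re-detected, re-classified and
re-matched independently, exactly the strategy that avoids both the fixed
sample frame (appearance drift) and adjacent-frame chaining (unrecoverable
failure propagation). A frame where the tracked category is missing from
either view, or fails a gate, is recorded blank; later frames are computed
as if nothing happened, which the failure-isolation test asserts literally.

Gap filling replaces a blank by the mean of its adjacent observations. The
stated rule covers an isolated blank; the package generalizes to runs of
blanks by scanning left to right and averaging the nearest non-blank
neighbour on each side, which reduces to the original rule for single
blanks. Leading/trailing blanks stay blank. The operation is idempotent and
never touches observed entries.

Motion summaries report per-axis ranges and a dominant period. The period
is the first significant local maximum of the mean-removed autocorrelation
of the axis with the largest range, normalized by the number of overlapping
terms (so a pure sinusoid gives ~cos(2πk/T) without triangular damping),
refined by parabolic interpolation through the peak and its neighbours.
The significance threshold is 0.5: high enough that slowly wandering
aperiodic paths do not produce a spurious period over the window lengths
used, low enough that two observed cycles suffice. The rate per minute is
`60 · fps / period`. Estimation requires at least 8 contiguous non-blank
entries and a maximum lag of 2/3 of the window.

## The synthetic scene generator

The generator emulates the reference acquisition at the numbers it states:
52 surface markers, 25 fps, deformation period 18.75 frames (4/3 Hz, i.e.
80 cycles per minute), focal length 1 mm, baseline 0.99 mm. Remaining
choices are the package's own, fixed once:

* **Geometry.** Base depth 10 mm, pixel size 1.5 µm, 320×320 px frames.
  This puts the nominal disparity at ≈ 66 px, so one pixel of disparity
  quantization is ≈ 1.5 % of depth and the *mean* 3D error of
  integer-pixel detections sits well below 2 % of depth — the regime in
  which a sparse feature pipeline is meaningfully testable without
  sub-pixel refinement.
* **Motion.** Regular markers follow coherent-phase sinusoids (per-marker
  phase jitter ±0.25 rad, as neighbouring points on a beating surface move
  nearly together): lateral amplitude 0.15 mm — the reported lateral ranges
  scaled down to stay inside the synthetic field of view — and depth
  amplitude 0.01 mm, matching the reported sub-hundredth-millimetre depth
  ranges directly. One marker is "irregular": driven by Gaussian-smoothed
  noise at twice the lateral amplitude (5× in depth), with its per-frame
  step capped at ~3.5 px so nearest-neighbour chaining keeps it in one
  chain; it is placed at the layout centre with extra clearance, which also
  makes it land among the centroid-nearest tracked points, mirroring the
  role of the irregular tracked point in the reference protocol.
* **Appearance.** Each marker is a distinct seeded pattern: one dominant
  central Gaussian (the detection anchor), 3–4 weaker bright satellites
  within 4.8 px and one dark blob, over a static low-frequency background
  texture. Satellites sit inside the 8 px suppression radius so detection
  returns exactly one corner per marker, while the patch retains enough
  structure to separate 52 classes. The same pattern is rendered at the
  projected position in both views, so both detectors latch onto the same
  pattern point and disparity errors largely cancel.
* **Not emulated:** occlusion, perspective patch distortion, specular
  highlights, lens distortion, illumination change, real tissue texture.
  Passing the synthetic study therefore demonstrates the *mechanics* of the
  pipeline (matching, geometry, triangulation, tracking, bookkeeping) under
  controlled appearance, not robustness to real surgical imagery; on real
  video the classifier would face appearance drift the generator does not
  produce.

Scenes are bit-reproducible from the seed; ground-truth image positions
are produced by the same projection code path as the reconstruction, so
truth and estimate are mutually convertible with zero residual.

## Problem sizes

The shipped study — also what `scripts/acceptance.R` re-runs — uses the
default scene (52 markers, 60 frames), trains on the first 20 frames
(~1 040 labelled patches, 30 epochs) and evaluates matching, reconstruction
and tracking on frames 21–60; it completes in a few minutes on one CPU
core. Unit fixtures use 12–20 markers, 6–16 frames and narrower networks.
Property tests run the triangulator against brute-force oracles at n ≤ 60
(empty-circle scans) and exhaustive flip-graph enumeration at n ≤ 8
(max-min-angle optimality).

## Known limitations

* Predicates are floating-point with tolerance bands; exact-arithmetic
  robustness is not claimed.
* The classifier caps the number of match pairs at `n` categories by
  design; dense or descriptor-based matching is out of scope.
* Integer-pixel detection bounds 3D precision; no sub-pixel corner
  refinement is performed.
* Tracking assumes the trained category set remains valid across the
  tracked span; markers that change appearance beyond the training
  distribution go blank rather than being re-acquired.
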
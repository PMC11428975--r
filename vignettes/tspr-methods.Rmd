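---
title: "Two-step progressive registration: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step progressive registration: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tspr)
```

## The problem

A labelled anatomical head atlas — a volume in which every structure of
interest carries an integer label — can localize organs in a clinical CT or
MRI head scan if a spatial map from atlas coordinates to subject coordinates
is known. Heads differ between people mainly by position, orientation and
overall size, so a uniform-scale similarity transform

$$p' = s\,R\,p + t, \qquad s > 0,\; R \in SO(3),$$

is an adequate global model: it cannot follow local anatomical variation, but
it is enough to *point at* a structure (orbit, pituitary fossa, temporalis
compartment) on the correct slices, which is the navigation task this package
addresses. The map is estimated from the exterior head surface only, which
both CT and MRI delineate sharply against air, so no cross-modality intensity
model is needed.

## The two-step procedure

Surfaces are represented as point clouds extracted slice by slice
(`surface_from_volume()`). Registration uses the iterative closest point
(ICP) scheme: alternate (i) nearest-neighbour pairing of the moving cloud
with the target cloud and (ii) a closed-form least-squares fit on the current
pairs, until the root-mean-square pair distance stops improving. The rigid
fit uses the quaternion eigen-method (an SVD Procrustes solver with a
determinant guard is provided as a cross-check; the two agree to $10^{-9}$ in
the test suite), the similarity fit the Umeyama estimator. Both are exact
minimizers for fixed pairs, which makes the recorded `rms_history`
non-increasing — asserted on every run in the tests.

Plain ICP started far from the solution converges to a local extremum — the
classic failure mode being the nose settling into an ear. The two-step
procedure avoids this by registering features in a fixed order:

1. **Spatial orientation (once).** The operator marks a rectangle over the
   eye–nose region on a face-on depth map of each surface
   (`project_depth()`), and 4 × 7 = 28 feature points are sampled on each
   grid (`sample_feature_grid()`). The orientation step then produces a
   *rigid* transform `m1` aligning the atlas face onto the subject face.
2. **Spatial scale (progressively, n times).** A circular band of the
   exterior contour bracketing the face (`select_band()`) is pushed through
   the accumulated transform and registered to the subject band by
   *similarity* ICP; each pass contributes `m2_x`.

The final map composes the steps in order of application,
`final = m2_n · … · m2_1 · m1` under the column-vector convention
(`compose_transforms()`), and the composition is stored factored so the
invariant `final = compose(m1, m2 list)` holds exactly. The number of scale
passes is capped at 5: orientation is registered once and repeating it, or
stacking many similarity passes, over-fits the band without new information.

### Why the orientation step is more than "ICP on 28 points"

Implementing step 1 literally as ICP between the two 28-point grids fails two
ways, both reproducible on the phantom:

* **Spin blindness.** Both grids are sampled on axis-aligned rectangles of
  their projection planes. If the subject's face is rotated *in* that plane,
  node $(r, c)$ of one grid no longer corresponds anatomically to node
  $(r, c)$ of the other, and — worse — no rigid alignment of the two sampled
  sets encodes the spin at all: the sets themselves were sampled on unrotated
  lattices. Measured on the phantom, a 25° in-plane rotation leaves the
  paired fit with a ~25° error that grid ICP cannot repair.
* **Scale bias.** A rigid fit of two faces that differ in size by 8–10%
  trades the size mismatch for a tilt; measured bias is several degrees,
  which the later scale passes cannot fully undo (they converge to a nearby
  local minimum of the discrete clouds).

The orientation step therefore (a) seeds from the paired node fit, which does
recover out-of-plane tilt; (b) multi-starts over spins about the viewing axis
in 15° increments, plus two 180° flips that cover the face/back ambiguity of
a projection, scoring each candidate by a short *rigid* ICP of the dense
atlas face patch against the full subject surface (rigid scoring on purpose:
a similarity fit at a wrong pose can shrink the patch into the surface and
fake a low rms); (c) polishes the winner with a scale-tolerant (similarity)
ICP; and (d) keeps only the rigid part — the fitted rotation plus the
translation that preserves the image of the face-patch centroid — leaving all
scaling to step 2. `m1` is rigid, as the model requires; it is merely
*estimated* through a scale-tolerant fit. With this step the phantom suite
recovers rotations to ≤ 0.3° across the whole study envelope, against 3–13°
for the literal reading.

### Bands

The moving band should be a slab that brackets the eye–nose region of the
atlas (50 mm tall by default in the examples). The *target* band may — and
usually should — be generous: correspondences run moving → target only, so
the target merely has to contain the moving band's anatomy, and a full-extent
target band avoids slab-edge mismatches when the subject is tilted. A
warning is raised when the two band point counts differ by more than 3:1.

## Contour extraction

Each slice is binarized (inclusive threshold), padded, hole-filled, opened
with a disc, reduced to its largest connected component, cropped back, and
the contour is taken as the body mask minus its erosion. Defaults: threshold
−300 HU for CT (air/skin boundary), per-slice Otsu otherwise; opening radius
3 px (removes headrest-sized impurities without eating facial features);
erosion radius 1 px, which with a Euclidean disc is the 4-neighbour cross, so
the contour is exactly the set of body pixels with a non-body 4-neighbour —
the property the tests assert against a brute-force boundary oracle. Slices
whose post-opening body is smaller than `min_area` (64 px) are treated as
body-free and flagged rather than erroring: clinical stacks legitimately
contain such slices. The opening deliberately bridges narrow concavities, so
a small fraction (~1% on the phantom) of contour voxels sit one voxel inside
sharp depressions such as eye-socket rims.

## ICP numerics

`icp_control()` defaults: `max_iter = 300`, `tol = 1e-6` mm on the change in
rms, moving clouds thinned to at most 3000 points by deterministic
even-index subsampling. The tolerance is deliberately tight: on voxelised
surface clouds the rms decays through a long shallow plateau, and stopping at
`1e-4` mm leaves the pose measurably short of the optimum (≈ 1.6° on the
phantom) while the extra iterations cost fractions of a second at these cloud
sizes. Correspondence ties break deterministically to the lowest target
index. A degenerate similarity update (collapsed correspondences driving the
scale non-positive) falls back to a rigid update for that iteration, which
preserves monotonicity. The pipeline contains no randomness; only the
phantom's noise fields are seeded.

## Label mapping and evaluation

`map_roi()` pulls labels: every subject voxel centre is sent through the
inverse transform and looked up in the atlas label grid (nearest neighbour).
Pulling avoids the holes that forward voxel splatting leaves wherever the
scale differs from 1. Localization is scored per axial slice by recall —
the fraction of the reference (expert-annotated, or phantom ground-truth)
ROI area covered by the mapped ROI, areas counted in voxels, slices without
reference area skipped — and summarized by max, min, median, mean and the
normal 95% confidence interval $\bar X \pm 1.96\,s/\sqrt n$ with the sample
($n-1$) standard deviation, omitted for $n < 2$. Recall is asymmetric by
design: growing the mapped region can only raise it. It measures coverage
for navigation, not segmentation quality; Dice-style symmetric overlap is
out of scope.

## The synthetic phantom

`generate_atlas()` rasterizes an analytic head: an ellipsoidal cranium
(semi-axes 40 × 50 × 42 mm), a conical nose along the anterior axis whose tip
protrudes ~15 mm beyond the ellipsoid — as a real nose does relative to the
facial plane, and enough that the nose tip stays the nearest-to-viewer point
under tilts up to ~30°, which face-window selection relies on — and two
spherical eye-socket depressions. Default grid: 96 × 144 × 128 voxels at
1 mm, sized so the head plus nose fits with margin. Embedded ROIs mirror the
clinical test structures by role: a midline sphere (pituitary), paired tubes
(optic nerves), a lateral tube (temporalis). `derive_subject()` maps the
atlas through a known similarity transform (rotation about the head centre,
then translation), resamples onto a grid framed around the transformed head
with a 10 mm margin — the way a scanner's field of view frames the patient;
a fixed grid clips the face and invalidates the experiment silently —
applies optional local defects (a zeroed sphere for missing teeth, a
foreground sphere for a post-trauma bulge) and seeded Gaussian noise, and
returns the exact transform as ground truth.

What the phantom does *not* emulate: real anatomical shape variation (it is
the *same* head on both sides, so recovery errors measure the algorithm, not
inter-subject anatomy), soft-tissue/bone intensity structure, slice-thickness
anisotropy artefacts, and partial scan coverage. Passing the recovery suite
therefore demonstrates correctness of the estimator under the similarity
model, not clinical accuracy on real heads.

## Problem sizes and test design

The test suite and the acceptance script run the full pipeline on the default
phantom (≈ 1.8 M voxels, ≈ 17 k surface points): five recovery draws spanning
scale 0.90–1.10, rotations to 30°, translations to 30 mm (each ≈ 30 s), one
half-voxel-jitter draw, one back-to-front (180° yaw) pair for the
local-extremum comparison, and property checks (fit oracles at $10^{-9}$,
rms monotonicity over 20 seeded runs, brute-force boundary and
nearest-neighbour oracles). Thresholds asserted: rotation ≤ 2°, scale ≤ 2%,
translation ≤ 2 voxels at zero noise; rotation ≤ 5° under 0.5-voxel jitter;
≤ 1° added rotation error for a defect outside the feature regions.

## Known limitations

* The global similarity model cannot express anisotropic growth or local
  deformation; mapped ROIs on real patients lean on the eye–nose region
  being registered well and degrade with distance from it.
* Face-window and band selection are operator inputs. The multi-start makes
  the orientation step robust to pose, but a window that misses the face
  entirely is unrecoverable; automatic facial-landmark detection is out of
  scope.
* Depth-map sampling assumes the face is visible along one of the six axis
  directions; oblique acquisitions would need a resampling to near-axial
  orientation first.
* The contour pipeline assumes the body is the largest bright component per
  slice; headrests wider than the opening element would need a larger
  opening radius.
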
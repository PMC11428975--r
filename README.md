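# tspr — two-step progressive registration of head surfaces

`tspr` registers a labelled anatomical head atlas to a clinical tomographic
volume (CT or MRI) and propagates the atlas's region-of-interest (ROI) labels
into the subject scan, so that a non-specialist reading the scan can see at a
glance *where* a structure — an optic nerve, the pituitary, a temporalis
compartment — lies on each slice. It is aimed at atlas-guided navigation
(rapid organ localization), not at segmentation.

## Method

Heads differ between people chiefly by position, orientation and overall
size, so the atlas-to-subject map is modelled as a uniform-scale similarity
transform `p' = s R p + t` (`s > 0`, `R` a rotation), carried as a 4×4
homogeneous matrix with last row `[0 0 0 1]`. The transform is estimated
from the exterior head surface only, extracted slice-by-slice by binary
morphology (binarize → fill → pad → open → largest component → crop →
body minus eroded body), which makes the method modality-agnostic: both CT
and MRI separate skin from air sharply.

Estimation is a two-step iterative-closest-point (ICP) procedure that exists
to dodge the local extrema of plain ICP (the nose settling into an ear):

1. **Spatial orientation, once (rigid).** 28 facial feature points (a 4×7
   grid over the operator-chosen eye–nose window of a face-on depth map) are
   sampled on each surface. Their paired fit seeds a deterministic
   multi-start (spins about the viewing axis and face/back flips) of a
   scale-tolerant ICP of the atlas face patch against the subject surface;
   the rigid part of the winner is the orientation transform `M1`.
2. **Spatial scale, progressively (similarity).** A circular band of
   exterior contour rings bracketing the face is pushed through the
   accumulated transform and registered to the subject band by similarity
   ICP, once or several times (`M2_1 … M2_n`, capped at 5).

The final map is the composition in order of application,
`M = M2_n ⋯ M2_1 · M1`. Rigid fits use the closed-form quaternion
eigen-method (Horn), similarity fits the Umeyama estimator; both are exact
minimizers on fixed correspondences, so the per-iteration rms is provably
non-increasing.

Localization quality is scored per axial slice by **recall**
`|mapped ∩ reference| / |reference|` (areas in voxels) and summarized by
max / min / median / mean and the normal 95% confidence interval
`mean ± 1.96 s / √n` (sample SD, omitted for n < 2).

Because real atlas and hospital volumes cannot ship with the package, a
deterministic synthetic head phantom (ellipsoidal cranium, protruding nose,
eye-socket depressions, embedded ROI labels) stands in for both sides:
`derive_subject()` produces a subject from the atlas under a *known*
similarity transform, so every pipeline stage is testable against ground
truth.

## Worked example

Generate a phantom pair (subject = atlas scaled 0.93, yawed 10°, shifted
20 mm), register, and map the optic nerve:

```r
library(tspr)

atlas   <- generate_atlas(phantom_spec(seed = 7))
subject <- derive_subject(atlas$volume, atlas$labels,
                          scale = 0.93, rotation = c(10, 0, 0),
                          translation = c(20, 5, 0), seed = 7)

surf_atlas   <- surface_from_volume(atlas$volume,   contour_params(threshold = 50))
surf_subject <- surface_from_volume(subject$volume, contour_params(threshold = 50))

# operator stand-in: a 42 x 30 mm face window centred on the nose tip
face_rect <- function(surf, view = "-y") {
  dm <- project_depth(surf, view, 1)
  ij <- which(dm$grid == min(dm$grid, na.rm = TRUE), arr.ind = TRUE)[1, ]
  u <- dm$u0 + (ij[1] - 1); v <- dm$v0 + (ij[2] - 1)
  c(u - 21, v - 10, u + 21, v + 20)
}
nose_z <- surf_atlas[which.max(surf_atlas[, 2]), 3]

fit <- tspr(surf_atlas, surf_subject,
            atlas_rect   = face_rect(surf_atlas),
            subject_rect = face_rect(surf_subject),
            atlas_band   = c(nose_z - 20, nose_z + 30),
            subject_band = range(surf_subject[, 3]),
            n_scale_steps = 3)
summary(fit)
```

```
Registration steps:
                 step    rms_mm iterations converged
  orientation (rigid) 0.5359966         88      TRUE
 scale 1 (similarity) 0.5231744         20      TRUE
 scale 2 (similarity) 0.5231696          3      TRUE
 scale 3 (similarity) 0.5231696          2      TRUE

Final transform:
       [,1]    [,2]    [,3]    [,4]
[1,] 0.9143 -0.1632 -0.0002 37.1253
[2,] 0.1632  0.9143 -0.0020  0.8674
[3,] 0.0006  0.0019  0.9288  3.1539
[4,] 0.0000  0.0000  0.0000  1.0000

scale 0.9288, rotation angle 10.12 deg, translation (37.13, 0.87, 3.15) mm
Residual surface rms: 0.552 mm
```

The generating parameters (scale 0.93, 10° yaw) are recovered to 0.14% and
0.12°; the residual 0.55 mm rms is the voxelization floor of 1 mm clouds.
Mapping the optic nerve through the fitted transform and scoring against the
subject's ground-truth labels:

```r
mapped <- map_roi(atlas$labels, "optic_nerve", fit$transform, subject$volume)
ref    <- roi_mask_from_labels(subject$labels, "optic_nerve")
summarize_recall(recall_per_slice(mapped, ref))
```

```
<recall_summary> n = 6 slices
  max 100.00%  min 95.51%  median 99.55%  mean 98.75%
  95% CI [97.311%, 100.184%]
```

A command-line front end over the same functions (phantom generation,
contour extraction, feature sampling, registration, ROI mapping, recall
evaluation) is installed at `cli/tspr.R` inside the package directory; see
its header for the subcommands.

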
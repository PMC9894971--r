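---
title: "Generating labelled X-ray training data from CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating labelled X-ray training data from CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxray)
```

## The problem

Industrial X-ray inspection must decide, from a single radiograph, whether a
product contains a foreign object (FO): a pebble stone in a lump of
modelling clay, an air pocket in an avocado, a bone in a fillet. Training an
image classifier for this task normally requires thousands of annotated
radiographs covering every combination of base-object shape and FO
placement. `foxray` implements an alternative: CT-scan one (or a few)
products, segment the reconstructed volume into materials, deform that
labelled volume algorithmically to synthesize many plausible product
variants, and forward-project each variant into labelled single-view
radiographs. Because the 3-D model is known, ground truth for every
generated image is computed, not annotated.

The pipeline is: reconstruction → segmentation → artificial sample
generation → forward projection → detector noise → labelled dataset →
classifier evaluation. Reconstruction itself (FDK) is out of scope: the
package takes reconstructed attenuation volumes, already-segmented label
volumes, or generates synthetic phantoms.

## Volumes and conventions

A `labeled_volume` is a 3-D integer grid where every voxel carries exactly
one material label (0 = exterior). Grids are isotropic; in memory they are
R arrays `dim = c(nx, ny, nz)` and the voxel with index `i` along an axis
covers `[(i-1) vs, i vs)` mm with its centre at `(i - 0.5) vs`. Membership
of a voxel in a geometric shape is always decided by its centre — there are
no partial-volume labels, matching the segmented-volume model. On disk a
volume is a multi-page TIFF (one page per z-slice) with a JSON sidecar
carrying the voxel size and label names.

A `material_table` maps material names to mean linear attenuation
coefficients (mm^-1), so any segmented volume converts back to physics via
`labels_to_attenuation()`. The phantom defaults (clay 0.06, stone 0.25,
flesh 0.05, peel 0.07, pit 0.08, air 0 mm^-1) are configuration, chosen for
a plausible contrast ordering (a stone ~4x denser than clay; fruit tissues
close together; air transparent), not physical constants.

## Phantoms: what the generator emulates and what it does not

The phantom module exists so every downstream stage is testable without
real scans. It emulates the *class structure* of two sample populations,
not their true shape statistics — real clay pieces and avocados have shape
distributions the generator does not attempt to match. Passing tests
therefore demonstrate that the pipeline is internally sound (labels,
conservation laws, class rules, learnability), not that a classifier
trained on phantoms transfers to real radiographs.

* `make_clay_phantom()`: the base object is a star-shaped blob whose radius
  is modulated by random low-order angular harmonics (roughness 0.18,
  radius ~0.32 of the grid edge), so the shape is smooth, unpredictable and
  varies with the seed — emulating clay remolded before every scan. Foreign
  objects are 0–2 random convex ellipsoids (semi-axes 6.5–9.5% of the grid
  edge, random orientation) placed fully inside the clay and kept
  26-disconnected from each other so component counting is well defined.
  Placement is rejection-sampled with a bounded retry budget.
* `make_avocado_phantom()`: concentric deformed-ellipsoid layers — a thin
  peel (~2% of the grid edge), flesh, and an offset pit — with the air
  phase placed as random small ellipsoidal pockets inside the flesh until a
  target air volume fraction is reached, then trimmed to within ±10%
  relative of the target. Air fractions are capped at 5%, bracketing the 1%
  class boundary.
* `make_ball_phantom()`: the didactic sphere-in-ball example, a unit sphere
  containing a smaller ball, parameterized by the inner radius and the
  centre-offset vector (a 4-dimensional configuration space). Containment
  (`|offset| + r <= 1`) is enforced at construction. This phantom has
  analytic volume ratios and chord lengths, so it anchors the projector and
  voxelization tests.

## Segmentation

`segment_materials()` thresholds the attenuation histogram with multi-level
Otsu (exhaustive maximization of between-class variance over a binned
histogram; 256 bins for up to two cuts, 64 beyond that to keep the search
cheap). The `n_materials` cuts produce `n_materials + 1` classes and the
lowest class is the exterior. We deliberately threshold over *all* voxels
rather than masking zeros first: with exactly-zero padding the zero voxels
form their own histogram mode and the lowest class absorbs them, while
excluding them would leave the lowest Otsu class to swallow the faintest
material whenever the exterior is exactly zero (the piecewise-constant
round trip would then fail). Cleanup follows the classical recipe:
per-class binary opening (6-neighbourhood, default radius 1), a
minimum-component-size speckle filter (default 27 voxels, i.e. a 3x3x3
cube) against reconstruction artifacts, and an optional convex-hull closure
of the object support, computed per z-slice with 2-D hulls. The closure is
appropriate for convex bases (clay) and should stay off where concavities
are real (avocado); voxels inside the closed support that fell to exterior
are relabelled as the base material (the largest class), so every voxel
ends with exactly one label. `estimate_attenuations()` then recovers the
material table as per-label means of the reconstruction, the segmentation
acting as a mask.

## Deformation models

Two models generate shape variety:

**Affine transforms** (`affine3d`, `sample_affine`,
`apply_affine_to_labels`). The linear part composes scale, shear and
rotation in a fixed order (`R %*% Sh %*% S`), followed by a translation;
each enabled component is drawn uniformly from its `affine_ranges`. Scale
ranges sit in a neighbourhood of 1 and shear around 0 so a deformed object
still resembles the product; the package defaults (whole-object scale
0.92–1.08, shear ±0.08; FO scale 0.85–1.15, shear ±0.1, rotation free,
translation up to 12 mm) are configuration values chosen by us — the
original acceptable ranges for real products are an expert's judgement and
are not reproduced here. Label volumes are resampled by *inverse-mapped
nearest-neighbour*: each output voxel pulls the label at the
inverse-transformed position, so labels stay categorical. The linear part
acts about the target's centroid unless a centre is given, keeping an FO in
place unless a translation is drawn. In FO mode vacated voxels become base
material (the FO is interior to the product) and moved voxels landing
outside the base are discarded; moving the whole FO outside the base is an
error, and random draws are rejected-and-resampled with a bounded retry
budget (100 by default) — an automated stand-in for the manual screening of
deformed volumes. In whole-object mode vacated voxels become exterior.

**Region removal** (`region_removal`). The target material's voxels are
partitioned by drawing `K` seed voxels uniformly without replacement and
assigning every voxel to its Euclidean-nearest seed (distances in mm, ties
to the lowest seed index — a deterministic Voronoi partition of the voxel
set). Clusters are then removed, either exactly `n_remove` of them or
greedily in random order until the retained fraction first drops to the
target, and removed voxels are relabelled to a replacement material (flesh
for air, clay for stone). This changes shape considerably while preserving
position — the right model when FO location is meaningful, as for air
pockets that form in specific regions of a fruit.

Two derived operations implement the generation strategies' primitives:
`remove_object()` (relabel a whole material or one 26-connected component)
and `duplicate_object()` (add an affine-transformed copy of a
single-component FO, rejecting copies that overlap the original or leave
the base).

## Generation strategies and ground truth

Class rules are recomputable functions of the volume, never stored state:
the clay class is the number of 26-connected stone components capped at 2;
the avocado class is 1 iff the air fraction of the whole fruit strictly
exceeds 1%. The strict inequality is a boundary convention we fixed and
test. Every `sample_record` carries its class, and `build_dataset()`
re-verifies the stored class against the rule before projecting — a
mislabelled record is an error, so ground-truth soundness is enforced
structurally.

*Basic modification* derives all classes from real samples of one class by
FO removal: a two-stone clay volume yields classes {2, 1, 0} (remove one
randomly chosen stone, then both), so `N_train = 3 p S_train` images; a
class-1 avocado yields {1, 0} via air region removal, `N_train = 2 p
S_train`. The class-0 avocado *must retain some air* strictly inside (0,
1%): a network shown only airless class-0 examples would misclassify real
class-0 fruit that contains a little air. The retained fraction is drawn
uniformly from (0.1%, 0.9%) by default — the distribution is exposed as
configuration because results depend on it and no canonical choice exists.

*Generation from one* applies the deformation models to a single volume,
`G` artificial volumes per real scan (`N_train = p G S_train`). Each clay
round draws a whole-object affine (resize + shear), duplicates the stone
under an FO affine (resize, shear, rotation, translation) to get class 2,
then removes stones for classes 1 and 0; avocado rounds produce a class-1
affine variant and a class-0 region-removal variant. `G` counts *volumes*,
not rounds — the round-robin allocation keeps output classes balanced
within one. A round whose duplication cannot be placed is skipped with a
warning and a bounded total retry budget.

## Forward projection

`forward_project()` computes Beer's-law line integrals with Siddon's exact
radiological-path traversal of the voxel grid: every voxel crossed by a ray
contributes its attenuation times the exact chord length, so projections of
piecewise-constant volumes carry no step-size error and analytic oracles
(chords through a voxelized ball) hold to voxelization accuracy. Parallel
beam is the default — it is desk-scale and its oracles are exact; cone beam
(point source, flat detector) sits behind the same interface since the
methodology is geometry-agnostic. Angles default to `p = 72` uniform views
over [0°, 360°). An object projecting outside the detector is an error
(silent truncation would corrupt a training set), checked conservatively on
the bounding box of occupied voxels.

Numerical notes. (1) Rays that lie exactly on voxel faces are nudged by
1e-9 voxel into the grid; with a detector pitch commensurate with the voxel
size whole ray columns can sit on faces and the nudge then picks the inner
voxel on one side of the object and the outer on the opposite side — a
half-voxel alignment artifact, not a traversal error. Choosing a pitch
incommensurate with the voxel size (as the defaults do) avoids it. (2) A
single ray per pixel is exact for chord oracles but aliases at object rims;
`supersample = 2` averages a 2x2 sub-grid per pixel, approximating the
physical pixel-aperture integral. With it, projections of a centred sphere
at 256^3 agree across angles within 1% relative RMS.

Beer transforms: `attenuance_to_counts()` maps line integrals to noiseless
photon counts `I0 = I_incident exp(-integral)`; `counts_to_attenuance()`
inverts with a one-count floor before the log. The incident count defaults
to `I_incident = 1e4` and classifiers consume attenuance-domain images;
both are configuration, as no canonical values exist for them.

## Detector noise and calibration

Pixel noise is mixed Poisson–Gaussian:

    I_noisy ~ (1/lambda) * Poisson(lambda * I0) + Normal(0, sigma^2)

with moments `E[I] = I0` and `Var[I] = I0/lambda + sigma^2`. `lambda` is
the photon gain and `sigma` the read-out standard deviation in counts; the
package default `lambda = 1.17, sigma = 20` is the clay-rig calibration
used throughout (no separate avocado values are published, so both cases
share it). The Poisson mean `lambda * I0` is used without rounding, and the
sum is clipped at zero — counts are physical and the clip protects the
subsequent log transform; this is the one documented deviation from the
unbounded model. `calibrate_noise()` recovers the parameters from
flat-field frames by the mean–variance method: pooled per-level sample
means and variances (pooling pixels within a frame assumes spatially
homogeneous flat fields), a least-squares line `v = m/lambda + sigma^2`,
`lambda = 1/slope`, `sigma = sqrt(max(intercept, 0))`. Fewer than two
distinct levels or a non-positive slope (non-physical data, or the pure-
Gaussian limit where the slope is statistically indistinguishable from
zero) is an error.

## Datasets, splits and evaluation

`build_dataset()` projects every record at all geometry angles, applies
Beer's law, noise and the log transform, writes 32-bit float TIFFs (TIFF
samples live in [0,1]; the affine map back to physical values travels in
the JSON sidecar) and a CSV manifest with a JSON header. The
train/validation split is *by volume*: all 72 views of one volume are
near-duplicates, so an image-level split would leak; `split_train_val()`
assigns `round(0.15 * n_volumes)` whole volumes to validation. Whether the
original protocol split by image or by volume is not stated; we chose the
leak-free variant and note that at 15% the image fractions coincide up to
volume granularity.

The evaluation module scores per-image accuracy `A = (1/N) sum 1(pred ==
true)` on a class-balanced test set and repeats training
`n_seeds = 4` times, reporting the mean and the sample standard deviation
`dA` across seeds (the published protocol calls this the uncertainty
without giving a formula; we fixed the sample SD). The baseline classifier
is deliberately small — the package's claims concern data generation, not
architecture, and a deep network is out of scope. It extracts engineered
features from each attenuance image (global statistics plus, after
subtracting a box-blurred background, the area, blob count, two largest
blob sizes and integrated mass of the positive and negative residuals at
several thresholds — compact dense inclusions produce positive residual
blobs, cavities negative ones) and fits gradient-boosted trees
single-threaded with early stopping on the validation score, so training
is deterministic given a seed and takes seconds. Per-image scoring only; no
per-object aggregation across views is applied.

## Problem sizes used in the test-suite experiments

The self-contained benchmark mirrors the generation-from-one protocol at
the package's chosen scale: one 64^3 clay phantom (voxel 1 mm), `G = 45`
generated volumes, `p = 72` views on an 80x80 detector (1.1 mm pitch,
`I_incident = 1e4`, noise at the default calibration), a 15% volume-level
validation split, 4 training seeds, and a test set of 200 fresh-seed
phantoms (classes balanced round-robin) at 2 views each. The 0.9 accuracy
bar for this benchmark is the package's own regression threshold on its own
synthetic task — it is not a claim about any published figure, and phantom
accuracy does not imply real-data accuracy (see the phantom caveats
above). The noise-calibration check uses 500 frames of 64x64 pixels at
mean levels {500, 1000, 2000, 4000}.

## Known limitations

* Monochromatic Beer's law only: no spectrum, scatter, detector blur or
  Monte-Carlo transport. The underlying methodology accepts this and
  compensates with the noise model.
* Materials are homogeneous; no intra-material texture.
* Phantom realism is bounded to class structure (see above).
* Elastic/mass-preserving deformations are not modelled; affine + region
  removal only.
* The per-slice convex hull closes concavities slice-wise, which is not a
  true 3-D hull (adequate for convex bases, the only place it is on by
  default).
* FDK reconstruction of real scans and GPU-scale network training are out
  of scope.
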
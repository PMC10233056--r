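---
title: "Automated LI-RADS scoring: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated LI-RADS scoring: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

LI-RADS (the Liver Imaging Reporting and Data System) grades how likely a
liver observation in a high-risk patient is to be hepatocellular carcinoma.
For the LR-3/4/5 range the grade is a deterministic function of four
ingredients: non-rim arterial-phase hyperenhancement (APHE), non-peripheral
washout, an enhancing capsule, and the lesion diameter. `autolirads`
automates the whole read on multi-phase contrast-enhanced studies in three
stages, mirroring how a radiologist works:

1. **Segmentation** finds lesion voxels on the delayed-phase volume.
2. **Characterization** estimates, per lesion, the probability that each
   major feature is present, reading APHE off the arterial phase and
   washout/capsule off the portal-venous and delayed phases.
3. **Rule inference** maps the Boolean feature calls plus the measured
   diameter through the LR-3/4/5 rule table.

Because clinical multi-phase studies cannot ship with a package, a phantom
generator produces synthetic studies with *known* feature dynamics and
rule-consistent labels, so every stage - and the pipeline end to end - is
testable.

## Preprocessing

Raw MR intensities have no fixed scale and a heavy right tail. Each volume
is normalized piecewise: values below a floor of 80 (scanner background) map
to 0, values above the volume's 99th percentile map to 1, and the range in
between is scaled linearly. The percentile is computed over the whole 3-D
volume, which avoids slice-to-slice brightness jumps; each volume is then
standardized to mean 0, standard deviation 1 (population convention, making
the map exactly idempotent).

The segmentation network reads 2.5D windows: three neighboring axial slices
stacked as channels, labeled with the center slice's mask. Only strictly
interior centers are used, so an S-slice volume yields S - 2 windows (a
300-slice study yields 298). Augmentation applies one random
rotation/shift/flip jointly to image and label (defaults: +/-15 degrees,
+/-10% shift, flip probability 0.5 - the transform families are standard;
the ranges are this package's choice since none are canonical).
Cross-validation splits at the *patient* level (default ninefold), never at
the window level, so neighboring slices of one patient cannot straddle the
train/test boundary.

## Losses

Segmentation trains under a hybrid loss: a per-class aggregated soft dice
term written as `1 - (2*sum(y*p) + eps) / (sum(y^2) + sum(p^2) + eps)` plus
a focal term `-(1/N) sum alpha_c (1-p)^gamma y log p`. Writing the dice part
as `1 - dice` (rather than `-dice`) shifts the loss by a constant, leaves
gradients unchanged, and makes the minimum 0 at a perfect prediction.
Targets are one-hot; the aggregated dice form avoids the 0/0 a literal
per-pixel ratio produces on background pixels; `eps = 1` by default. The
focal weights follow the originating convention (`alpha` for the lesion
class, `1 - alpha` for background, defaults `alpha = 0.25`, `gamma = 2`).

Once the smoothed training loss falls below a trigger (default 0.3,
configurable), a Lovasz-Softmax term is *added* - the surrogate for the
Jaccard loss built by sorting per-pixel errors and taking the inner product
with the discrete gradient of the Lovasz extension. The switch is latched:
once on, it stays on for the rest of training. For hard predictions the
per-class value equals `1 - IoU` exactly, which the test suite verifies
exhaustively on 8-pixel toys.

The characterizer's three heads are trained under the phase-routed adaptive
loss `L = (1-x) L_aphe + x L_washout + x L_capsule`, where `x` is 0 for
arterial crops and 1 for portal-venous/delayed crops. Arterial samples
therefore carry no gradient into the washout/capsule heads and vice versa,
while the shared backbone learns from every sample.

## Networks and the compact engine

No deep-learning framework is part of this package's dependency set; both
networks run on a small reverse-mode engine written over base R matrix
algebra (im2col convolutions dispatched to BLAS), with every operator's
backward pass verified against finite differences in the test suite.

The segmentation model is a nested encoder-decoder: a residual encoder
(four stages at full scale; the desk-scale default is two), channel+spatial
attention applied to each encoder residual block, and a dense grid of
decoder nodes in which node (i, j) convolves the concatenation of all
same-level predecessors with the upsampled node one level deeper. Only the
final nested output feeds the 1x1 output convolution (no deep-supervision
averaging). The output head is zero-initialized so training starts from
p = 0.5 everywhere rather than inside the softmax saturation region; inside
the loss, probabilities are clamped to [1e-6, 1 - 1e-6] so the loss
derivative and the softmax jacobian always see the same values and the
gradient chain stays bounded.

The characterizer is a shared convolutional backbone (plain VGG-style
blocks by default; a residual variant is available for the ablation
harness) with global average pooling, one fully connected layer, and three
parameter-disjoint sigmoid heads. Crops are 224 x 224 by convention and are
downscaled to the configured network input (default 32 x 32 at desk scale).

The optimizer is Adam (default 1e-3 for the general API; the pipeline uses
5e-3 for the reduced nets, chosen for CPU-scale budgets). One deliberate
deviation from textbook Adam: parameters whose gradient is exactly zero in
a step are left untouched - no moment decay - so that heads switched off by
the phase indicator stay bit-identical, which is the semantics the routing
promises and what the isolation tests assert.

Three further training-dynamics choices matter when lesion appearances are
multimodal (washout-dark versus persistently-enhancing-bright) and one
mode is both rarer and lower-contrast:

* **Per-window dice within the mini-batch.** The dice and Lovasz terms are
  computed per 2.5D window and averaged, while the focal term stays
  per-pixel. Pooling dice over the whole batch lets well-segmented lesions
  swamp a missed one - the same local-versus-global DICE effect the
  evaluation section describes, acting inside the optimizer.
* **A gradient floor for suppressed positives.** The softmax jacobian
  multiplies upstream derivatives by `p(1-p)`; once a region saturates at
  `p ~ 1e-6` the dice term's restoring force is annihilated and the focal
  term's analytic limit is only `alpha/N` per pixel, so a suppressed
  minority mode can never recover. Pixels whose true class has fallen
  below 1% therefore have their gradients evaluated at probabilities
  floored to 0.01 (only those pixels; confidently correct ones keep exact
  gradients). The loss *value* is always exact.
* **Hard-example mining.** Lesion-containing windows are sampled for each
  batch in proportion to a running estimate of their per-window loss (the
  window-level analogue of the focal principle), so lesions the network
  currently misses keep receiving gradient pressure instead of being
  extinguished by the well-learned majority.

## Scoring

Lesion size is the maximum in-plane Feret (caliper) diameter over axial
slices plus one in-plane voxel, so a single-voxel component measures one
spacing unit instead of zero. The rule table is total over
(B1, B2+B3, size bin) with half-open size bins: "<10" is [0, 10), "10-19"
is [10, 20), ">=20" is [20, Inf). One cell - APHE-positive, 10-19 mm, one
of washout/capsule - is ambiguous between LR-4 and LR-5 in the collapsed
table; the default policy resolves it to LR-5 when the present feature is
washout and LR-4 when it is only the capsule (recovering the distinction
ACR LI-RADS v2018 makes), with `report_both`, `force_lr4` and `force_lr5`
available. In the automatic pipeline the size comes from the *predicted*
segmentation; the ablation harness swaps in ground-truth sizes to isolate
characterization error.

## Evaluation

DICE is reported two ways: the *average local* DICE (one DICE per patient,
then the unweighted mean) and the *global* DICE (pool TP/FP/FN over
patients first). The two separate exactly when many patients contribute
near-zero values with small lesion volumes - pooling then dominates by the
well-segmented bulk. Pixel-level sweeps report precision, recall
(= sensitivity = TPR), specificity and FPR from pooled counts per
threshold; on background-dominant volumes specificity is uninformatively
high, which is why the lesion- and patient-level precision-recall views
exist. A true lesion counts as detected if any predicted component overlaps
it (an IoU-threshold rule is available); detected lesions are TPs - a
"true negative" is undefined at lesion and patient granularity, and the
package reports it as not applicable. Degenerate precision (no predictions)
is reported as 1 with an explicit flag so threshold sweeps stay total.
Patient-level DICE for an empty-vs-empty pair defaults to 1 (configurable).

## The phantom

Each patient is three co-registered phases of a simplified abdomen: air
background (intensity 40, below the normalization floor, as scanner
background is), a body ellipsoid with a bright subcutaneous-fat ring
(600 - the brightest tissue, as in T1-weighted imaging, so the volume's
99th percentile lands in fat rather than on the lesions), mid-intensity
soft tissue (250), and a liver ellipsoid (400) containing spherical
lesions plus sparse bright vessel voxels (650, 0.3% of the volume).
Contrast encodes the features:

* APHE: +120 in the arterial phase; APHE-negative lesions are rendered
  hypovascular (-60) so arterial elevation holds *iff* B1.
* Washout: -100 in portal-venous/delayed; washout-negative lesions get
  *persistent enhancement* (+60) - mildly hyperintense late phases, the
  benign-lesion pattern - so late-phase depression holds iff B2 while every
  lesion stays visible in the delayed phase the segmenter reads.
* Capsule: a 1-2 voxel rim at +140 in the late phases iff B3.

Diameters follow a truncated log-normal (median ~22 mm) with a configurable
fraction below 20 mm (default 44.8%, the cohort composition the pipeline
targets; full range 4-164 mm), 0-3 lesions per patient, feature prevalences
(0.7, 0.6, 0.4) typical of an LR-3/4/5 population, and additive Gaussian
noise. Lesions are placed largest-first (greedy packing), with two bounded
0.85x shrink steps if a patient's liver is too crowded, before the
placement error the generator promises. Per-lesion seeds derive from
(dataset seed, patient, lesion), so generation is bit-reproducible and
patients are independent. Spheres are used because their diameter is
analytically known; the phantom deliberately has no liver texture, organ
anatomy beyond the ellipsoids, breathing motion or MR physics, so passing
tests demonstrate that the *pipeline machinery* works - recovery of known
contrast dynamics, correct plumbing, correct rules - not clinical
performance on real anatomy.

`phantom_spec()` defaults mirror the target cohort at a 160 x 160 grid;
`phantom_spec_easy()` is the desk-scale regime used by the heavier tests:
40 patients, 64 x 64 x 16 voxels at (5, 2.5, 2.5) mm spacing, 1-2 lesions
of 10-40 mm, noise 5 against feature contrasts of 60-140 - high-contrast,
low-noise conditions under which the reduced networks are expected to work
well within CPU-minute budgets.

## Problem sizes and numerical choices

The heavier checks run the full pipeline on the easy preset (40 patients,
two thirds training) with the reduced segmentation net (2 stages, base
width 8, ~1250 Adam steps at batch 8; attention off in that run - the
attention path is exercised by the gradient checks, parameter-count tests
and the pipeline smoke test) and the reduced characterizer (~1000 steps);
these sizes are the package's desk-scale choices and complete in CPU
minutes. Training batches oversample lesion-containing windows to half of
each batch - with ~1% foreground voxels, unbalanced batches spend most
steps on background. The binarization threshold is selected from a
0.2-0.8 sweep on training patients (the DICE-versus-threshold curve is
non-monotone, so an appropriate operating point must be picked; selection
never touches held-out patients). Probabilities entering logarithms are
clipped at 1e-7; ties in representative-slice selection break toward the
lowest slice index; connected components use face connectivity, with
components under 5 voxels dropped by default (configurable to 1) to
suppress speckle.

Known limitations: the engine is CPU-bound and meant for reduced
configurations (the full-scale 512 x 512, four-stage configuration is
expressible but not practical without acceleration); washout/capsule
evidence is fused across the two late phases by the maximum ("present in
either"), a deliberate choice where no canonical fusion exists; DICOM
ingestion is limited to what the NIfTI reader covers (series conversion is
out of scope); and phantom realism is intentionally minimal, as above.
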
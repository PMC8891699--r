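---
title: "Joint skull stripping and hippocampus segmentation in rat brain MRI: models and methods"
author: "munetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint skull stripping and hippocampus segmentation in rat brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lateral fluid-percussion injury in the rat produces cortical lesions,
hippocampal atrophy and displacement, and ventricular enlargement.
Registration-based segmentation of the hippocampus degrades in the injured
(ipsilateral) hemisphere because atlas alignment fails near the lesion.
`munetr` implements the alternative: a compact multi-task convolutional
encoder-decoder that simultaneously skull-strips and segments the
ipsilateral and contralateral hippocampus directly from a T2*-weighted
volume, trained and evaluated by animal-level nested cross-validation with
six-member majority-vote ensembling, plus the evaluation metrics and
statistics needed to compare segmentation methods and to model hippocampal
volume over time after injury.

Because raw animal MRI cannot ship with a package, all pipelines are
exercised end-to-end on a synthetic phantom cohort (below).  Everything is
pure R plus a small compiled numerical core; there is no deep-learning
framework dependency.

## The network

`modelConfig()` / `buildNetwork()` construct a U-Net-like encoder-decoder:

* three encoder blocks and a bottleneck with channel widths 16 / 32 / 64 /
  64 (shallowest to deepest);
* each block is three iterations of *Leaky ReLU (slope 0.01), batch
  normalisation, "same" zero-padded convolution*, in that order — note the
  activation-first ordering, which also applies to the raw input of the
  first block;
* 2x max-pooling with retained indices connects encoder stages downward;
  index-based max-unpooling (parameter-free, reversing the pooling) feeds
  the decoder upward; each encoder output is concatenated onto the
  corresponding decoder stage (skip connections);
* two heads read the full-resolution 16-channel decoder feature: a
  three-class softmax (background, ipsilateral, contralateral hippocampus)
  and a sigmoid brain-mask probability, each a 1x1 convolution.

Index unpooling constrains the decoder channel plan: the tensor being
unpooled must carry exactly the channel count of the encoder feature whose
pooling indices it reuses.  The decoder therefore mirrors the encoder
widths with a transition in each block's last convolution
(128→64→64→32, then 64→32→32→16, then 32→16→16→16).  With dual 1x1 heads
this build has 403,750 trainable parameters in the 2D variant (3x3
kernels) and 1,205,830 in the 3D variant (3x3x3 kernels), counting
convolution weights and biases plus all batch-norm scales and shifts.  The
larger 5x5-kernel, 64-channels-throughout baseline configuration from
which the compact design descends can be built with
`modelConfig(channels = rep(64L, 4), kernel = 5L)`.

The 2D variant processes coronal slices independently (kernels 3x3x1,
pooling 2x2x1 internally); volumes remain 3D at the I/O layer and the
slice axis is taken to be the lowest-resolution axis by voxel spacing.
It is intended for anisotropic multi-slice acquisitions
(0.15 x 0.15 x 0.5 mm); the 3D variant for isotropic ones (0.16 mm).

### Normalisation semantics

Batch normalisation always uses the statistics of the current batch: one
slice (2D) or one volume (3D) during training, and the whole input volume
at inference.  We implemented and rejected the running-average evaluation
mode: with batch-size-one slice training the running moments track neither
the per-slice training distribution nor the volume-level inference
distribution, and held-out accuracy collapsed.  Volume-level inference
statistics keep absolute intensity information (a per-slice normalisation
would stretch hippocampus-free slices until ordinary tissue mimics the
bright hippocampal signal) and make prediction a deterministic pure
function of the input volume.  Inference on the 2D variant is consequently
a single whole-volume pass.

## Objective

The loss is the sum of two terms (`totalLoss()`):

* `generalizedDiceLoss()`:
  `1 - 2 * sum_l w_l sum_n y_ln p_ln / (sum_l w_l sum_n (y_ln + p_ln))`
  over the three region classes.  The default class weights are computed
  from the ground truth, `w_l = (sum_n y_ln)^-2` (stabilised as
  `1/((sum y)^2 + 1e-5)`), the form used in the generalized-Dice
  literature; `weightsFrom = "prediction"` switches to weights computed
  from the predicted class volumes.  We default to ground-truth weights:
  in side-by-side training runs the prediction-based weights were
  unstable, driving one hippocampus class into runaway over-segmentation
  while the other converged.  The weights are treated as constants in the
  gradient.
* `brainDiceLoss()`: `-sum_n y_n p_n / sum_n (y_n + p_n)`, exactly this
  form, whose optimum at perfect overlap is -0.5 (no factor 2).  The
  constant factor does not move the optimum, so the composite loss ranges
  over [-0.5, 1].

## Training protocol

`trainConfig()` defaults: rectified Adam (lr 0.001, beta1 0.9, beta2
0.999, eps 1e-8, no weight decay), batch size one, at most 250 epochs,
early stopping once the mean validation loss has not improved for 10
consecutive epochs, with the weights restored from the best-validation
epoch (standard early-stopping semantics; restoring rather than keeping
the last epoch is our choice where the protocol leaves it open).
Augmentation rescales each loaded sample with probability 0.5 by a factor
drawn uniformly from [0.95, 1.05] — image trilinearly, labels by nearest
neighbour, about the grid centre on the fixed grid — and no rotations are
ever applied.  Augmentation happens on loading, before the per-sample
standardization; for 2D slices the (affine) volume standardization is
applied first and the in-plane scaling second, which is equivalent up to
the zero fill at the slice border.

A *sample* is one coronal slice for the 2D variant and one whole volume
for the 3D variant; this is what batch size one means in each case.  The
rectified-Adam variance rectification warms up over roughly the first
thousand steps (its step-size multiplier is ~0.2 after 100 steps and ~1
after 5,000), so per-slice sampling is also what makes desk-scale 2D
training converge in a handful of epochs.  Validation loss is always
computed by whole-volume forward passes — the inference-time semantics —
so early stopping tracks test-time behaviour.

`radamStep()` follows the published update: bias-corrected first moment
always; the variance-rectified adaptive step only once the approximated
SMA length exceeds 4, otherwise a plain momentum step.  A unit test locks
the update sequence to an independently coded scalar trace on a quadratic
bowl.

## Cross-validation and ensembling

`makeFolds()` partitions animals (never scans) into equal folds.  For each
outer test fold, `trainEnsemble()` randomly divides the remaining animals
into six nested folds and trains one network per nested fold (validating
on it, training on the other five), giving a six-member ensemble whose
training never sees the test animals — asserted by tests on the recorded
manifests.  `fuseMajority()` implements per-voxel majority voting over
hard label maps; with six voters 3-3 ties are possible, so ties are broken
by the mean class probability when probability maps are available and by
the lowest class index otherwise (background wins a tied brain-mask vote).
`segmentVolume()` standardizes, runs all members, fuses, and post-processes.

`registrationCohortPlan()` / `planRegistrations()` reproduce the
bookkeeping of the registration-based baselines: within each timepoint,
every annotated available scan is a target, and its atlases are all
annotated available animals *outside the target's entire fold* — the
reading that yields 10 atlases per target for 12 animals in folds of two.
The planner only enumerates pairs; image registration itself is out of
scope.

## Post-processing

`postprocessSegmentation()` keeps, independently for the brain mask and
each hippocampus class, the largest 26-connected component and fills its
interior cavities (background regions not 6-connected to the array
border).  Size ties keep the component containing the first voxel in
array storage order.  Should filling make the two hippocampus regions
overlap, contested voxels go to the smaller region (ties to the
ipsilateral class).  The operation is idempotent and never removes voxels
from the kept component.

`completeBrainMask()` reconstructs a full brain mask from sparse manual
annotation (every second sagittal slice): binary closing with a
structuring element spanning five voxels along the sparse axis (a
half-length-1 line dilated by a 3x3x3 ball — the exact hand-crafted kernel
of the original protocol is not documented, so this default is validated
by the round-trip property Dice > 0.98 against `sparseAnnotate()`), then
volumetric hole filling.  A mask with a single annotated slice is returned
unchanged with a warning.

## Evaluation metrics

All metrics are millimetre-aware through the voxel spacing:

* Dice `2|Y∩Yt|/(|Y|+|Yt|)`; precision `|Y∩Yt|/|Y|`; recall
  `|Y∩Yt|/|Yt|`.
* HD95: surfaces are mask voxels with an exposed 6-face (array borders
  count); distances are Euclidean in mm; the statistic is the maximum of
  the two directed 95th percentiles (linear-interpolation quantiles).
* Volume similarity `1 - ||Yt|-|Y||/(|Yt|+|Y|)`.
* Compactness `area^1.5 / volume`, with the surface area from
  exposed-face counting (each face weighted by its mm^2 area) — a
  deterministic, exactly reproducible voxel-set measure, not a mesh
  estimate; the compactness score is `1 - 2|C - C_GT|/(C + C_GT)`, which
  is 1 exactly when the two compactness values agree (the absolute value
  makes the score symmetric, forced by that stated property).

`evaluatePair()` assembles the six metrics per hemisphere plus volumes;
failed preconditions (e.g. an empty predicted region) become `NA`s with
reasons, never hard errors.  Every metric is cross-checked in the test
suite against independent brute-force oracles (all-pairs surface
distances, loop-based face counting) on hundreds of random small masks.

## Statistics

* `pairedPermutationTest()`: two-sided sign-flip test of zero mean paired
  difference; exact enumeration whenever `2^n` does not exceed the
  iteration budget (10,000 by default), otherwise seeded Monte Carlo with
  add-one smoothing.
* `bonferroniAdjust()`: `min(1, m p)`.
* `interhemisphericDifferences()`: per-metric mean of (ipsilateral -
  contralateral) with a seeded percentile bootstrap CI (default 2,000
  resamples), excluding incomplete pairs.
* `fitVolumeModel()`: the fixed-effects model
  `V = a + bt*t + bR*R + bB*B + btR*tR + btB*tB + bRB*RB + E` with `t` in
  days (continuous), `R = 1` for the ipsilateral hippocampus, `B = 1` for
  injured animals, and a diagonal error covariance with one variance per
  timepoint.  With only fixed effects this "repeated measures" model class
  is exactly heteroscedastic feasible generalized least squares: iterate
  OLS/WLS and per-timepoint residual variances to convergence; Wald
  z-tests per coefficient.  Variances are indexed by timepoint (stated in
  the output) and the fit reduces to OLS when they are equal.  Parameter
  recovery is verified by simulation in the acceptance suite.

## The phantom cohort

`generatePhantom()` builds, deterministically from its spec and seed, an
ellipsoidal brain with a cortical shell; two hippocampi as mirrored
sectors of a torus bent around the midline vertical axis (capturing the
elongated, curved rostro-caudal shape without any atlas dependency);
paired ventricles; and for injured animals a left dorsolateral cortical
cavity adjacent to — never overlapping — the left hippocampus, whose
tube radius shrinks as `sqrt(1 - atrophyFraction)` (so volume scales as
`1 - atrophyFraction`) with a lateral-dorsal displacement toward the
cavity.  Intensities use five tissue classes (background 0.05, tissue
1.0, cortex 0.92, hippocampus 1.30, ventricle 0.35, cavity 0.22), a
smooth multiplicative Gaussian-bump bias field (default amplitude 0.1)
and additive Gaussian noise (default SD 0.05; the summed-echo magnitude
images this emulates are high-SNR, where a Gaussian approximation of
Rician noise is appropriate).  Label 1 is the left hippocampus: injury is
always induced in the left hemisphere, so ipsilateral is fixed to left.

`generateCohort()` adds per-animal random effects held constant across
timepoints (size 0.95-1.05, lesion severity 0.45-0.85 for TBI animals)
and monotone post-injury dynamics (atrophy `0.4 * severity * t/(t+25)`,
ventricular enlargement `0.8 * severity * t/(t+30)`); these defaults are
free parameters of the generator, documented here, not claims about any
real cohort.  The default desk-scale grid is 64 x 64 x 48 (isotropic
dialect) so that CPU training completes in minutes.

What the phantom does *not* emulate: real anatomy (no atlas geometry, no
skull or scalp), Rician noise, multi-echo signal formation, partial-volume
mixtures, or inter-site intensity variation.  Passing tests on phantoms
demonstrates that the pipeline's machinery — losses, optimisation,
ensembling, metrics, statistics — is correct and that the network can
learn a bilateral, injury-perturbed segmentation task; they say nothing
about accuracy on real rat MRI.

One geometric caveat: sham phantoms are exactly mirror symmetric up to
noise, so the only cue distinguishing "ipsilateral" from "contralateral"
is position relative to the volume borders (zero padding) — harder than
real data, where anatomy and lesions break symmetry.  The end-to-end test's
Dice thresholds are only attainable if the trained networks resolve the
two sides; residual errors concentrate at region boundaries.

## Numerical choices

* Convolutions run in single precision through an im2col + GEMM core
  (OpenBLAS); everything else is double precision.  Training is therefore
  bit-reproducible on a given BLAS given (seed, data, config).
* He-style weight initialisation, biases zero, BN scale 1 / shift 0.
* Loss epsilons: 1e-5 in the generalized-Dice weight denominators and the
  loss denominator; the brain term needs none (an empty brain mask is a
  precondition error).
* Argmax decoding breaks ties toward the lowest class index; the brain
  mask thresholds the sigmoid at 0.5 inclusively.
* Degenerate inputs error early with messages naming the offending
  precondition (constant volume in `standardizeVolume()`, empty masks in
  the metrics, non-divisible shapes in the network with the required
  padding reported).

## Problem sizes used by the automated checks

The test suite trains the six-member ensemble on a ten-animal anisotropic
phantom cohort at 64 x 64 x 48 (four held-out animals, six training
animals, one scan each, 10 epochs per member) and verifies held-out
majority-vote Dice for both hippocampi; metric implementations are checked
against brute-force oracles on 200 random mask pairs at up to 15^3 voxels;
the volume model is verified by 200-replication parameter recovery; the
permutation test by exhaustive enumeration up to n = 12.  These sizes are
the package's own desk-scale study conditions; the full-resolution
configuration is available through the same interfaces.

## Known limitations

* The printed parameter totals of this implementation correspond to the
  block structure documented above; other head/skip resolutions of the
  same textual architecture description yield different totals.
* The 2D variant assumes the slice axis is the lowest-resolution axis.
* `fitVolumeModel()` supports only the diagonal (per-timepoint) error
  structure; no random effects.
* STEPS-style weighted label fusion and image registration itself are out
  of scope; the planner only enumerates registration pairs.
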
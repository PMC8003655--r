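---
title: "Facility adaptation for glioma MR segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facility adaptation for glioma MR segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A segmentation model trained on brain MR images from one facility (domain A)
usually loses accuracy when applied to images from another facility (domain
B).  Scanners, field strengths, sequences and slice thicknesses differ —
in heterogeneous multi-facility glioma cohorts the z-axis voxel size alone
can range from about 3.3 to 9 mm — and the resulting *domain shift* changes
the intensity statistics that a trained network has calibrated itself to.
Collecting enough annotated cases at every new facility to train from
scratch is unrealistic: glioma is rare, and expert neuroradiologist
annotation is expensive.

`glioadapt` implements a lightweight answer: take a model trained on a
large source dataset and *fine-tune only a few named blocks* of the network
on at most 20 cases from the new facility.  The package provides every
stage of that study as reusable, tested components:

* a synthetic multi-facility phantom generator (`phantoms`),
* NIfTI I/O, VOI label merging, Z-score normalization and crop/resize
  preprocessing (`volio`),
* a block-named 3D encoder–decoder segmentation network (`blocknet`),
* the five selective freezing strategies and the fine-tuning engine
  (`tuner`),
* Dice evaluation, Welch ANOVA, Games–Howell post-hoc comparison and
  Dice-vs-volume correlation (`evalstats`),
* and a workflow driver that reproduces the full degradation-and-recovery
  experiment at desk scale (`workflow`).

## The network and its block registry

The segmentation model is a 3D encoder–decoder with `depth` *down* blocks
and `depth` *up* blocks.  Each block holds `convs_per_block` 3×3×3
convolutions (shape-preserving, ReLU) and one dropout layer; where the
channel counts allow, the block's inner convolutions are wrapped in a
residual element-wise sum — block boundaries sit between element-wise sums
or merge operations.  The down path halves resolution with a strided entry
convolution (doubling channels); the up path doubles resolution with a
kernel-2 stride-2 transposed convolution and concatenates the mirrored down
block's output (`skip_mode = "concatenate"`; `"sum"` is available).  The
final up block ends in a pointwise sigmoid head: the output is a voxelwise
probability map for one binary whole-tumor VOI, because the evaluated
target is the merged tumor region (edema + enhancing tumor + necrotic
core), not the individual sub-regions.

Every learnable parameter belongs to exactly one named block.  Down blocks
are numbered shallow→deep ("1st down" … "5th down"); up-block ordinals run
deep→shallow, so "1st up" is the *deepest* up block.  The registry is the
contract the freezing strategies operate on, and
`block_param_counts(model)` prints it.

### The down2_up2 ambiguity

The ordinal convention makes "down2_up2" ambiguous.  Read literally, the
strategy unfreezes the two shallowest down blocks and the two *deepest* up
blocks.  Read as "the mirror blocks of the selected down blocks", it
unfreezes the two shallowest blocks on both paths — which is the reading
supported by the rationale that facility differences live in low-level
image features (lines, edges, local contrast), best corrected where the
network processes them.  `freeze_strategy()` implements both
(`up_reading = "shallow"` or `"literal"`) and defaults to the
symmetric-shallow reading; under it the selected up blocks include the
output head, which also lets the model recalibrate its decision threshold
for the new facility.  Neither reading is asserted as the original intent;
both satisfy every structural contract in the test suite.

## Training

* **Loss.** Soft Dice, `1 − (2Σpt + ε)/(Σp + Σt + ε)` with `ε = 1`,
  aligning the objective with the evaluation metric; `ε` is part of the
  contract and keeps the tumor-free case finite.
* **Base training** defaults to RMSprop with learning rate 5e-4; the
  best-validation-Dice checkpoint is retained.
* **Fine-tuning** defaults to AdaGrad with learning rate 0.005 for a fixed
  20 epochs, no validation split; AdaGrad uses the Keras convention of a
  0.1 initial accumulator (a zero-initialized accumulator makes the first
  update exactly ±lr for every parameter, which can saturate the sigmoid
  head and collapse predictions): all supplied cases (at most
  `max_cases = 20`) are training data.  Frozen parameters are
  bit-identical to the base model afterwards — asserted in the tests, not
  just intended.
* **Batch size** is 1 (whole 3D volumes; also removes batch-statistics
  nondeterminism).  One integer seed drives initialization, data order and
  dropout; all compute kernels are deterministic on a single thread, so
  experiments reproduce bit-for-bit.

The convolution kernels are written in C++ (single-precision BLAS gemms;
the stride-1 convolution runs as 27 row-shifted gemms on a zero-halo padded
layout, which avoids materializing an im2col matrix).  Gradients are
checked against finite differences in the test suite.

## The phantom generator

The generator's job is to emulate the *properties of real multi-facility
glioma data that make domain shift harmful*, at sizes where the full
experiment runs on a laptop.

A case is a skull-free brain modeled as an axis-aligned ellipsoid with a
smooth low-frequency texture field, containing:

* a three-compartment tumor (necrotic core, enhancing rim, edema) as
  concentric ellipsoids, labeled with BraTS codes (1 = necrotic core,
  2 = edema, 4 = enhancing tumor) so real BraTS label files and phantoms
  share one code path;
* channel contrasts following the standard glioma appearance: tumor and
  edema hyperintense on T2/FLAIR, enhancing rim bright on GdT1, necrotic
  core dark on T1 and GdT1;
* an *infiltration ramp*: the edema contrast fades linearly with ellipsoidal
  radius, and the label boundary sits at the 50% point of the ramp.  Real
  glioma margins are diffuse; a piecewise-constant phantom would put the
  label edge on an intensity step that survives any monotone intensity
  remap, making segmentation unrealistically robust to acquisition shifts;
* ventricle-like CSF distractors (T2-bright, FLAIR-dark) and small
  white-matter-hyperintensity-like lesions whose signature is separated
  from edema only by a narrow margin — so accurate segmentation depends on
  calibrated multi-channel intensities, the calibration an acquisition
  shift corrupts;
* per-case variation in tumor size, position, anisotropy and contrast
  (lesion conspicuity varies across patients).

A `facility_spec` then applies the acquisition transform in a fixed,
documented order: per-channel scale/offset → gamma on unit-max-normalized
intensities → multiplicative bias field (a normalized degree-2 polynomial,
the standard MRI inhomogeneity surrogate) → slice-thickness degradation
(z block-average, piecewise-constant replication) → additive in-brain
Gaussian noise.  The order is part of the contract because the operations
do not commute.  Noise is confined to the brain so the background stays
exactly zero, as in skull-stripped data — this keeps the in-brain support
(used by Z-score normalization) well defined.  Labels are never touched by
facility transforms.

What the phantoms do *not* model: real anatomy (gyri, white/gray matter
boundaries), skull or CSF spaces beyond the ventricle surrogates, motion or
ghosting artifacts, annotation variability between raters.  Passing the
package's tests therefore demonstrates that the *method* behaves as claimed
under controlled shifts — not that any particular Dice level would be
attained on clinical data.

## Preprocessing conventions

* The VOI is the merged whole-tumor mask: a voxel is tumor exactly when its
  label is nonzero.
* Images are cropped to the tight bounding box of the in-brain support and
  resampled to the model shape (trilinear); masks use the box computed from
  their paired image and nearest-neighbor resampling, so they stay binary.
  Voxel indices are 0-based and boxes half-open.
* Z-score normalization is per channel over the in-brain support (not the
  whole array — background zeros would dominate the statistics), with the
  population (n) standard deviation, fixed for test determinism.
  Whether normalization happens before or after resizing is a free choice;
  the package normalizes *last* so the model always sees zero-mean,
  unit-variance input regardless of interpolation.  Both-empty-mask Dice is
  an error rather than 1: silently scoring tumor-free cases perfect would
  inflate averages.

## Statistics

Dice scores are computed per case and then aggregated (mean ± sample SD per
facility / model type / stratum); they are never pooled voxelwise.  Model
types are compared with Welch's heteroscedastic ANOVA (via
`stats::oneway.test`) and the Games–Howell post-hoc test (studentized-range
statistic on the Welch standard error with Welch–Satterthwaite degrees of
freedom), which assume neither equal variances nor equal group sizes.
`compare_models(..., level = "case")` compares per-case scores pooled
across facilities; `level = "facility"` compares facility means — both are
exposed because either aggregation is defensible.  Correlation of Dice with
tumor volume uses Pearson's product-moment coefficient.
`histogram_profile()` summarizes a normalized volume against its VOI over
60 uniform Z-score bins on [−3, 3] (values beyond the range are clamped
into the edge bins so counts conserve): easy cases show the VOI at the
right edge of the T2 histogram occupying a visible fraction; hard cases sit
centrally.

## The desk-scale experiment

`degradation_recovery_trial()` runs the core study for one seed under these
conditions, chosen once as the package's study configuration:

* volumes 32³ at 1 mm spacing; network depth 3, 8 base channels,
  2 convolutions per block, dropout 0.2, concatenation skips;
* facility A: identity acquisition; facility B: gamma 1.8, noise SD 0.08,
  bias amplitude 0.2, slice factor 2;
* 40 A training cases (6 validation), a 20-case B pool (4 validation for
  the B-trained reference model), 20 held-out B test cases;
* base training RMSprop lr 1e-3 — 3 epochs for A, 12 for B, giving both
  models a comparable number of optimization steps (the package-default
  5e-4 converges too slowly for a ~200-step budget), each keeping its
  best-validation-Dice checkpoint;
* fine-tuning from the A model with 10 B cases: AdaGrad lr 0.005,
  20 epochs, strategies `down2_up2` and `fine_all`.

Across seeds this reproduces the qualitative findings: the A model
underperforms the B-trained model on B's test cases; `down2_up2`
fine-tuning with 10 cases recovers most of the gap; and `down2_up2` is
comparable to `fine_all` while updating a fraction of the parameters
(lower cost, less overfitting risk on small target datasets).
`run_experiment()` generalizes the same flow to many facilities with the
split conventions (source 60/20/20; per-facility halves balanced within one
case; pre-training half split 75/25; largest-remainder rounding with ties
broken in role order).

## Numerical and degenerate-input choices

* Gamma requires strictly positive in-brain intensities and, for γ ≠ 1,
  maps to the unit-normalized scale (`(v/max)^γ`); γ = 1 is an exact no-op.
  Downstream Z-scoring makes the absolute scale immaterial.
* Tumor radii of 0 generate a tumor-free case (empty labels, intact brain);
  a tumor that does not fit inside the brain ellipsoid is rejected naming
  the offending radius.
* `binarize()` uses the ≥ convention, so exact-threshold ties count as
  tumor; the default threshold 0.5 is a config value (the evaluated VOI is
  binary, but no canonical threshold exists).
* Welch ANOVA rejects groups with fewer than 2 values or zero variance;
  Games–Howell adjusted p-values can never be smaller than the pairwise
  Welch p (multiplicity never increases significance), and the Welch
  statistic reduces to the classical ANOVA only in the two-group
  equal-variance case (for three or more groups the Welch denominator
  correction differs from 1 even under exactly equal variances).
* Checkpoints store parameters plus a JSON manifest of the block registry
  (parameter names, shapes, counts per block), so a saved model can be
  audited without loading it.

## Limitations

The network is a faithful but small member of the U-Net family, not a
reproduction of any specific published layer graph; multi-class output
heads, data augmentation, mixed precision and distributed training are out
of scope.  The phantom generator's facility shifts are parametric
surrogates; their magnitudes were chosen to produce measurable, recoverable
degradation at desk scale, since clinical acquisitions differ in ways no
compact parameterization fully captures.  Dice levels on phantoms say
nothing quantitative about clinical data.
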
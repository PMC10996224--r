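---
title: "dcisnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dcisnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ductal carcinoma in situ (DCIS) is usually detected through the
calcifications it leaves on screening mammograms. Active-surveillance
trials (COMET, LORIS, LORD, LORETTA) enrol only low-risk — grade I/II —
DCIS, but under surveillance no surgical specimen exists to confirm the
grade, and biopsies can miss high-grade foci or occult invasive disease.
A classifier that reads the mammogram itself can act as an extra safety
check: the morphology of calcifications carries grade information (fine
granular clusters lean low grade; fine linear and branching forms lean
high grade), yet radiologists agree poorly on exactly those descriptors.

`dcisnet` implements a multi-task convolutional network for this setting:
a single fully convolutional encoder–decoder that simultaneously

* segments the calcified region (an auxiliary task that forces the
  features to attend to the calcifications), and
* classifies the lesion as low risk (grade I/II) versus high risk
  (grade III and/or occult invasive disease),

together with everything around it: DICOM/PNG/TIFF/NRRD input, the
augmentation pipeline, patient-level grade-stratified partitioning,
the training schedule, threshold-based evaluation — and a synthetic
phantom cohort so the whole pipeline is testable without clinical data.

## Network

The backbone is the canonical U-Net at depth 5: four encoder blocks (two
3×3 convolutions + ReLU, then 2×2 max pooling), a double-convolution
bottleneck, and four decoder blocks (bilinear 2× upsampling — not
transposed convolution — concatenation with the matching encoder skip,
double convolution). Channel widths double per level from
`base_channels` (64 at full scale). Two heads:

* **segmentation head** — two 3×3 conv+ReLU layers and a 1×1 convolution
  to two per-pixel score maps;
* **classification branch** — reads the bottleneck feature map through a
  single 3×3 convolution, a double 3×3 convolutional block, a 1×1 score
  convolution, global average pooling, and a softmax.

Where the reference description is silent we committed to standard
choices and left them configurable: two convolutions per block and
doubling channel widths (the "well-known" U-Net scheme), 3×3 kernels in
the classification branch with global average pooling as the all-
convolutional way to reduce a map to a class vector, and the branch
tapping the bottleneck *after* its double convolution. No normalisation
layers are used anywhere — the reference description mentions none, and
at the data scales exercised here they were not needed; this is a
deliberate omission rather than a flag, to keep the hand-written
backward pass small and fully tested.

The segmentation head emits unnormalised scores; softmax happens inside
the loss and at thresholding time, which is numerically safer. The
implementation is plain R orchestration over compiled im2col/GEMM
convolution kernels, with a mirrored hand-written backward pass that the
test suite verifies against finite differences.

## Losses

The training loss is the equally balanced (unit-weighted) sum of:

* **focal classification loss**
  `FL = -alpha_y (1 - p_y)^gamma log p_y`, `p = softmax(scores)`. The
  exponent and class weights are not fixed by the reference, so the
  canonical focal setting is the default: `gamma = 2`, uniform `alpha`.
  `gamma = 0` recovers cross-entropy (tested).
* **top-k pixel cross-entropy** for segmentation: per-pixel softmax
  cross-entropy where only the `k` worst-classified pixels are averaged
  and receive gradient. `k` is expressed as a fraction of pixels
  (default 0.10, i.e. `k = ceiling(0.1 * n_pixels)` per image — applied
  per image, not per batch). Ties at the k-th loss value keep the first
  `k` pixels in stable index order, so training is bit-reproducible.

Probabilities are clamped at `1e-12` before `log`; gradient masking
(zero gradient outside the selected set) is enforced exactly and checked
by finite differences.

## Optimisation

Adam (conventional moments `0.9/0.999`) with the published schedule:
starting learning rate `0.00025`, halved every 150 iterations, batch 16,
500 epochs per fold, five folds. "Iterations" is read as optimiser
steps. Read literally, halving every 150 steps drives the rate to zero:
the total Adam displacement per parameter is bounded by roughly
`2 * 150 * lr` regardless of training length. A configurable floor
(`1e-7`) therefore caps the decay while honouring the stated rule early
on. Checkpoint selection — unspecified in the reference — keeps the
weights with the best validation AUROC, breaking ties by validation
DICE and then by the later epoch; with a saturating classification task
this retains the checkpoint whose segmentation is also good. At test
time the five fold models are ensembled by averaging their class
probabilities (and per-pixel lesion probabilities) per image before any
patient-level averaging.

Training labels use the surgical ground-truth grouping: grade III
and/or upstaged disease is the positive class. The "pure" evaluation
scenario then simply excludes upstaged patients.

## Preprocessing and augmentation

Composition order follows the reference narrative: vendor LUT →
linear rescale to `[0, 1]` → lesion-centred crop → horizontal flip →
gamma → additive noise. Specifics that required a decision:

* **LUT** — one lookup table drawn uniformly from the DICOM VOI LUT
  family at training time; identity at evaluation time. Tables must be
  monotone non-decreasing and are rejected at load otherwise.
* **Crop** — `1024 x 1024` around the lesion center, perturbed by
  integer offsets drawn independently per axis from `[-150, 150]` in
  training; zero padding outside the image (mammographic background is
  near zero). Since `150 < 1024/2`, the lesion center always stays
  inside the crop.
* **Noise** — "magnitude at most 5%" is ambiguous between a per-pixel
  relative and a global reading; we use the simplest consistent one:
  the noise standard deviation is drawn uniformly from `[0, 0.05]` on
  the unit intensity scale, applied additively, then clipped to
  `[0, 1]`.
* **Degenerate input** — a constant image rescales to all zeros rather
  than dividing by zero.
* Coordinates are 0-based `(row, col)`; masks are strictly `{0, 1}`.

Geometric operations always transform image and mask together;
photometric operations never touch the mask. These congruence, range,
shape, and determinism properties are tested directly.

## The synthetic cohort

No clinical data ships with the package; the generator produces
mammogram-like phantoms whose *class signal is morphological*, encoding
the radiological contrast the task rests on:

* **low risk** — clusters of small, round, high-intensity blobs
  (granular calcifications; eccentricity near 0). Grade II differs from
  grade I only in blob density (factor 1.4).
* **high risk** — elongated, occasionally branching linear segments at
  higher spatial density (eccentricity near 1). Upstaged patients are
  rendered with high-risk morphology, matching the surgical grouping
  that treats them as positives.
* **matched intensities** — both classes draw element amplitudes from
  the same distribution, so brightness alone carries no signal.

Cohort structure defaults mirror the reference cohort: grade mix
30.0 / 41.6 / 28.4% (largest-remainder quota allocation, so a
464-patient cohort reproduces counts 139/193/132 exactly), 14.7%
upstage rate (68 of 464), CC and MLO views per patient. Backgrounds are
low-frequency random fields inside a soft half-elliptical breast region
against a near-zero border. The default `image_size` is 256 (desk
scale); 2048 approximates clinical resolution. Morphology scales are
free parameters — the reference reports no quantitative descriptors —
chosen once so that a handcrafted statistic (mean eccentricity of mask
components) separates the classes with AUROC ≥ 0.90 at 100 patients,
the learnability guard that makes the end-to-end training test
meaningful. A null-signal control (`render_high_as_low`) renders both
classes identically and drives that statistic to chance.

What the generator does **not** emulate: X-ray physics, breast-density
patterns, scanner noise spectra, magnification views, or inter-reader
annotation variability. A green end-to-end test therefore establishes
that the pipeline can learn a morphological contrast of this kind — not
any level of clinical performance.

## Evaluation

* **DICE** `2|A∩B| / (|A| + |B|)`; two empty masks score 1.0 (nothing to
  find, nothing predicted). Predicted masks binarise at per-pixel
  lesion probability 0.5.
* **AUROC** by the Mann–Whitney rank statistic with midrank ties —
  exact, threshold-free, and verified against exhaustive pair counting.
* **PPV/NPV** at the clinical 0.5 likelihood threshold; a score exactly
  at the threshold counts positive; a rate with an empty denominator is
  reported missing rather than invented.
* **Patient score** — the mean of the available CC and MLO view
  probabilities. Non-standard views (ML, LM, XCCL, …) are excluded when
  a standard view exists and serve as fallback otherwise, so every
  patient is predictable.
* Reports are pure functions of the per-image prediction table, so a
  saved prediction CSV replays to the identical report.

## Desk-scale acceptance run

The reference results were obtained on a private cohort with GPU-scale
training; the package's acceptance check instead verifies *parameter
recovery at desk scale*: 100 synthetic patients, 128×128 crops, a
depth-3 network, 15 epochs, a single fold, on one CPU. Scaled-down
choices, made once and not revisited: single (CC) view per patient and
8 base channels — the smallest capacity at which the segmentation task
trains reliably within 15 epochs (4 channels under-fits: its features
collapse to the background prior before the lesion signal is learned) —
and batch 4, giving the optimiser enough steps within 15 epochs under
the bounded-displacement schedule above. The criterion is held-out
pure-scenario AUROC ≥ 0.85 and mean DICE ≥ 0.5 in at least 2 of 3
fixed seeds: classification saturates (AUROC 1.0) on every seed, two of
the three seeds reach DICE ≈ 0.88, and one seed falls into the
segmentation-collapse basin described above (DICE 0) — exactly the
stochastic failure mode the 2-of-3 rule exists for. The run costs
roughly 10 CPU minutes.

## Configuration and artifacts

Run configuration is JSON (the one structured format whose parser is
guaranteed in the target runtime; the schema mirrors the constructor
arguments of each module config), validated field by field before any
work. A single global seed expands into per-module seeds through a
fixed arithmetic derivation (`derive_seed`), so one integer reproduces
a whole run byte-for-byte: manifests, images, splits, weights, reports.
Checkpoints are RDS files stamped with a format version. Image formats
are handled by small self-contained codecs (grayscale PNG via zlib,
single-frame Explicit-VR little-endian DICOM with VOI LUT sequences,
uncompressed grayscale TIFF, raw/gzip NRRD as exported by 3D Slicer) —
none of the guaranteed runtime packages read these formats, and each
codec is round-trip tested; the PNG writer was additionally verified
against an independent reader.

## Limitations

* The hand-built network trains on CPUs at desk scale; full-scale
  (1024² crops, 64 base channels, 500 epochs) training is out of reach
  without an accelerator and is not attempted by any test.
* The synthetic contrast is deliberately easy; AUROC near 1.0 on
  phantoms says nothing about clinical discrimination.
* DICOM support covers the dialect the package writes (single-frame,
  uncompressed, Explicit VR little endian) — enough for round trips and
  LUT handling, not for arbitrary clinical archives.
* Batch normalisation, Dice/boundary losses, elastic deformation, and
  pretrained weights are intentionally absent: they are not part of the
  reference pipeline.
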
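---
title: "Two-stage detection of carotid artery calcifications in CBCT: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage detection of carotid artery calcifications in CBCT: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cervical carotid artery calcification (CAC) is an incidental finding in
dental cone-beam CT (CBCT) with real cardiovascular significance, easily
missed because CBCT has poor soft-tissue contrast and the deposits are
tiny — typically a handful of hyperdense pixels near the carotid
bifurcation, around the C3–C4 vertebral level. `cacseg` implements a
two-stage detection pipeline:

1. **Anatomical gating.** A small CNN classifies every axial slice as
   above or below the C2–C3 intervertebral disc level, producing a
   per-slice confidence in [0, 100]. A least-squares step-function fit
   reduces the confidence series to a single boundary slice; only slices
   at or below it proceed to stage 2.
2. **Patch-based semantic segmentation.** A compact U-shaped
   encoder–decoder labels every pixel as calcification or background,
   trained either on random overlapping patches (multi-patch sampling,
   "Method A") or on two fixed windows centred on the left/right carotid
   spaces ("Method B"), with an optional class-weighted cross-entropy
   loss that counteracts the extreme foreground rarity (≪ 1% of pixels).

Per-slice CAC calls derive from the binarized, component-filtered
foreground map, and are scored with the standard diagnostic metrics
(sensitivity, specificity, PPV, NPV, accuracy) plus per-class and mean
IoU for segmentation quality.

## The step-function boundary fit

Stage 1 treats each slice independently, so a scan yields a noisy series
$v_1, \dots, v_n$ of below-boundary confidences. A clean scan looks like
a step from 0 to 100. We fit the fixed-level step by least squares over
the single breakpoint $k \in \{0, \dots, n\}$:

$$\mathrm{SSE}(k) \;=\; \sum_{i \le k} v_i^2 \;+\; \sum_{i > k} (v_i - 100)^2 ,$$

computed for all $k$ in one pass with prefix sums. The boundary is the
first slice after the $k$ minimizing SSE; ties break toward the smallest
$k$, i.e. the superior-most boundary, which is the conservative choice
for a gate (it keeps more slices for stage 2). The extremes $k = 0$ and
$k = n$ are admissible and mean "entire scan below" / "entire scan
above". A free-level variant (`levels = "free"`), which estimates the
two plateau values by segment means, is provided for sensitivity
analyses but is off by default: with confidences that are genuinely
probabilities scaled to [0, 100], the 0/100 plateaus are the model, not
parameters to fit.

## Class-weighted cross-entropy

With foreground prevalence $f \ll 1\%$, a mean-reduced cross-entropy
gives the network almost no incentive to ever predict foreground — the
all-background predictor is a strong local optimum, and in practice a
few epochs of unweighted training converge exactly there. The weighted
loss

$$L = -\frac{1}{N}\sum_p w_{y_p} \log \hat p_p(y_p), \qquad
  w = (w_{\text{bg}}, w_{\text{fg}})$$

raises the penalty for every missed calcification pixel. The default
`class_weights = "auto"` sets $w_{\text{bg}} = 1$ and $w_{\text{fg}}$ to
the inverse foreground pixel frequency of the training patches (several
hundred at typical prevalence). With weights $(1, 1)$ the loss reduces
exactly to standard cross-entropy, which is how the unweighted baseline
is trained. Because inverse-frequency weights occasionally produce very
large batch gradients early in training, updates are clipped to a global
gradient norm (`grad_clip`, default 5) — a standard stabilizer that
leaves converged behaviour untouched.

A consequence worth understanding: a network trained with weight $w$ and
thresholded at 0.5 behaves like an unweighted posterior thresholded near
$1/(1+w)$ — strongly recall-biased. That is the intended trade: missed
calcifications are costly, false positives are reviewable. The
small-component filter in the slice decision rule exists precisely to
absorb some of that recall bias before the slice-level call.

## Network architectures

No deep-learning framework is assumed: both networks are small,
fully-specified CNNs with compiled (C++) conv/pool/upsample kernels and
an Adam optimizer, seeded and reproducible.

* **Slice classifier** (`classifier_config()`): three 3×3 conv blocks
  (8, 16, 32 channels) with 2×2 max-pooling, global average pooling and
  a 2-way softmax; inputs resized to `input_size` (default 96, matching
  the phantom's slice size). The published pipeline used a large
  pretrained backbone; here the backbone is a *pluggable slot* —
  `backbone` accepts any `fit`/`predict` pair — and the built-in network
  is trained from scratch, which suffices on phantoms and keeps the
  package free of downloaded weights.
* **Segmenter** (`seg_config()`): a depth-3 encoder–decoder, two 3×3
  convs per level (8/16/32 channels), nearest-neighbour upsampling with
  a 3×3 up-conv, skip concatenation at each level, 1×1 conv to two
  per-pixel logits. The same family scales to the published size (depth
  5, 64 base channels, 192–224 px patches) by configuration; the
  defaults are sized for CPU training in minutes.

Backpropagation was verified against central finite differences layer by
layer (agreement to ~1e-9 away from ReLU kinks).

## The synthetic phantom

Clinical CBCT data cannot be redistributed, so every stage is trained
and tested on a generated phantom (`phantom_config()`,
`generate_phantom_scan()`, `generate_dataset()`). Each scan emulates the
features the pipeline actually depends on:

* a stack of `n_slices` axial slices (default 64 at 96×96 px — a
  desk-scale stand-in for clinical 536×536 stacks; the clinical geometry
  is reachable through the config);
* `artifact_margin` (default 7) degraded high-noise slices at each stack
  end, mimicking cone-beam edge artifacts, which are trimmed before
  classification;
* a boundary index drawn uniformly within `boundary_fraction_range` of
  the stack, strictly inside the non-artifact region, at which the
  simulated vertebral cross-section changes shape (wide-and-flat above,
  rounder below) — the learnable signature of the C2–C3 transition;
* two lateral "carotid space" discs in which calcifications are seeded:
  each below-boundary slice carries a lesion with probability
  `lesion_prob`, a small bright disc (radius 1–4 px) whose intensity
  falls off quadratically toward the rim (partial-volume softening) and
  whose peak is drawn from 30–100% of `lesion_intensity`, so faint
  deposits sit near the noise floor — the conspicuity spectrum that
  makes class weighting matter;
* with probability `confounder_prob`, a calcified-cartilage look-alike
  blob at a medial location: identical appearance, background label, so
  appearance alone cannot separate the classes;
* additive Gaussian noise (`noise_sd`, default 0.05 on the [0,1] scale).

Foreground prevalence stays well below 1% by construction. Determinism
is strict: a `(config, scan_seed)` pair always produces bit-identical
scans, and dataset-level seeds derive from `config$seed` through a fixed
integer hash, so no seed bookkeeping is needed. Positive scans are
spread evenly through a dataset so contiguous train/test splits stay
balanced.

**What the phantom does not model:** beam hardening, Hounsfield
calibration, anatomical variability between patients, 3-D lesion
continuity across slices (lesion draws are per-slice independent), or
annotation noise. Passing tests therefore demonstrate that the pipeline
machinery is correct and that the published *mechanisms* (boundary
recoverability, the weighted-loss advantage under extreme imbalance)
reproduce — not that clinical accuracy figures transfer.

## Numerical and design choices

* **Indexing.** All slice indices are 1-based; `boundary_index` is the
  first below-boundary slice. `offset` from artifact trimming maps
  retained-series positions back to original stack coordinates.
* **Method B windows.** "Two fixed patches from the center" is realized
  as windows symmetric about the vertical midline and vertically
  centred — left window ending at the midline, right window starting
  after it — matching left/right carotid anatomy; the windows clip
  inward (and may overlap) when the image is narrower than two patch
  widths. Coordinates are pure functions of the image size.
* **Augmentation.** Rotation ±15°, shear ±8°, scale 0.9–1.1, brightness
  ±10%, horizontal flips — conservative magnitudes for axial anatomy,
  all configurable. Geometric transforms use bilinear interpolation for
  images and nearest-neighbour for masks, so masks remain exactly
  binary; brightness touches the image only. Alignment is testable:
  `transform_points()` exposes the exact point map of any applied
  transform, and mask centroids track it within 1 px.
* **Reassembly.** Overlapping patch probabilities are averaged
  per pixel; uncovered pixels get probability 0 (i.e., background),
  which is the conservative call for a detector.
* **Slice decision rule.** Threshold 0.5, drop connected components
  smaller than 3 px, call a slice positive at ≥ 3 surviving foreground
  pixels. The published work never states its pixel-to-slice rule; these
  defaults suppress single-pixel noise while keeping 2–3 px lesions
  detectable, and every run reports the rule it used.
* **Rounding.** Diagnostic percentages round half-up — 1 decimal for
  sensitivity/specificity/PPV/NPV, 2 for accuracy — matching clinical
  reporting convention. Zero-denominator metrics are reported as
  `NA` ("undefined"), never as 0.
* **mIoU aggregation.** Default `per_class_pooled` (pool intersections
  and unions per class, then average the two class IoUs); a
  `per_image_mean` variant is provided and labelled in the output, since
  published mean-IoU figures rarely state their aggregation. Empty-set
  IoU is defined as 1.
* **DICOM.** Slice stacks are read from PNG/TIFF directories (sorted by
  the numeric index embedded in filenames). DICOM import is out of
  scope for this build; series should be exported to PNG/TIFF first.

## Problem sizes used by the test-suite and acceptance runs

The heavier checks train real models at fixed, deliberately small sizes:
the boundary check trains the classifier on 24 phantom scans (64 slices
of 96×96 each, 5 epochs) and evaluates the maximum absolute boundary
error on 8 held-out scans; the loss-ordering check trains the segmenter
twice (weighted fixed-patch vs unweighted random-patch, 6 epochs, 48 px
patches from 8 scans) and compares held-out foreground IoU on 4 scans.
These sizes are the package's chosen reference conditions for its
synthetic study; larger configurations are a config change away.

## Known limitations

* The phantom's lesions are per-slice independent discs; volumetric
  lesion models and annotation-noise models would make the synthetic
  study stricter.
* The built-in networks are deliberately small; they saturate the
  phantom but are not claimed to match pretrained backbones on clinical
  data.
* Absolute clinical figures (e.g. published mIoU values near 0.76–0.83)
  are not reproducible without the clinical data; only ordering and
  bound properties are asserted on phantoms.
* Training is single-threaded CPU; at clinical scale (536×536, hundreds
  of slices) the defaults would need to grow and training would take
  hours, not minutes.
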
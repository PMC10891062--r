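---
title: "Iterative pseudo-balancing: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative pseudo-balancing: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the parameters that matter,
what the synthetic generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open. It states
no empirical result that the test suite or acceptance script does not
itself compute.

## The problem

Stem-cell time-lapse microscopy produces colony images in four
morphological classes — *dense* (pluripotent, fine uniform speckle),
*spread* (progenitors, coarse smooth texture), *differentiated* (mature
neurons, dark cell bodies with thin axonal protrusions) and *debris*
(dying cells, high-contrast bright-rimmed spheres) — at severely uneven
rates, with many composite colonies that contain several classes at
once and therefore admit no image-level label. Semi-supervised
student–teacher training with pseudo-labels can exploit the unlabeled
majority, but a pseudo-labeler trained on an imbalanced pool drifts
toward the majority class (confirmation bias), and minority-class
recall collapses.

## The training loop

`run_ipb()` composes four operations per epoch over the unlabeled set
U, with a balanced labeled subset L held out:

1. **Pseudo-labeling** (`assign_pseudo_labels`): the teacher scores one
   random in-mask patch per unlabeled image. The hard label is the
   argmax (lowest index on ties); items whose maximum softmax
   probability falls below τ = 0.65 are discarded for this epoch. The
   threshold is the published operating point; it trades label noise
   against sample efficiency, and the loop degrades gracefully when
   nothing clears it (see *Degenerate inputs*).
2. **Distribution estimation** (`estimate_distribution`): kept hard
   labels give counts `n_i` and proportions `p_i`. Classes with
   `n_i = 0` receive a floor pseudo-count of 1 *for weighting only*, so
   no weight is infinite; reported proportions use the raw counts.
3. **Balanced resampling** (`balanced_resample`): |U| items are drawn
   with replacement, item j of class c with probability proportional to
   `1/(m·p_c)`. The expected class share is exactly 1/m for every
   populated class — this is the balancing guarantee, and it holds in
   expectation regardless of the imbalance severity. The source text
   describes this step with a self-referential formula
   ("n_i = p_i · n_i"); the inverse-proportion multinomial implemented
   here is the reading that realises both the stated mechanism
   (inversely proportional weights) and the stated goal (a balanced
   dataset per epoch), and is fixed as the canonical interpretation.
4. **Student and teacher updates** (`student_step`, `teacher_step`):
   the student takes SGD steps (momentum 0.9, weight decay 1e-4) on
   cross-entropy against the hard pseudo-labels. The teacher then moves
   along the meta-gradient of the *updated* student's loss on L.

### The meta-gradient

With hard pseudo-labels the chain from teacher parameters to the
student's labeled loss is not differentiable, so the teacher update
uses the standard first-order meta-pseudo-label signal
`h = η_S · ⟨g_l, g_u⟩` — the inner product of the updated student's
labeled-loss gradient with the student's pseudo-batch gradient — and
moves the teacher along `h · ∇_{θ_T} CE(ŷ_u, θ_T(x_u))`. A positive
`h` means the pseudo-labeled step helped the student on labeled data,
so the teacher is reinforced toward those labels; a negative `h`
pushes it away.

With *soft* pseudo-labels the exact one-step meta-gradient exists in
closed form: for one plain student step,
`dL_l/dθ_T = −η_S ∇_{θ_T} (1/N) Σ_{jk} p_T,jk · a_jk` with
`a_jk = ⟨g_l, ∇_{θ_S}(−log p_S,jk)⟩`. `meta_teacher_grad_exact()`
implements this route (one backward pass per item-class pair, so small
batches only), and a one-parameter scalar instance
(`toy_meta_gradient()`) shares the same per-class algebra. Both are
validated against central finite differences in the test suite; the
production loop uses the first-order signal for cost reasons, which is
the same choice the original meta-pseudo-label implementations make.

An optional consistency term (weight λ, default 1 in the full
configuration) adds the KL divergence from the teacher's prediction on
a weakly augmented view (no gradient) to its prediction on a strongly
augmented view, masked at confidence τ. Both views pass through the
network in training mode so they share batch-normalisation statistics;
with identical views the term is exactly zero. The weak view is an
independently sampled unaugmented patch of the same image rather than
a byte-identical copy of the strong view's source crop — same-image,
different-view consistency, which is the spirit of the original
unsupervised-data-augmentation regulariser; its exact weighting in the
original experiments is unstated, so λ is config-exposed with a 0
switch.

### Warm-up, selection, determinism

The student learning rate ramps linearly over the first 10 epochs
(η_S · e/10), keeping early meta-signals small while the student
catches up to the pre-trained teacher. After each epoch the student is
scored on deterministic (mask-centred, unaugmented) patches of L, and
the best-scoring student is kept as the final model. L doubles as the
selection set because the test split must stay unseen; this is a
deliberate choice where the source is silent, and it biases selection
toward L-performance, which is acceptable because L is balanced.
Every entry point takes a seed; named substreams derived by
`derive_seed()` keep data generation, augmentation, sampling and
initialisation independent, and a full run is reproducible
bit-for-bit.

## Hyperparameters

| parameter | default | units | why |
|---|---|---|---|
| η_S, η_T | 0.005 | – | published SGD rate for both networks |
| momentum / weight decay | 0.9 / 1e-4 | – | published optimizer settings |
| batch size | 32 | patches | published |
| pre-train / IPB epochs | 200 / 200 | epochs | published full-scale schedule; scaled runs use 30/40 |
| warm-up | 10 | epochs | published plateau length |
| τ | 0.65 | probability | published confidence threshold |
| λ | 1.0 | – | consistency weight; magnitude unstated in the source, 0 disables |
| patch sizes | 224/112 dual, 128 single | px | published; 179.2/89.6/102.4 μm at 0.8 μm/px |
| min coverage | 0.5 | fraction | "within the colony borders" made quantitative; 50-trial rejection sampling with max-coverage fallback guarantees termination |
| augmentation probability | 0.25 | per transform | published; five transforms (h-flip, v-flip, rotation U(0,180)°, joint brightness/contrast U(0.8,1.2), blur σ U(0.3,1.0) px); magnitudes are package defaults, unstated in the source |
| segmentation | 3×3 blur, disk r=3, min area 2000 px | – | published six-step pipeline |

## The synthetic world

The real dataset is available only on request, so all tests run on a
generated stand-in (`gen_class_texture`, `gen_scene`, `gen_dataset`)
that reproduces the *statistical structure* the method relies on:

- four classes distinguishable by local texture, rendered so that one
  scalar statistic (mean local 3×3 variance) separates them with
  disjoint bands — spread ≲ 1e-3 < dense ≈ 2.4e-3 < diff ≈ 1.1e-2 <
  debris ≈ 3.4e-2. Amplitudes were fixed once so a nearest-centroid
  classifier on the statistic exceeds 90% on held-out seeds (it reaches
  100%), which is what makes the downstream learning tests well-posed;
- darker, textured colonies on a bright low-noise background
  (phase-contrast polarity), so entropy-based segmentation behaves as
  on real data;
- composite multi-label scenes with 2–4 colonies of distinct classes;
- severe imbalance and the published size extremes (55×85 to 771×1298
  px, log-uniform in between — only the extremes are published).

What it does **not** emulate: optical artifacts (halos, shading,
debris outside colonies), within-class heterogeneity across
experiments, contiguous class boundaries inside one colony, and
temporal correlation between frames. A green test therefore
establishes that the algorithmic machinery is correct and that
balancing helps when minority features are learnable — not that the
published accuracy on the real dataset is reproduced. The headline
numbers of the source (e.g. average TPR 0.8872) depend on that
request-only dataset and ~200-epoch trainings and are out of scope by
design.

### The scaled-down effectiveness experiment

The acceptance suite runs the method's central contrast at desk scale:
unlabeled counts 30:10:10:1 (30/10/1/10 with *differentiated* as
minority, mirroring the real class that is rarest), balanced labeled
(8/class) and test (24/class) sets, tiny dual-stream networks, 30
pre-training and 40 IPB epochs, five paired seeds sharing one
pre-trained teacher per seed. The mechanism under test is visible in
the sampling arithmetic: the balanced arm oversamples the lone minority
image roughly 13-fold per epoch, the imbalanced arm sees it about once.
24 test images per class give TPR resolution 1/24 for strict paired
comparisons. Thirty pre-training epochs is the depth at which the tiny
teacher's confidence clears τ; below that every epoch falls back to
soft labels and the balanced/imbalanced arms are identical by
construction. These choices follow from those well-posedness arguments.
The distribution-tracking check averages the per-epoch L1 distance
between estimated and true class proportions across the five balanced
runs in four 10-epoch blocks; single-run traces at ~50 kept
pseudo-labels per epoch carry binomial noise of the same order as the
late-training signal.

## Architectures

All classifiers share one pattern: 3×3 convolutions (stride 1, or 2
for downsampling), each followed by batch normalisation and ReLU;
global average pooling per stream; feature concatenation; batch
normalisation of the concatenated vector; then fully connected layers
with ReLU between. Global average pooling decouples the head from the
patch size, which is what lets the tiny variants train in seconds —
the flattening scheme is unstated in the source, and this is the
choice that keeps patch sizes configurable.

- `dual_stream_vgg`: two VGG-style streams (64→512 channels) on the
  224/112 pair, 512 features each, concatenated to 1024.
- `compact_hires`: the compact high-resolution classifier as described
  textually — 10 convolutional and 5 fully connected layers, two
  parallel-resolution branches over one input fused before the head.
  The printed 15-layer description conflicts with the canonical
  high-resolution-network architecture it names; the textual
  description is taken as authoritative, and per-branch widths are
  config defaults because they are not fully printed.
- `tiny_test` / `tiny_single`: 2 convolutions per stream at width 16
  on 32/16 px inputs, both stride 2 (the stride schedule is free in
  the contract; stride 2 quarters the activation size and keeps the
  whole paired-seed experiment inside the test-time budget).

Initialisation is Kaiming (`N(0, √(2/fan_in))`, zero biases); the
empirical weight variance is tested against the closed form. The
engine (convolution via cached-index im2col and BLAS matmul, batch
norm, backprop, SGD) is written in base R because no deep-learning
framework exists in the target environment; gradient correctness is
established by the finite-difference tests rather than by trust in a
framework.

## Numerical and degenerate-input choices

- **Otsu on a degenerate histogram** (single-valued entropy map, e.g.
  a constant image) returns empty foreground rather than
  all-foreground.
- **Entropy dynamic range**: the local-entropy map is rescaled to
  [0,1] before Otsu; the source does not state its range handling.
  Entropy uses 64 gray bins over a disk of radius 3 (29 pixels), in
  bits -- the reference rank filter sees full 8-bit data, and 64 bins
  is the coarsest quantisation at which within-colony local histograms
  stay stably above background (32 bins makes colony entropy patchy and
  fragments masks under opening); finer binning costs proportionally
  more and changes nothing downstream.
- **Connectivity** is 8-connected for foreground components (merges
  diagonal colony bridges, matches common morphology suites; the
  source is silent), 4-connected for the background flood in hole
  filling.
- **Coordinates**: 0-based, row-major, half-open boxes in every
  external interface; R's 1-based indexing appears only at the point
  of subsetting.
- **Resize rule**: images smaller than the patch are upscaled so the
  minimum side equals the patch side, aspect preserved, long side
  rounded half-up (55×85 → 128×198).
- **Rotation/resampling** is bilinear with clamp-to-edge for
  out-of-support samples; a θ/−θ round trip on smooth images stays
  within 0.05 absolute error.
- **Empty epoch** (no pseudo-label clears τ): the student trains on
  soft teacher distributions for that epoch, the teacher is left
  unchanged (the first-order meta-signal is defined for hard labels),
  and a warning is logged.
- **Empty mask** at evaluation: centre-patch fallback, logged.
- **Ties** in argmax resolve to the lowest class index everywhere.
- **Zero-variance fold comparisons**: the pooled-variance t statistic
  is reported as 0 (p = 1) for identical lists and ±∞ (p = 0) for a
  pure shift, flagged as degenerate rather than erroring.

## Known limitations

- The first-order teacher signal is an approximation; the exact route
  is exposed but quadratic in batch·classes backward passes.
- Pure-R convolution limits full-scale (224 px, 512-channel) training
  to patience; the architectures are faithful but the published
  200-epoch schedules are not run in CI.
- The labeled set doubles as the model-selection set (the source never
  names one); with very small L this inflates selection variance.
- The published labeled-image counts at the 1/5/10% budgets (191, 938,
  1873) are not reproducible from any simple rounding of the published
  totals; `labeled_budget()` fixes `floor(fraction × n_single_class)`,
  which does reproduce the 50% and 80% counts (9341, 14946) exactly.
- PGM replaces PNG/TIFF as the image format because the target
  environment has no R image codec; the format is lossless 8-bit
  grayscale either way.
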
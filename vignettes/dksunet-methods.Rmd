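---
title: "Dual-branch kernel-selecting segmentation of breast tubules: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch kernel-selecting segmentation of breast tubules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tubule formation is one of the three factors of the Nottingham grading
system for breast cancer. In H&E-stained tissue a tubule is a clear lumen
surrounded by a ring of epithelial cells; segmenting tubules is hard because
their shapes vary (tubular, round, oval), because epithelium and stroma can
look locally similar, and because tissue-shrinkage clefts produce white gaps
that mimic lumina. `dksunet` implements a two-branch ("double U-Net")
encoder-decoder network specialised for this task, together with the full
training stack, data preparation, evaluation metrics, and a synthetic data
generator so that the entire pipeline can be exercised end to end without
clinical data.

## The network

The model is two U-shaped subnetworks connected end to end.

**Branch 1** encodes the RGB tile with a VGG19-style encoder: five stages of
3×3 convolutions (2, 2, 4, 4, 4 per stage; widths 64, 128, 256, 512, 512
scaled by a global width multiplier), each convolution followed by batch
normalisation and ReLU, with 2×2 max pooling between stages. The bottleneck
passes through atrous spatial pyramid pooling (ASPP): parallel branches at
dilation rates (1, 6, 12, 18) — a 1×1 convolution for rate 1 — plus an
image-level pooled branch, concatenated and projected by a 1×1 convolution.
Four decoder blocks then upsample back to full resolution; each block is
bilinear ×2 upsampling → concatenation with the matching-scale encoder skip
→ two (3×3 conv → BN → ReLU) stages → a squeeze-and-excitation (SE) gate. A
kernel-selecting module (below) sits between the last decoder block and the
1×1-convolution + sigmoid head, which emits a coarse tubule probability
mask.

**Gating.** The input image is multiplied channel-wise by branch 1's mask so
branch 2 sees only the candidate tubule regions. During training the
*continuous* sigmoid output is used — a binarised gate would block all
gradient flow into branch 1 from branch 2's loss. At inference the package
offers both conventions (`gating_mode = "soft"` or `"hard"`, the latter
thresholding at 0.5); soft is the default, matching the double-U-Net
lineage.

**Branch 2** re-encodes the gated image with a dense-connectivity encoder.
Standard DenseNet stems (7×7 stride-2 convolution + pool) cannot provide a
full-resolution skip, so the encoder here is: a full-resolution two-conv
stem (2 × growth-rate channels), then four stages of [transition, dense
block]. A transition is BN → 1×1 convolution to `floor(0.5 · C)` channels →
2×2 average pooling; a dense block with `L` layers and growth rate `g` runs
`L` times (BN → ReLU → 1×1 conv to `4g` → BN → ReLU → 3×3 conv to `g`) and
concatenates each layer's output onto the running stack, so the input
channels survive verbatim as the leading slab and the output has
`C + L·g` channels. Default block lengths are (4, 6, 8, 10) with growth 16.
Branch 2's decoder blocks concatenate **two** skips per scale — one from
each encoder — before their convolutions; its KSM + head produce the final
mask.

## The kernel-selecting module (KSM)

The KSM adapts the receptive field per channel. Three parallel same-padding
convolutions with kernels 3×3, 5×5 and 7×7 (literal kernels, not dilated
equivalents) map the C-channel input U to U′, U″, U‴. Their sum Ū is
globally average-pooled, passed through a shared bottleneck FC layer of
width `max(ceiling(C/r), 32)` (reduction r = 8) with batch normalisation and
ReLU — the selective-kernel convention — and then through three
branch-specific FC maps giving per-channel logits α′, β′, γ′. A softmax
across the three branches yields attention vectors with
α_c + β_c + γ_c = 1 for every channel, and the output is the convex
combination

V_c = α_c·U′_c + β_c·U″_c + γ_c·U‴_c,

so V always lies elementwise between the min and max of the three branch
maps — a property the test suite asserts on random inputs. Because the
attention uses 1-D batch normalisation over the batch axis, it degenerates
at batch size 1 in training mode (zero variance); training therefore uses
batches of at least 2 (default 4). Inference uses running statistics and is
unaffected.

## Loss, metrics and conventions

Training minimises the soft Dice loss, `1 − (2Σpt + s)/(Σp + Σt + s)` with
smoothing `s = 1e-6`, averaged over the batch and applied to **both** heads
with equal weights (0.5/0.5, configurable): supervising the coarse mask as
well keeps branch 1 anchored to the tubule ground truth.

Evaluation reports Dice = 2TP/(2TP+FP+FN), the foreground IoU
TP/(TP+FP+FN) (`miou_paper`, the printed convention of the comparison
tables this package mirrors), the two-class mean IoU reported alongside for
comparability with other work, precision TP/(TP+FP), recall TP/(TP+FN) and
F1. One source formula prints precision as TP/(TP+FN), which duplicates
recall; this is treated as a typo, with the printed variant available via
`compute_metrics(..., printed_precision = TRUE)` for audit. Zero-denominator
ratios are defined as 1 when both masks are empty and 0 otherwise. Because
whether published tables are per-image means or pooled counts is generally
unstated, `aggregate_metrics()` and `evaluate_model()` always report both.

## Data preparation

Large source images (e.g. 2000×2000) are cut into 16 random overlapping
512×512 tiles; the sampling scheme is uniform independent top-left corners
with replacement (0-based, half-open extents), with a deterministic grid
mode for inference coverage. Masks are single-channel 8-bit PNGs
(255 = tubule); grey values are thresholded at 128 with a warning. Images
are resized bilinearly, masks with nearest neighbour. Dataset splits are
80/10/10 by default, seeded, at source-image level so tiles of one image
never leak across splits; validation and test receive `floor(0.1·n)` images
each and training the remainder (398 ids → 320/39/39). Small-component
denoising removes 8-connected foreground components below a caller-chosen
`min_area` (the MATLAB `bwareaopen` convention; the area threshold is
data-dependent and deliberately has no default). `annotation_bootstrap()`
composes prediction and denoising over a directory of unlabeled images and
writes a manifest for later manual refinement, supporting a coarse-to-fine
annotation workflow.

## The synthetic data generator

`generate_sample()` emulates the geometry that makes tubule segmentation
non-trivial rather than the full appearance of H&E tissue. On a pink
stroma-like background it draws, per tubule, a rotated ellipse: a
near-white lumen (semi-axes uniform in 10–26 px at the 128 px default
profile) surrounded by a darker epithelial annulus (thickness 3–6 px)
stippled with nuclei dots; the ground-truth mask is exactly the union of
the outer ellipses (ring + lumen, the whole-tubule labelling convention).
Thin white slits — shrinkage-cleft distractors — are drawn on background
pixels only and are excluded from the mask, so brightness alone cannot
solve the task: the model must learn the ring context. Multiplicative
Gaussian speckle (sd 0.05) is applied and the image quantised to 8 bits,
making output byte-identical for a given (parameters, seed) pair;
per-sample seeds in `generate_dataset()` derive deterministically from a
master seed.

What the generator does **not** emulate: stain variation, texture of real
stroma and epithelium, touching/merging glands, nuclear pleomorphism, and
annotation noise. Passing the end-to-end tests therefore demonstrates that
the architecture, gradients, optimiser and pipeline work — scores near 1.0
on this synthetic corpus say nothing quantitative about performance on
clinical H&E data, which requires real annotated slides and full-scale
training.

## Numerical choices

* All convolutions are stride-1 with same zero padding; downsampling is done
  only by pooling, upsampling only by bilinear ×2 interpolation
  (align-corners disabled). Dilated kernels larger than the feature map are
  legal — zero padding makes them computable, as at small ASPP bottlenecks —
  and only absurd rates (> 4096) are rejected.
* Convolution, pooling and upsampling kernels run in C++ (im2col + BLAS
  sgemm) in float32, the precision segmentation networks are ordinarily
  trained in; surrounding arithmetic is double. Gradient correctness of
  every operator is verified against central finite differences, and the
  convolution against a direct quadruple-loop oracle.
* Weights use He-normal initialisation seeded from the model configuration,
  so builds are bit-reproducible. The SE squeeze layer is initialised with
  0.25-scaled weights and bias +1: at small width multipliers its bottleneck
  can be a single unit, and a symmetric zero-bias init can leave that unit
  dead (zero gradient) from the first step.
* Batch norm uses eps 1e-5, momentum 0.1, biased batch variance, and
  running statistics at inference; convolutions followed by BN carry no
  bias.
* Binarisation uses a strict `> threshold` comparison (a probability exactly
  at the threshold is background), default 0.5.
* Dice smoothing 1e-6; with both masks empty the loss is 0 and the metric
  conventions above apply.
* Adam with β₁ = 0.9, β₂ = 0.999, eps = 1e-8. The shipped training defaults
  (learning rate 1e-5, batch 4, 200 epochs) describe the full-scale 512 px
  protocol; the scaled-down profile used by the package's own tests and by
  `scripts/acceptance.R` — width multiplier 0.25 at 128 px tiles, learning
  rate 1e-3, ≤ 4 epochs, 120–200 training tiles — was chosen once as a
  desk-scale configuration on which the synthetic task is comfortably
  learnable, and is stated here as the package's reference problem size.

## Open design points and how they were resolved

* The sources describe the decoder once as "SE block, 3×3 convolutions,
  upsampling" and once as upsample → concat → convolutions with SE after;
  the latter ordering is implemented.
* "Two 3×3 convolution operations" per decoder block is read as one
  two-convolution unit, not two such units.
* The dense encoder's variant, pretraining, and inter-stage downsampling are
  unspecified in the architecture's description; this package uses the
  custom full-resolution-stem arrangement above, random initialisation, and
  transitions with compression 0.5, and makes no attempt to reproduce
  published parameter totals (the variant is under-determined).
* The softmax constraint is written with a λ_c in some sources; it is read
  as γ_c.
* Whether the inter-branch gate was binary or continuous in the original
  training is unstated; continuous is used for differentiability, binary
  offered at inference.
* Model selection uses best validation Dice of the binarised final mask;
  early stopping is optional and off by default.

## Limitations

The engine is CPU-only and single-threaded apart from BLAS; full-scale
training (512 px tiles, width multiplier 1, 200 epochs) is out of desk
scope. Inputs must have spatial dimensions divisible by 16 (callers may
resize, as `predict_to_file()` does with a warning). Whole-slide formats,
stain normalisation and multi-class output are out of scope.
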
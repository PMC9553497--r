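# dksunet

Semantic segmentation of breast tubules in H&E-stained histology with a
dual-branch kernel-selecting U-Net, implemented end to end in R.

Tubule formation is one of the three factors of the Nottingham grading
system for breast cancer, and segmenting tubules in hematoxylin-and-eosin
images is hard: a tubule is a clear lumen wrapped in a ring of epithelial
cells, its shape varies from tubular to round to oval, and white
tissue-shrinkage clefts mimic lumina without being tubules. This package is
for computational-pathology researchers who want a fully inspectable,
dependency-light reference implementation of the architecture and its
training pipeline — every layer, gradient and optimizer step is in this
package (C++ kernels via Rcpp/RcppArmadillo for convolution, pooling and
upsampling; no external deep-learning framework).

## The model

Two U-shaped subnetworks connected end to end:

1. **Branch 1**: VGG19-style encoder (3×3 convolutions, widths
   64–512 × a global width multiplier) → atrous spatial pyramid pooling
   (dilation rates 1, 6, 12, 18) → four decoder blocks (bilinear ×2
   upsample, skip concatenation, two conv–BN–ReLU stages,
   squeeze-and-excitation gate) → kernel-selecting module → 1×1 conv +
   sigmoid, giving a coarse tubule mask `m₁`.
2. **Gating**: the input is multiplied by `m₁`, so branch 2 sees only the
   candidate regions.
3. **Branch 2**: dense-connectivity encoder (full-resolution stem, then
   four [transition, dense block] stages; each dense layer is
   BN→ReLU→1×1→BN→ReLU→3×3 with its output concatenated onto the running
   stack) → ASPP → four decoder blocks that concatenate skips from **both**
   encoders → kernel-selecting module → head, giving the final mask `m₂`.

The **kernel-selecting module** (KSM) runs 3×3, 5×5 and 7×7 convolutions in
parallel (U′, U″, U‴), pools their sum, and derives per-channel softmax
attention (α, β, γ with α_c + β_c + γ_c = 1) from a shared bottleneck FC
layer; the output V_c = α_c U′_c + β_c U″_c + γ_c U‴_c adapts the receptive
field channel by channel.

Training minimises the soft Dice loss `1 − (2Σpt + s)/(Σp + Σt + s)` on both
heads (weights 0.5/0.5) with Adam. Evaluation reports Dice, foreground IoU
(`mIou` in the usual table convention), two-class mean IoU, precision,
recall and F1, with both per-image-mean and pooled aggregation.

The package also implements the surrounding pipeline: random overlapping
512×512 tiling of large source images, bilinear/nearest resizing, binary
mask PNG I/O, 8-connected small-component removal (`bwareaopen`
convention), seeded 80/10/10 source-level splits, an annotation-bootstrap
step for coarse-to-fine labelling, and a seeded generator of histology-like
synthetic tiles (elliptical lumina with epithelial rings and nuclei,
plus unlabeled cleft distractors) with exact ground-truth masks.

## Worked example

Train a width-0.25 model on 48 synthetic 128 px tiles and evaluate on 16
held-out tiles (about two minutes on one CPU):

```r
library(dksunet)

params <- synthetic_params()                  # 128 px H&E-like tiles
train <- lapply(1:48, function(i) {
  s <- generate_sample(params, seed = 100 + i)
  list(image = s$image, mask = s$mask)
})
val <- lapply(1:16, function(i) {
  s <- generate_sample(params, seed = 9000 + i)
  list(image = s$image, mask = s$mask)
})

model <- dks_model(model_config(input_size = 128, width_multiplier = 0.25,
                                seed = 7))
print(model)
#> Dual-branch kernel-selecting U-Net
#>   input: 128x128x3 (any div-16 size runs)  width multiplier: 0.25
#>   branch 1: VGG19-style encoder (16, 32, 64, 128, 128)
#>   branch 2: dense encoder (stem 8, growth 4, blocks 4-6-8-10)
#>   ASPP rates (1, 6, 12, 18) @ 16 ch; decoder widths (64, 32, 16, 8); KSM 3/5/7
#>   gating: soft;  parameters: 1,800,160

fit <- train_model(model, train, val,
                   train_config(learning_rate = 1e-3, batch_size = 4,
                                epochs = 3, seed = 11))
#> epoch   1/3  train loss 0.4873  val loss 0.5321  val Dice 0.4680
#> epoch   2/3  train loss 0.2777  val loss 0.2672  val Dice 0.9264
#> epoch   3/3  train loss 0.1684  val loss 0.1172  val Dice 0.9834

evaluate_model(fit, val)
#> Evaluation over 16 image(s), threshold 0.50
#>   per-image mean: Dice 0.9834 | mIoU(fg) 0.9674 | IoU(2-class) 0.9761 | P 0.9803 | R 0.9867 | F1 0.9834
#>   pooled:         Dice 0.9841 | mIoU(fg) 0.9687 | IoU(2-class) 0.9771 | P 0.9813 | R 0.9869 | F1 0.9841

mask <- predict_mask(fit$model, val[[1]]$image)   # (H, W) 0/1 matrix
```

The validation Dice climbing from 0.47 to 0.98 over three epochs shows the
two-branch network learning to separate true tubules (lumen + ring) from
the white cleft distractors, which brightness alone cannot do. Scores this
high reflect the synthetic task's simplicity, not clinical performance; see
the methods vignette (`vignettes/dksunet-methods.Rmd`) for what the
generator does and does not emulate.

A command-line front end over the same functions is installed at
`inst/cli/dksunet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dksunet.R", package="dksunet"))')" \
    synth --out data/synth --n 100 --size 128 --seed 1
```

with subcommands `synth | tile | split | train | evaluate | predict |
bootstrap` (use `--config config.yaml` to override model and training
defaults).

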
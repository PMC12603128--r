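# spineseg

Semantic segmentation of sagittal lumbar-spine MRI in R, built around an
enhanced U-Net: the first encoder block is a four-branch **Inception module**
(1x1/64; 1x1/96 → 3x3/128; 1x1/16 → 5x5/32; 3x3 max-pool → 1x1/32,
concatenated to 256 channels) and a **dual-output** head adds an auxiliary
8x8 softmax at the bottleneck whose loss supplements the final
full-resolution head during training (deep supervision).  The intended users
are medical-imaging researchers who want a fully inspectable, CPU-runnable
reference implementation of this architecture — there is no deep-learning
framework underneath: convolutions, batch normalisation, pooling, transposed
convolutions, reverse-mode gradients and Adam are implemented in the package
(R + C++ kernels).

Segmentation assigns each pixel of a 128x128 T1-weighted slice to
foreground spinal structures vs background (2 classes) or to
background/vertebra/intervertebral-disc/spinal-canal (4 classes).  Training
minimises, with equal head weights,

    L = w_f · L(final head, mask) + w_b · L(bottleneck head, 8x8 mask)

where `L` is one of: binary cross-entropy; Dice loss
`1 − (2Σyŷ + s)/(Σy + Σŷ + s)` (batch-wise per channel, smoothing s = 1);
focal loss `α(1−p_t)^γ(−log p_t)` with α = 0.5, γ = 2; the compound
`λ₁·BCE + λ₂·Dice` (λ₁ = λ₂ = 1); or the categorical variants (CCE,
CCE-Dice) for 4 classes.  Evaluation pools per-class confusion counts into
mIoU, accuracy, precision, recall and F1, and measures boundary agreement by
Hausdorff distance and average symmetric surface distance in pixels.

The package also ships the preprocessing pipeline (T1 series selection,
central slice, 8-bit rescale, 128x128 resize, [0,1] normalisation, one-hot
masks with the 8x8 bottleneck target; NIfTI and MetaImage readers), a
Grad-CAM explainer, a multi-seed stability harness, and a seeded synthetic
**spine phantom** generator so the whole stack is testable without clinical
data.  See `vignettes/spineseg-methods.Rmd` for the full methods account.

## Worked example

Train the quarter-scale network on 80 synthetic spine phantoms (64x64,
Dice loss at both heads, Adam 1e-3, batch 2, 30 epochs):

```r
library(spineseg)
bench <- run_phantom_benchmark(seed = 1)
bench$fit
#> <spine_unet_fit>
#>   loss    : dice (lr 0.001, batch 2, 30 epochs)
#>   split   : 51 train / 13 val / 16 test
#>   loss    : first epoch 0.4649 -> final 0.0410 (val 0.0416)
str(bench$val_metrics)
#> List of 5
#>  $ miou     : num 0.998
#>  $ accuracy : num 1
#>  $ precision: num 0.998
#>  $ recall   : num 0.999
#>  $ f1       : num 0.999
cat(sprintf("test HD %.4f px, ASSD %.4f px\n", bench$test_hd, bench$test_assd))
#> test HD 0.7500 px, ASSD 0.0050 px
```

The Dice loss falls from 0.465 to 0.041 over 30 epochs and held-out phantoms
are segmented almost perfectly (validation mIoU 0.998; mean Hausdorff
distance under one pixel), confirming that the architecture, losses,
gradients and metrics are wired correctly end-to-end.  Phantoms are much
easier than clinical MRI, so these numbers characterise the implementation,
not clinical performance.

The full-size model is exact about its complexity:

```r
count_params_analytic(unet_config())
#> $total
#> [1] 31475396
#> $trainable
#> [1] 31463140
#> $non_trainable
#> [1] 12256
```

and `count_params_built(build_unet(unet_config()))` returns the same counts
measured on the realized weights.  `summary()` on a model prints the layer
table; `plot()` on a fit draws the loss curves; `gradcam()` produces
class-discriminative heatmaps.

A command-line front end over the same functions lives in
`inst/cli/spineseg.R` (subcommands `phantom`, `preprocess`, `train`,
`evaluate`, `gradcam`).

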
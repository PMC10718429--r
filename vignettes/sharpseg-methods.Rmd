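---
title: "Sharp Attention U-Net segmentation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharp Attention U-Net segmentation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharpseg)
```

## The problem

Breast ultrasound is cheap and radiation-free, but B-mode images are noisy:
multiplicative speckle, attenuation shadows, and low lesion/background
contrast make manual lesion outlining slow and operator-dependent. This
package implements a family of encoder-decoder segmentation networks for
binary lesion masks in grayscale breast ultrasound, together with the full
protocol around them: CLAHE contrast enhancement, paired affine
augmentation, BCE-Dice training, a pooled pixel-wise metric suite, and
pairwise model comparison by McNemar tests. A synthetic speckle-phantom
generator stands in for clinical data so that every stage is exercisable
and testable offline.

## Architectures

All four variants share a U-Net backbone: `depth` encoder levels (two 3x3
same-padding convolutions + activation, dropout 0.1, 2x2 max-pooling,
channels doubling from `base_filters`), a two-convolution bottleneck
(no dropout: regularization is placed in the encoder and decoder blocks),
and a mirrored decoder (learned 2x2 stride-2 transposed-convolution
upsampling, skip concatenation, two convolutions, dropout 0.5), closed by a
1x1 convolution + sigmoid that emits a probability map at input resolution.
The variants differ only in what each skip connection carries:

* **unet** — raw encoder features.
* **sharp** — encoder features convolved depthwise with the fixed 3x3
  kernel `[[0,-1,0],[-1,5,-1],[0,-1,0]]` (identity plus negative
  Laplacian). The kernel sums to one and we use edge-replicate padding, so
  constant maps pass unchanged and no parameters are added. The deepest
  skip (last encoder level into the first decoder level) is left
  unsharpened; removing that one filter is part of the design.
* **attention** — an additive attention gate per skip:
  `a = sigmoid(Ws^T swish(Wx^T x + Wg^T g))` with 1x1 channel-wise
  convolutions and both biases fixed at zero; the skip features are
  multiplied elementwise by the single-channel coefficient map `a`. The
  gating signal `g` is the decoder feature from one level coarser brought
  to the skip's resolution by the decoder's learned transposed
  convolution; we reuse that upsampled tensor as `g` rather than learning
  a second upsampler, which keeps one transposed convolution per level.
* **sharp_attention** — both of the above in parallel: the decoder block
  receives the concatenation of the upsampled decoder features, the gate
  output, and the sharpened encoder features (sharpening acts on the raw
  features, not on the gate output). At the deepest level the sharpening
  branch passes raw features, mirroring the sharp variant, while the gate
  is kept at every level.

Channel widths are not part of the published description; `base_filters`
defaults to 16 (64 reproduces classic U-Net widths, 8 is used in the
desk-scale experiments below). No batch normalization is used anywhere, and
the gates always use swish internally regardless of the backbone
activation. The compute engine — convolution, pooling, transposed
convolution, their adjoints, and Adam — is compiled code inside the
package; analytic gradients are verified against central finite differences
in the test suite.

## Preprocessing and augmentation

**CLAHE.** Each of `tile_rows x tile_cols` tiles gets an `N`-bin histogram
clipped at `beta = (M/N) * (1 + (alpha/100) * (S_max - 1))` (`M` = tile
pixel count); the clipped excess is redistributed uniformly over all bins
in a single pass. The tile mapping is the cumulative histogram rescaled so
the lowest occupied level maps to 0 and the top to `N - 1`; a tile whose
histogram occupies a single level keeps the identity mapping, so constant
images are exact fixed points. Pixels blend the four surrounding tile
mappings bilinearly, clamping to edge tiles at the border. Defaults
(8x8 tiles, `N = 256`, `alpha = 100`, `S_max = 4`, i.e. a clip limit of
four uniform bin counts) are conventional choices: the clip-limit formula
is parameterized exactly, but no published tile grid or clip factor exists
to reproduce, so these are package defaults, exposed in the configuration.
CLAHE is applied at native resolution before resizing.

**Augmentation.** One affine warp per training sample per epoch — rotation
(uniform in [-45, 45] degrees) o shear ([-0.03, 0.03], interpreted as a
shear coefficient along x) o zoom (scale `1 + z`, z in [-0.08, 0.08]) o
shift (±15% of width/height), composed about the image centre, then a fair
horizontal coin-flip. Image and mask receive the identical warp; sampling
is bilinear with edge replication for images and zero fill for masks (no
lesion pixels are invented at borders), and the warped mask is re-binarized
at 0.5. Brightness (uniform in [0.99, 1.07]) multiplies the image only.
Validation and test data are never augmented.

## Training, thresholding, evaluation

The loss is the sum of mean binary cross-entropy (probabilities clamped at
1e-7) and soft Dice loss (`epsilon = 1e-5`), pooled over the minibatch.
Optimization is Adam with learning rate 0.001, `beta1 = 0.9`,
`beta2 = 0.9`, `epsilon = 1e-7`; note `beta2 = 0.9` is the published
setting and is implemented as printed even though 0.999 is the usual Adam
default. The reference protocol trains 300 epochs at batch size 32 with a
random 80/10/10 split (single seeded shuffle, floor cuts, no
stratification; 780 records split as 624/78/78). After each epoch the
validation soft Dice is computed with dropout off; the best weights are
checkpointed and restored, with early stopping after 50 stale epochs.

The evaluation threshold is derived on pooled validation pixels as the
Youden point (max TPR − FPR) of the ROC curve, with 0.4 — the published
operating point — as the default when derivation is skipped. The test set
never influences the threshold. Reported metrics pool pixel counts over
the whole evaluated set ("micro" aggregation): accuracy, precision,
sensitivity, specificity, F1 and Jaccard from the binarized masks, hard
Dice `2TP/(2TP+FP+FN)`, and the soft-probability loss and Dice loss. A
ratio with an empty denominator scores 1 if its error count is also zero
and 0 otherwise.

## Model comparison

Two models are compared by McNemar's test on pooled discordant pixels:
`b` counts pixels where A is correct (against ground truth) and B wrong,
`c` the reverse, pooled over the whole test set; the statistic
`(b - c)^2 / (b + c)` is referred to chi-squared with 1 degree of freedom,
upper tail, without continuity correction (an exact binomial fallback is
available for small `b + c`). Pooling across images — rather than
aggregating per-image tests — is our reading of a pixel-wise test over the
entire test set; it is also the more powerful variant and is flagged here
as a choice. Families of pairwise tests are Bonferroni-corrected over the
number of pairs at family alpha 0.1; with six pairs the per-test cutoff is
0.1/6 ≈ 0.017, consistent with a 0.02 significance rule.

## The phantom generator

`generate_phantom()` emulates the statistics that matter for this task:

* **Speckle**: squared magnitude of a complex Gaussian field smoothed with
  a Gaussian of sigma `speckle_scale` (default 1.5 px) — a Rayleigh-like
  multiplicative envelope, normalized to the background mean (default 140).
* **Lesions**: hypoechoic ellipses (intensity times `lesion_contrast`,
  default 0.45) with seeded centre, semi-axes drawn from
  `lesion_radius_frac` (default 12-26% of the side) and orientation;
  malignant lesions perturb the boundary radius by a unit-RMS sum of
  harmonics 3-8 scaled by `boundary_irregularity` (0.25), benign ones are
  smooth; a posterior shadow of strength 0.2 darkens the band below the
  lesion. The mask is the analytic support — ground truth is exact.
* **Layout**: PNG image/mask pairs in the three-class BUSI-style folder
  dialect, with per-item seeds derived from one base seed (byte-identical
  regeneration) and sides cycled through a small set to exercise resizing.

What the phantoms do **not** model: attenuation with depth, refraction and
reverberation artifacts, anatomical context (glandular tissue, ribs),
multiple lesions per image, and annotation noise. Passing the end-to-end
tests therefore shows that the pipeline can learn hypoechoic-region
segmentation under speckle from exact labels — not that clinical BUSI
performance is reproduced: that would require the clinical dataset,
channel widths that were never reported, and GPU-scale training, all
deliberately out of scope here.

## Desk-scale study sizes

The built-in experiments (tests and `scripts/acceptance.R`) use 200
phantoms (34/112/54 normal/benign/malignant, matching the 17/56/27 class
proportions of the clinical dataset), 64x64 inputs, `base_filters = 8`,
batch size 32 and 30 epochs — sizes chosen so a single CPU completes the
whole study in minutes while still demonstrating learning well above an
untrained baseline (validation soft Dice > 0.8 versus ~0.15 untrained).

One protocol difference from the clinical pipeline is deliberate: the
phantom experiments skip CLAHE. Clinical ultrasound benefits from local
contrast equalization because illumination and gain vary across the image;
the phantoms are generated contrast-normalized (a single background mean,
a fixed lesion contrast), so there is no uneven illumination to correct
and equalization only amplifies the speckle texture. Enhancement remains
the default first stage of `run_pipeline()` for on-disk datasets and is
tested on its own contracts.

```{r example, eval = FALSE}
data_dir <- tempfile("phantoms")
recs <- generate_dataset(c(34, 112, 54), data_dir, base_seed = 101,
                         sides = c(96L, 112L, 128L))
split <- split_dataset(recs, c(0.8, 0.1, 0.1), seed = 7)
dtr <- prepare_arrays(split$train, 64)
dva <- prepare_arrays(split$validation, 64)
model <- build_model(model_spec("sharp_attention", base_filters = 8,
                                input_side = 64), seed = 11)
fit <- train_model(model, dtr, dva, training_config(epochs = 30, seed = 5),
                   augmentation_config(), verbose = TRUE)
dte <- prepare_arrays(split$test, 64)
evaluate_model(fit$model, dte, threshold = 0.4)
```

## Numerical choices and degenerate inputs

* Probability clamping at 1e-7 keeps the cross-entropy finite; the Dice
  epsilon 1e-5 guards empty masks.
* `binarize()` uses the `>= threshold` convention and is idempotent.
* Nearest-neighbour mask resizing samples at pixel centres
  (`floor((i + 0.5) * scale)`), so masks stay strictly binary for any
  output side.
* The RNG contract: one seed per concern (dataset, split, initialization,
  training) — `run_pipeline()` fans a single global seed out to per-module
  seeds so stages stay independently reproducible; helpers restore the
  caller's RNG state.
* He-normal initialization scaled by each layer's fan-in; attention-gate
  inter-channel width is half the skip width (minimum 1).
* Ties in max-pooling resolve to the first element in column-major window
  order; this is fixed, so forward passes are bit-reproducible.

## Known limitations

The engine is CPU-only and single-threaded beyond BLAS; 300-epoch,
128x128, width-64 training is possible but slow, and no GPU path is
provided. Only binary (single-lesion-class) segmentation is supported.
The attention-gate bias terms are fixed at zero by design. UNet++/UNet3+
baselines and GAN-based augmentation are out of scope.
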
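---
title: "A multi-output U-Net for joint lung segmentation and classification, with mask-cropped Grad-CAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-output U-Net for joint lung segmentation and classification, with mask-cropped Grad-CAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(munet)
```

## The model

`munet` implements a multi-output (multi-task) U-Net for chest radiographs:
one shared convolutional encoder feeds both a per-pixel lung segmentation
decoder and an auxiliary disease-classification branch. The point of the
joint architecture is the explanation workflow built on top of it: a
Grad-CAM heatmap computed from the deepest shared features is *cropped by
the predicted lung mask* before being overlaid on the radiograph, so the
explanation can only highlight tissue inside the lungs.

The architecture, parameterized by encoder depth $E$ and base filter count
$F$ (an `(E, F)` pair is written `3E8F` etc.):

* **Encoder** — $E$ blocks of (3×3 convolution → batch normalization →
  ReLU) ×2 followed by 2×2 max pooling with stride 2. Block $l$ has
  $2^{l-1}F$ channels: each downsampling doubles the channel count.
* **Bottleneck** — one more conv block at $2^{E}F$ channels. Its output is
  the "latent" feature tensor.
* **Classification branch** — taps the bottleneck: 2×2 max pool, flatten,
  then three dense layers (defaults 128 and 64 units with ReLU, then a
  $C$-way softmax).
* **Decoder** — $E$ blocks of (2×2 transposed convolution with stride 2 →
  concatenation with the mirror encoder feature map → (3×3 convolution →
  batch normalization → decoder activation) ×2), closed by a 1×1
  convolution to 2 channels and a per-pixel softmax.

Everything — convolutions, transposed convolutions, batch normalization,
pooling, dense layers, softmax, the full backward pass, and Adam — is
implemented inside the package (C++ kernels via Rcpp/RcppArmadillo under an
R training loop); there is no external deep-learning runtime. Analytic
gradients are verified against central finite differences in the test
suite.

Both outputs are trained jointly with

$$\mathcal{L} = w_\text{seg}\,\mathrm{SCCE}_\text{pixel}(\text{mask}) +
  w_\text{cls}\,\mathrm{SCCE}(\text{label}),$$

where SCCE is sparse categorical cross-entropy, the mean of
$-\log \hat p_{\text{true class}}$ with probabilities clipped to
$[10^{-7}, 1]$ before the logarithm. The weights default to $(1, 1)$: the
task weighting is genuinely open (nothing in the underlying training
recipe fixes it), so we chose the neutral setting and made it a
`training_protocol()` field.

### Design choices in the architecture

Several details of the recipe we follow are stated ambiguously or not at
all in the field's descriptions of this architecture family; the package
fixes them as follows.

* **Padding.** Convolutions are SAME-padded, so the segmentation output has
  exactly the input's spatial shape and no skip-connection cropping is
  needed. (Classic U-Net used unpadded convolutions plus cropping; with
  full-resolution masks as the target, SAME padding is the modern
  convention and the only self-consistent reading.)
* **Classification tap point.** The branch taps the bottleneck *after* its
  conv block — the deepest, most class-discriminative shared features.
* **Dense head widths** default to (128, 64, $C$): small enough for
  CPU-scale training, expressive enough for the phantom tasks.
* **Upsampling** is a learned 2×2 stride-2 transposed convolution, not
  fixed interpolation.
* **Activations.** The encoder always uses ReLU; the decoder activation is
  configurable among ReLU, leaky ReLU ($\max(\alpha z, z)$, default
  $\alpha = 0.1$, which is unstated in most recipes and left configurable)
  and ELU ($z$ for $z \ge 0$, $\alpha(e^z - 1)$ otherwise, $\alpha = 1$).
  We use the standard piecewise ELU; the occasionally printed form
  $\max(z, \alpha(e^z-1))$ coincides with it only for $\alpha \le 1$.
* **Batch normalization** precedes each activation; running statistics use
  momentum 0.9 and $\varepsilon = 10^{-5}$, and inference always uses the
  running statistics. A conv bias before batch norm has zero gradient (the
  normalization subtracts it); it is retained for structural simplicity.
* **Initialization** is He-normal, seeded, so builds are bit-reproducible.

## Metrics

All segmentation metrics derive from one confusion-count core
(`confusion_counts()`): Dice $= 2TP/(2TP+FP+FN)$, IoU (Jaccard)
$= TP/(TP+FP+FN)$, pixel accuracy $= (TP+TN)/\text{total}$, and dice loss
$= 1 - \text{Dice}$. Dice and IoU satisfy $\mathrm{DSC} = 2J/(1+J)$
exactly, which the tests exploit as an internal consistency oracle. When
*both* masks are empty the union is empty and Dice/IoU are defined as 1
("perfect agreement on emptiness") with an `empty_union` attribute so
reports can flag it — scoring agreement on "no lung" as failure would be
misleading, but it should stay auditable.

The cross-entropy is implemented as the standard negative log-likelihood of
the true integer class. (One widely circulated printing of the formula
drops the leading minus sign and mixes in the two-term binary form; every
training framework's "sparse categorical cross-entropy" is the NLL, and
that is what both the loss and the evaluation report use.)

Images enter the network rescaled to $[0, 1]$ by division by the image
maximum (`rescale_image()`); a constant-zero image falls back to the format
maximum 255 to avoid division by zero.

## The phantom generator

Real chest X-ray corpora with expert lung masks are large external
downloads, so the package ships a deterministic phantom generator that
makes every stage testable offline. `generate_phantom(seed, label, size)`
draws:

* two rotated ellipses ("lung fields", jittered centers near 28% and 72%
  of the width, semi-axes 12–16% × 24–30% of the frame, rotation
  $|\theta| \le 0.15$ rad) on a brighter torso background (~160 on the
  0–255 scale with a gentle vertical gradient and $\sigma = 6$ Gaussian
  noise). The geometry guarantees, by construction, that the ellipses are
  disjoint, fully in frame, and cover 10–50% of the image; the stored mask
  is exactly their rasterized union (`rasterize_lungs()` re-derives it from
  the stored parameters).
* class-conditional lung texture: *normal* lungs are dark (~60);
  *diffuse haze* adds a smooth low-pass random field (amplitude 45);
  *dense haze* adds a stronger field (amplitude 85); the *focal* class adds
  1–3 bright Gaussian blobs, the first of which is anchored well inside a
  lung and sized so a connected bright region covers at least 2% of lung
  pixels. Mean lung intensity is therefore ordered
  normal < diffuse < dense, and a trivial threshold on mean-in-mask
  intensity separates normal from dense phantoms with ≥ 95% accuracy —
  which is what makes the learning tests achievable by construction.
* intensities are generated as floats and quantized to 8-bit at creation
  time, so the $[0,1]$ rescaling in the pipeline is exercised realistically.

Per-sample seeds are a deterministic Lehmer-style mix of the master seed
and the sample index, so a dataset regenerates bit-identically and any
single sample can be regenerated in isolation. Class counts follow the
largest-remainder apportionment of $n \times$ proportions.

With four classes the labels follow the chest X-ray convention
(Normal, COVID-19 → diffuse haze, Viral Pneumonia → focal, Lung Opacity →
dense haze); with three classes the set is normal / diffuse / dense.

What the phantoms deliberately do **not** emulate: anatomy (ribs,
mediastinum, clavicles), acquisition physics, inter-patient variability,
or any overlap between class textures. Passing the phantom study shows the
implementation learns and localizes correctly on a controlled task; it
says nothing about clinical performance on real radiographs.

## Training protocol

`training_protocol()` defaults to the full-scale recipe: 20% of the data
held out for testing, sessions of 300 randomly drawn training images, 6
sessions × 200 epochs, batch size 32, and 10% of the remaining pool for
validation (in the classification split mode, a fixed 10,000-image
training set is removed first and the 10% applies to what is left — on a
21,165-image corpus this yields the 4,233 / 16,932 / 693 test / remainder
/ validation counts the tests pin down). Draws are seeded; sessions sample
without replacement within a session and independently across sessions
(whether sessions may re-use images is unspecified in the original recipe;
independent draws are the simplest reading). After every epoch the
validation *total* loss is evaluated in inference mode and the best
weights are checkpointed; `train_munet()` returns that checkpoint, which
by construction reproduces the history's minimum validation loss.

The optimizer is Adam (learning rate $10^{-3}$, $\beta = (0.9, 0.999)$) —
a detail the original recipe leaves unstated; Adam at $10^{-3}$ is the
field's default for U-Nets.

### Desk scale

The experiments the package actually runs (`desk_protocol()`) are scaled
to a single CPU: 64×64 phantoms, a 3E8F model, 375 samples split
300 / 15 / 60 train / validation / test, 3 sessions × 5 epochs. 64 divides
by $2^3$ (three encoder blocks); 256×256 with up to five blocks is
available for demonstrations. On this task the model reaches test Dice
≈ 0.99 and classification accuracy 1.0 in a few minutes; the acceptance
thresholds (Dice ≥ 0.90, accuracy ≥ 0.80 on three independent seeds) are
the package's CPU-scale stand-in for the published full-scale scores,
which require the external radiograph corpus and are out of scope here.
The `hyperparameter_sweep()` and `compare_activations()` harnesses run the
same protocol across $(E, F)$ grids and decoder activations with shared
splits so rows are comparable.

## Explainability

`gradcam()` implements gradient-weighted class activation mapping against
the bottleneck features: the weight of feature map $k$ is the spatial mean
of $\partial s_c / \partial A_k$ where $s_c$ is the **pre-softmax** class
score (post-softmax gradients vanish at confident predictions), the map is
$\mathrm{ReLU}(\sum_k \alpha_k A_k)$, normalized by its maximum (an
all-non-positive map stays all-zero rather than dividing by zero), and
bilinearly upsampled to input resolution. The classification head itself
contains no convolutions, so the deepest shared conv features are the
faithful "last convolutional layer" for CAM purposes. (Descriptions of
this workflow sometimes blur classic CAM — softmax-weight averaging — with
Grad-CAM; the gradient-weighted form is implemented, matching the name.)

`masked_cam_overlay()` multiplies the heatmap elementwise by the binary
lung mask and alpha-blends it (default $\alpha = 0.4$, perceptually
ordered blue→red colormap) over the grayscale image; wherever the mask is
0 the original pixel renders unchanged, and masking an already-masked
heatmap is a no-op. `binarize_mask()` takes the per-pixel argmax with ties
broken toward background. `error_map()` renders the trinary
truth-vs-prediction difference (missing = FN = black, additional = FP =
white, correct = gray) and its counts are definitionally the FN/FP of
`confusion_counts()` on the same pair — a cross-module consistency the
tests assert.

The only *statistical* claim the package tests about explanations is
localization: over 50 diseased phantoms, the mean heatmap value inside the
true lung mask exceeds the mean outside for a trained desk-scale model.
Whether warm regions mark "where the disease is" on real radiographs is a
clinical claim outside what phantoms can establish.

## Numerical conventions

* Probability clipping $\varepsilon = 10^{-7}$ before all logarithms.
* Softmax is computed with per-pixel/per-sample max subtraction.
* Max-pooling ties resolve to the first element in scan order, fixing the
  backward scatter deterministically.
* `input_size` must be divisible by $2^E$ with a bottleneck of at least
  2×2 (the classification head pools once more); violations are rejected
  at configuration time, before any allocation.
* All randomness (geometry, noise, init, splits, session draws, shuffles)
  flows from explicit seeds; training twice with one seed is
  bit-identical.

## Interfaces

Datasets are plain directories: 8-bit grayscale PNGs, masks stored as
{0, 255} and binarized at 128 on load (tolerating mild compression
artifacts), a `manifest.csv` (`image,mask,label,seed`) and a `classes.txt`
naming classes in index order. `load_dataset_dir()` also accepts the
per-class-folder layout used by public chest X-ray archives. Checkpoints
are a directory of weights plus a `config.json` echo of the architecture,
so they are self-describing. A thin command-line wrapper
(`inst/cli/munet.R`, subcommands `generate-data`, `train`, `evaluate`,
`sweep`, `compare-activations`, `explain`) drives the same exported
functions and writes run directories containing `history.csv`,
`checkpoint/`, `report.json`, `config.json` and a plain-text log.

## Known limitations

* CPU-only and desk-scale; the full 1,200-epoch protocol is expressible
  through `training_protocol()` but not exercised by the tests.
* Segmentation is the two-class lung/not-lung problem; no boundary-distance
  metrics (Hausdorff, ASSD), no Grad-CAM++/occlusion baselines, no
  pretrained encoders, and no DICOM or 3-D volumes.
* Phantom results bound implementation correctness, not clinical accuracy.
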
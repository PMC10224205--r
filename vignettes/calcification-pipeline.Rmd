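---
title: "Classifying mammographic calcifications with multiscale decision fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mammographic calcifications with multiscale decision fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcamdf)
```

## The clinical problem

When screening mammography shows indeterminate microcalcifications, the
work-up proceeds to diagnostic spot magnification views, and clusters judged
suspicious (BI-RADS category 4) are sent to biopsy. Because the positive
predictive value of that recommendation is low, a large share of biopsies
return benign. `calcamdf` implements, at desk scale, an image-analysis
pipeline intended to help discriminate benign from malignant calcifications
on such magnification views: contrast-boosting preprocessing, a small
single-stage pyramid detector whose scale heads are combined by an adaptive
multiscale decision fusion (AMDF) layer, and a mixed-input multilayer
perceptron (MLP) that merges the detectors' confidence scores with
radiologist-style descriptors and clinical covariates.

Clinical mammography datasets of this kind are not redistributable, so the
package ships a synthetic phantom generator that emulates the cohort
structure and the imaging phenotype well enough to exercise — and test —
every stage end to end.

## Pipeline overview

For each case (1–2 views):

1. **Preprocessing (`mask_overlap`)** — 3×3 median filter, gamma
   correction, white top-hat segmentation of small bright foci, and
   additive superimposition of the binary mask on the original image. The
   preprocessed image feeds the *baseline* detector; the AMDF detector
   receives the original image.
2. **Detection (`build_detector`, `train_detector`)** — a reduced
   cross-stage-partial backbone with Mish activations produces feature maps
   at strides 8/16/32; 1×1 heads emit per-scale pre-detection tensors
   $d_3, d_4, d_5$ of shape $N_l \times N_l \times [3\,(1 + 4 + 2)]$
   (3 anchors × objectness $p_c$, box offsets $b_x, b_y, b_h, b_w$, class
   scores $c_1, c_2$).
3. **Fusion (`amdf_fuse`)** — the coarser tensors are aligned to the
   level-3 grid by nearest-neighbour upsampling and combined as
   $y_s = \alpha d_3 + \beta d_4 + \gamma d_5$ with softmax reliabilities
   $\alpha = e^{\lambda_\alpha} / (e^{\lambda_\alpha} + e^{\lambda_\beta} +
   e^{\lambda_\gamma})$ (cyclically for $\beta, \gamma$), so
   $\alpha + \beta + \gamma = 1$ and each lies in $[0, 1]$. The three
   $\lambda$ are ordinary trainable parameters: because
   $\partial y_s / \partial d_l$ equals the corresponding reliability, the
   chain rule routes a scale's share of the loss gradient through its
   reliability, and the reliabilities themselves receive gradients through
   the softmax Jacobian.
4. **Scoring (`image_score`)** — a per-image malignancy confidence is the
   maximum over cells and anchors of
   $\sigma(p_c)\,\sigma(c_\text{malignant})$ (a mean-of-top-k reduction is
   available).
5. **Ensemble (`train_ensemble`)** — a two-hidden-layer tanh MLP (Adam,
   initial learning rate 0.005, L2 penalty $10^{-4}$, 20% internal
   validation split with early stopping) maps 16 features to a malignancy
   probability: both detector confidences, multi-hot morphology (6 flags;
   a lesion can show more than one pattern), one-hot distribution
   (5 flags), and z-scored age, ROI area and ROI aspect ratio. The z-score
   moments are always fitted on the training split only, and a guard
   (`check_standardizer_leakage`) makes contamination a hard error.
6. **Evaluation (`monte_carlo_cv`)** — case-level splits (a case's views
   never straddle train/test), full retraining per holdout, ROC/AUC by the
   trapezoidal rule (equal to the tie-corrected concordance probability),
   optimal cutoff by Youden's J (the distance-to-(0,1) index is available),
   and sensitivity/specificity/accuracy/PPV with Wilson intervals. Two-view
   cases are scored by averaging the per-view probabilities.

## Loss and training

All classification terms are binary cross-entropy
$l(y, \hat y) = -\sum_i [y_i \log \hat y_i + (1 - y_i)\log(1 - \hat y_i)]$
with predictions clipped to $[10^{-7}, 1 - 10^{-7}]$. Training targets are
assigned per scale: each ground-truth box activates the best shape-IoU
anchor at its responsible grid cell. The AMDF variant applies objectness,
class and (by default) box losses to the fused tensor on the level-3 grid;
the baseline trains its three heads independently with per-scale targets.
Box offsets use sigmoid-coded centre offsets and log size ratios with a
squared-error penalty; cross-entropy is reserved for the probabilistic
(objectness/class) channels, where it is defined.

Numerical choices worth knowing:

- $y_s$ is fused **in logit space** and the sigmoid applied afterwards.
  This keeps the reliability-gradient contract exact; fusing post-sigmoid
  probabilities would make $\partial y_s / \partial d_l$ depend on the
  operating point.
- The softmax is stabilized by max-subtraction, so extreme $\lambda$ do not
  overflow.
- Objectness positives and negatives are separately mean-normalized
  (negatives down-weighted ×0.5): with three anchors on a 16×16 grid a
  single lesion is 1 positive among 768 slots, and an unbalanced sum leaves
  the class signal unlearnable at this scale. The 1/1/1 weighting *between*
  the objectness/box/class terms is the default and configurable.
- Head objectness biases start at −3 (a low "no lesion" prior), a standard
  initialization that avoids the early flood of false positives.
- Optimization is Adam (β₁ = 0.9, β₂ = 0.999) on minibatches; the λ
  parameters sit in the same update loop as the weights. Training aborts
  with diagnostics on a non-finite loss.
- All randomness (phantom, shuffling, jitter, splits, bootstrap) flows from
  explicitly passed seeds through one internal helper; nothing depends on
  the global RNG state left behind by other code.

The backbone is deliberately small (default width 8, one cross-stage
block). A full-resolution stride-1 stem convolution precedes the first
downsampling because the discriminative texture — individual
calcification particles — lives at the 1–3 px scale of the phantom and
would otherwise be lost at the first stride-2 layer.

## The phantom generator

`generate_roster()` emulates a biopsy-referred diagnostic cohort: 432
benign / 204 malignant cases (67.92% / 32.08%), ages drawn from a normal
(54.4, 8.42) truncated to [29, 81] by rejection, BI-RADS 4A/4B/4C mixtures
per class whose blend reproduces the cohort-level 68.4/28.0/3.6%
composition, malignant histology probabilities 61/204 IDC, 3/204 ILC,
140/204 DCIS (a deterministic largest-remainder "quota" mode reproduces
the exact counts), exactly three single-view cases, and two views
(CC + MLO/ML) otherwise — 1269 images in the default configuration.
Descriptor linkage is class-conditional and configurable: benign cases skew
punctate/round + grouped, malignant cases pleomorphic/amorphous/fine-linear
+ grouped/segmental. The overlap between the class-conditional tables is
what makes the task non-trivial; the linkage itself is what lets the
ensemble demonstrate its use of descriptor features.

`render_view()` draws a smooth low-frequency tissue texture plus pixel
noise and stamps particles whose cluster footprint follows the distribution
descriptor (disc, wedge, band, or large area) and whose shapes follow the
morphology set (Gaussian spots, hard discs, faint blurred blobs, irregular
polygons, speckled coarse discs, or short branching segments). The
ground-truth box is the tight particle box padded by 3 px, in 0-based,
origin-top-left, half-open pixel coordinates. Intensities are kept in
[0, 1] and written as 16-bit TIFF.

What the phantom does *not* emulate: breast anatomy, X-ray physics,
scanner-specific noise, the full variability of real parenchymal texture,
or inter-reader descriptor disagreement. Passing the end-to-end tests
therefore demonstrates that the pipeline's machinery works and that its
components interact correctly under a controlled, learnable signal — not
that the clinical operating points of the reference study would be
reproduced on real mammograms.

## Problem sizes and defaults

The default experiment (`default_run_config()`) uses 200 cases / 397
images at 128 px, detector width 8, 14 training epochs, and two Monte-Carlo
holdouts with an 85/15 case-level split — sized so a complete run trains
four detectors and two ensembles on one desk CPU in a few minutes while
leaving enough test cases (30 per holdout) for a stable case-level AUC.
Larger rosters, deeper/wider backbones, more epochs and five holdouts are
plain configuration changes.

## Open design points, resolved

Choices the package had to make where the method description leaves
latitude, and why:

- **Top-hat threshold** — Otsu on the top-hat response by default, with a
  fixed threshold available; whether the reference system thresholds
  adaptively is not stated, so neither mode is asserted as "the" choice.
- **Superimposition** — additive overlay with clipping
  (`original + 0.5 × mask`), the simplest reading of superimposing a binary
  mask that strictly brightens detected foci.
- **Gamma exponent 2, disc radius 3 px** — unstated upstream; chosen once
  at phantom scale.
- **Fusing the box channels** — the pixel-wise addition of whole
  pre-detection tensors suggests fusing all 21 channels, which is the
  default; a classification/objectness-only fusion is selectable.
- **Per-image MLP training** — the ensemble trains on per-image rows and
  averages per-case at inference; whether the reference MLP saw per-image
  or per-case rows is not stated.
- **Youden's J** as the default cutoff index (the cited cutoff methodology
  offers several; the distance-to-corner index is provided), ties broken
  towards higher specificity.
- **CI procedures** — stratified bootstrap for AUC, Wilson for
  proportions, across-holdout normal approximation for pooled metrics; the
  reference reports CIs without naming methods.
- **Mosaic on single-lesion magnification views** is flag-controlled and
  off by default; boxes keep ≥ 25% of their rescaled area or are dropped.
- **Saturation jitter** is accepted in configuration but is a no-op on
  single-channel images.

## Known limitations

- The detector is a reduced design: no pretrained backbone, three fixed
  pyramid levels, anchors from k-means on phantom boxes. It is sized for
  testability, not leaderboard accuracy.
- Grayscale morphology and the median filter use edge replication;
  implementations with different border policies will differ on a 1-px rim.
- The fused head decodes boxes on the level-3 grid with level-3 anchors;
  very large lesions are represented but coarsely regressed.
- DICOM input is not supported; PNG/TIFF only.
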
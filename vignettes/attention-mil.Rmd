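---
title: "Clustering-constrained attention MIL for two-view mammography: models and methods"
author: "MammoMIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-constrained attention MIL for two-view mammography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MammoMIL)
```

## The problem

Screening mammography produces two projections per breast — craniocaudal
(CC) and mediolateral oblique (MLO) — at high resolution (a full-field
digital mammogram is typically 3518 x 2800 px at 0.085 mm/px). Clinical
archives are usually labelled only at image level ("cancer" /
"non-cancer"), without pixel-level lesion annotations, and lesions occupy a
tiny fraction of the breast. Downscaling whole images to CNN-native input
sizes destroys the lesion signal; training on full images dilutes it
through global pooling.

MammoMIL implements the weakly supervised alternative: multiple instance
learning (MIL). Each image (or a CC + MLO pair concatenated into one
*multimodal* image) is tiled into square patches; the patches that contain
enough breast tissue form a *bag* that inherits the image label. A
gated-attention pooling head learns which patches matter, a bag classifier
predicts the label from the attention-weighted patch embedding, and the
attention weights double as a coarse lesion-localisation map.

## The model

With $K$ patches encoded as feature vectors $h_1, \dots, h_K$ (reduced to
256 dimensions by a fully connected ReLU layer), the bag embedding is the
attention-weighted average

$$B = \sum_{k=1}^{K} a_k h_k,$$

with gated attention weights

$$a_k = \frac{\exp\{w^\top(\tanh(V h_k^\top) \odot \sigma(U h_k^\top))\}}
            {\sum_{j=1}^{K}\exp\{w^\top(\tanh(V h_j^\top) \odot \sigma(U h_j^\top))\}},$$

where $V, U \in \mathbb{R}^{L \times 256}$ and $w \in \mathbb{R}^{L}$ are
learnable, $\odot$ is the element-wise product, and the softmax makes the
weights a probability vector regardless of bag size. The tanh branch
captures (dis)similarity structure; the sigmoid gate relieves its
near-linearity on $[-1, 1]$. The bag classifier is one 256-neuron hidden
layer with a single sigmoid output neuron; scores above 0.5 are predicted
cancer by default.

**Clustering constraint.** Because positive bags contain few truly positive
patches, attention is additionally constrained: after each forward pass the
$k_\mathrm{eff} = \min(k, \lfloor K/2 \rfloor)$ highest-attended patches are
pseudo-labelled 1 (positive evidence) and the $k_\mathrm{eff}$
lowest-attended patches 0 (negative evidence); a shared two-class instance
classifier (one 256-neuron hidden layer) is trained on them with
categorical cross-entropy. The training loss is the fixed mixture

$$\mathcal{L} = 0.7\,\mathrm{BCE}(\hat p, y) + 0.3\,\mathrm{CCE}_\mathrm{instances},$$

which sharpens the instance-level feature space and concentrates the
attention maps. The default evidence count is $k = 8$; the clamp to
$\lfloor K/2 \rfloor$ keeps the two clusters disjoint in small bags.
Evidence selection is treated as non-differentiable; ties in attention
resolve toward the lower patch index (with disjointness of the two clusters
taking precedence if a tie group spans both ends), so runs are
deterministic.

**Feature extraction.** Extractors are pluggable behind `ExtractorSpec`
(name, feature dimension, extraction function) and frozen: the package
never trains them. The built-in `tinyExtractor()` is a fixed-weight
two-stage convolutional network — 3 x 3 convolution with 8 filters (the
first a box mean, so one channel tracks plain local intensity), ReLU,
4 x 4 max pooling, a second 3 x 3 convolution with 16 filters, ReLU, then
global mean + max pooling per channel — giving 32 features per patch from
weights drawn once from an internal fixed seed. Per-dimension feature
standardisation statistics are fitted once on the training features
(`fitFeatureNorm()`) and frozen thereafter, mirroring the frozen
normalisation statistics of a pretrained backbone. A production deployment
would substitute an ImageNet-pretrained CNN (ResNet-18/34/50,
EfficientNet-B0: 512/512/2048/1280 features) behind the same contract.

### Open design points and how they were resolved

* **Attention hidden width $L$** is not pinned by the architecture
  description; the default is $L = 256$, matching every other hidden width
  in the head, and is configurable in `initModel()`.
* **Dropout** (rate 0.25) applies after each fully connected layer of the
  attention module — the feature reduction and both attention branches —
  during training only; inference disables it.
* **Which features are pooled:** the pipeline order (reduction, attention,
  bag embedding, 256-neuron classifier) implies Eq. above pools the
  *reduced* 256-d features, which is what is implemented.
* **Evidence bookkeeping:** the clustering constraint is applied per bag
  ($2k_\mathrm{eff}$ instances per forward pass); cumulative counts over an
  epoch are a consequence, not a parameter.

## Preprocessing

* **Intensity scaling** divides raw detector values by the bit-depth full
  scale ($2^{12}-1 = 4095$ or $2^8-1 = 255$), not per-image min–max, so 0
  maps to exactly 0.0, full scale to exactly 1.0, and contrast remains
  comparable across images. Values above the declared full scale raise a
  range error naming the value.
* **Channel expansion** replicates the grayscale image to 3 identical
  channels for CNN consumption.
* **Orientation** is normalised chest-wall-left: the chest-wall edge is the
  vertical edge whose outermost 5% column band is brighter; the image is
  mirrored iff that edge is not on the target side. The operation is a
  fixed point of itself; equally bright edges yield a warning and no flip.
* **Edge-artifact removal** deletes the 20 columns (configurable) adjacent
  to the chest-wall edge. This removes the high-intensity collimator band
  that can act as a label-correlated shortcut. A described alternative —
  shifting the image toward the chest wall — discards the same band; the
  crop formulation is implemented because it leaves no wrapped or
  duplicated pixels.
* **Half-resizing** uses 2 x 2 area averaging with floored output
  dimensions (3518 x 2800 becomes 1759 x 1400): it preserves constants,
  keeps intensities in [0, 1], needs no interpolation seed, and doubles the
  recorded pixel spacing.
* **Multimodal concatenation** stacks the CC view on top of the MLO view
  (row counts add: 3518 + 3518 = 7036, columns unchanged), forced by the
  printed geometry of the multimodal input. Width mismatches — possible
  after cropping only one view — are zero-padded on the non-chest-wall
  side.
* **Readers.** PNG (8/16-bit grayscale) and in-memory matrices are
  supported, with labels in a CSV (`patient_id, laterality, view, label,
  path`). DICOM ingestion is out of scope for this package; DICOM pixel
  arrays exported to PNG (or passed as matrices) take the same path.

Coordinates are row-major, 0-based, half-open throughout: patch $k$ covers
rows $[r_0, r_0 + P)$ and columns $[c_0, c_0 + P)$.

## Bagging

`tileGrid()` starts at the top-left corner with per-axis stride
$\mathrm{round}((1 - \mathrm{overlap}) \cdot P)$ (half-up, minimum 1) and
keeps every offset at which the patch still fits entirely; trailing
remainders are dropped so all patches are identically sized. A patch enters
the bag iff at least 75% of its pixels are strictly positive (`>= 0.75`,
inclusive; "non-zero" is exact because scaling maps raw 0 to 0.0). The rule
is applied once at bag construction, before any augmentation. An image
whose patches all fail the rule is rejected with a diagnostic carrying the
image id. The studied patch sizes and overlaps are 128/224/448 px and
0, 0.25, 0.5; at 0.085 mm/px a 224-px patch spans 19.04 mm of tissue.

Training-time augmentation is per patch and sequential: one uniformly
chosen right-angle rotation, horizontal flip (p = 0.5), vertical flip
(p = 0.5), and a random resized crop with area scale uniform in [0.8, 1]
resized back bilinearly. Validation and test patches are never augmented,
and calling the augmenter outside training mode is a contract error.
Because the built-in extractor is frozen, the default desk-scale training
path precomputes features once per bag and trains the head on them;
passing an `augmentationPolicy()` to `extractFeatures()` re-renders
features per draw instead.

## Training

`trainConfig()` defaults encode the training regime: SGD with momentum
0.9, learning rate 0.001 multiplied by 0.9 every 10 epochs ("decayed by a
constant factor"), weight decay 0.001 (weights only, not biases), batch
size 1 with gradient accumulation over 8 samples (the mean of the
accumulated gradients feeds one optimiser step; a final partial group
still updates), at least 20 and at most 100 epochs with 20-epoch
early-stopping patience, loss mixture 0.7/0.3, $k = 8$, dropout 0.25, seed
42. Training halts after epoch $e$ iff
$e \ge \max(\mathrm{minEpochs}, \mathrm{bestEpoch} + \mathrm{patience})$
or $e = \mathrm{maxEpochs}$; the returned checkpoint is the best
validation epoch. The validation selection metric is validation loss
(configurable to AUC): of the candidates, loss is the one that needs no
decision threshold and stays defined on single-class validation sets.

Class imbalance is handled by weighted random oversampling: each training
case is drawn with probability inversely proportional to its class
frequency, giving each class expected draw mass 0.5.

Cross-validation is patient-wise and class-stratified: patients are
shuffled once per class with the seed, dealt round-robin into five
near-equal test folds, and the remainder is split 7:1 into training and
validation, giving approximately 70/10/20. All images of a patient follow
the patient. Stratification keeps per-fold class counts near-balanced,
which plain patient shuffling cannot guarantee.

`transferInit()` copies all learnable parameters (and the frozen feature
normalisation) from an architecture-compatible source checkpoint, erroring
atomically on any shape mismatch, so a model trained on one domain can
warm-start another.

All randomness — fold shuffling, oversampling draws, dropout masks,
initialisation — flows from the configured seed; two runs with the same
configuration produce byte-identical logs and reports.

## Evaluation

Confusion counts use a strictly-greater decision rule (a score exactly at
the threshold is predicted non-cancer). Accuracy, precision, recall and F1
follow the standard confusion-matrix formulas; a zero-denominator metric
is reported as 0 with a warning flag rather than raising, so fold
aggregation stays total. AUC is the Mann–Whitney pairwise statistic with
half-credit ties (computed via average ranks, equivalent to exhaustive
pair counting). The Youden-optimal threshold maximises
$J = \mathrm{sensitivity} + \mathrm{specificity} - 1$ over midpoints
between consecutive distinct scores plus $\pm\infty$ sentinels; ties —
assessed at a small numerical tolerance, since equal $J$ values can be
assembled from different sensitivity/specificity pairs — resolve to the
smallest threshold. Cross-validated results are reported as arithmetic
mean ± sample (n−1) standard deviation per metric, AUC to 3 decimals and
percentage metrics to 1.

## Attention heatmaps

`renderHeatmap()` creates an empty canvas of the source-image shape, adds
each patch's attention weight over its pixel square, divides each pixel by
the number of patches covering it, and min–max scales over *covered*
pixels; uncovered background is pinned to 0, and a constant covered region
maps to 1 so a single-patch map stays visible. Raw attention weights are
accumulated (no per-image re-normalisation before accumulation). Higher
overlap increases per-pixel coverage and thus map resolution.
`localizationScore()` compares mean heatmap values inside versus outside a
known lesion mask; `edgeAttentionMass()` measures the fraction of heat in
the chest-wall band, whose uniform-attention expectation is the band's
share of the covered area.

## The phantom generator

`phantomSpec()` / `generateDataset()` produce paired CC/MLO phantoms with
known ground truth so every stage is testable without clinical data:

* breast = half-ellipse flush with the left (chest-wall) edge, semi-axes
  drawn per view (0.35–0.45 of rows, 0.60–0.80 of columns), base intensity
  0.45 with Gaussian texture noise (sd 0.08) clipped to stay positive;
  background exactly 0, matching the foreground rule's assumption;
* lesions (cancer cases only): 1–3 radially decaying bright discs per
  view, radius 6–12 px, peak intensity lift 0.30–0.50, placed uniformly
  inside the breast with the whole disc inside breast and image; CC and
  MLO share the label but draw geometry, noise and lesion positions
  independently, mirroring real projections;
* optional edge artifact: a near-saturated (0.98) full-height band of 20
  columns at the chest-wall edge, drawn with class-conditional
  probabilities, emulating a collimator-misalignment line whose presence
  can be correlated with the label;
* labels: exactly `round(cancerFraction * nPatients)` cancer patients in
  shuffled order; the whole dataset is a pure function of the spec seed.

`biasedPair()` renders the same patient stream twice — with the
label-correlated artifact and with the band cropped away — for the paired
bias experiment. `generateDataset(spec, lesions = FALSE)` yields a null
dataset with no pixel-level class signal, used to check that the pipeline
cannot manufacture separation from nothing.

**Study conditions.** Desk-scale experiments use 256 x 192 px images with
patch 64 px and overlap 0.5 (preserving the tiling, foreground-rule and
concatenation geometry of the full-scale setting at tractable cost):
lesion recovery uses 200 patients (dataset seed 42) with training capped
at 30 epochs; the bias experiment uses 120 patients with artifact
probabilities 0.9 given cancer and 0.1 given non-cancer; the determinism
check uses 30 patients, 3 folds and a shortened epoch schedule. Full-scale
3518 x 2800 generation is supported but not the default.

**What the phantoms do not emulate** — and hence what passing tests do not
show about clinical data: radiographic texture (quantum noise, tissue
structure), spiculated or low-contrast lesion morphology, pectoral muscle
in MLO views, scanner/vendor intensity profiles, and population label
noise. The phantom lesion is deliberately a contrast blob: it validates
the mechanics of weak supervision and localisation, not clinical
performance. One consequence, observable in the bias experiment run by
`scripts/acceptance.R`: because phantom lesions are perfectly predictive
while the artifact is only 0.9/0.1-correlated, a trained model learns both
cues; edge attention is systematically inflated by the artifact and falls
back to near its area share after the band is cropped, but the artifact
does not fully displace the lesion signal the way a subtle-lesion clinical
dataset can experience.

## Numerical choices

* Stride and crop sizes round half away from zero; all dimension halving
  floors.
* Softmax and the instance log-softmax subtract the row maximum before
  exponentiation; bag probabilities are clamped to
  $[10^{-12}, 1 - 10^{-12}]$ inside the cross-entropy only.
* Attention-weight normalisation is validated to $\sum_k a_k = 1$ within
  $10^{-6}$; a non-finite attention score aborts with the patch index.
* Gradients of the full head are analytic and are verified against central
  finite differences in the test suite.
* Feature standard deviations below $10^{-8}$ are replaced by 1 to keep
  standardisation defined for dead feature dimensions.
* Divergence (non-finite loss) aborts training with epoch/step context.

## Limitations

* The built-in extractor is a fixed random-weight CNN: sufficient for
  phantom contrast, far below a pretrained backbone on real tissue.
* Only binary (cancer / non-cancer) classification; no multi-class
  variant, no per-class attention branches.
* No DICOM ingestion, overlay planes, or window/level handling; no
  GPU-scale training. Training cost is linear in bags x epochs and is
  intended for desk-scale studies and method validation.
* Heatmaps are rendered from raw attention; no confidence calibration or
  DeLong-style AUC intervals are provided.
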
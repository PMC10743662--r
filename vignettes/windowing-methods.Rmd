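---
title: "Intensity windowing as a learnable model component"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity windowing as a learnable model component}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radwindow)
```

## The problem

High-bit-depth radiographs encode more gray levels (a 12-bit chest
X-ray has 4096) than either a display or a conventionally preprocessed
classifier ever sees. Radiologists compensate by *windowing*: clamping
the image to an intensity interval given by a level `WL` (center) and
width `WW` (extent) and spreading that interval over the whole output
gray scale, which multiplies the local contrast by `4096/WW`. Findings
whose contrast is a few dozen gray values inside a narrow band are
invisible both after 8-bit quantization (which merges every 16 adjacent
12-bit values) and under a mis-set window (which saturates the band to
black or white). This package treats the window transform as a model
component whose parameters are learned from data, plus the scaffolding
needed to measure whether that helps.

## The window operator and its affine form

`window(px) = min(max(px, L), U)` with `L = WL - WW/2`,
`U = WL + WW/2`. Mapping `[L, U]` affinely onto the display range
`[0, out_max]` (255 by default) gives the clamped affine map

```
clamp(W px + b, 0, out_max),  W = out_max/WW,  b = -(out_max/WW)(WL - WW/2)
```

which is exactly a 1×1 convolution channel with output clamping, so its
two parameters are trainable. The identity

```
clamp(W px + b, 0, out_max) = (out_max/WW) * (window(px) - L)
```

holds for every pixel and every positive width (a property test in the
suite checks it over the full fixed-window grid at 1e-5 absolute
tolerance on the 0–255 scale), and window settings are recovered from
trained parameters by `WW = out_max/W`, `WL = -b/W + WW/2`. One
notational subtlety: the clamp bound is always the *output* scale
(0–255), never the window's upper limit `U`, even though both are
bounds — conflating them breaks the identity whenever `U != 255`.
Negative learned weights are legal (training is unconstrained); they
describe inverted windows and are reported with negative width and an
`inverted` flag rather than rejected, so post-training summaries stay
total. A weight of exactly zero carries no window and is flagged
degenerate. All window math is floating point even on integer pixels,
both for the gradient path and so the equivalence identity is exact.

## Architectures

Four configurations share one interface (`model_config()`):

* **windownet** — K clamped affine channels (the window layer),
  initialized from a window list; a 1×1 K→3 mixer; a per-image,
  per-channel affine rescale onto `[0, 255]`; ImageNet normalization;
  a backbone classifier with 14 logits.
* **no_windowing** — identical, but the first layer is a conventional
  (unclamped) 1×1 convolution, Kaiming-initialized. This isolates the
  clamp: without it the first two layers compose to an affine map of
  the input, which the rescale then cancels almost entirely.
* **augmentations** — the no_windowing architecture trained with random
  brightness/contrast perturbations (probability 1/2 per image,
  contrast factor in [0.8, 1.25] about the image mean, brightness shift
  up to ±20% of the representable range, clipped). The ranges are
  conventional defaults; they are exposed nowhere else because the
  variant exists only as a comparison arm.
* **baseline** — fixed full-range preprocessing (optionally after
  bit-depth reduction) straight into the backbone.

Design choices that were genuinely open:

* **Placement of scale/normalize.** The rescale to `[0, 255]` and the
  ImageNet normalization sit *after* the mixer, immediately before the
  backbone: the mixer's output range is unbounded during training and
  normalization is a backbone input contract, so normalizing any
  earlier would leave the backbone unprotected.
* **What "scale to (0, 255)" means.** Implemented as an affine min–max
  rescale per image and channel, with a constant-channel guard (output
  127.5, zero gradient). Per-image statistics keep inference
  deterministic and independent of batch composition; a per-batch
  variant would make the checkpoint-selection metric depend on how the
  validation set happens to be batched. The backward pass
  differentiates the rescale exactly, routing gradient through the
  min/max via the pixels attaining them — treating them as constants is
  measurably wrong for the unclamped ablation, where the true gradient
  of everything upstream of the rescale is zero by affine invariance.
* **Mixer initialization.** Windows are sorted by level and split into
  three contiguous groups; each mixer output channel starts as the
  average of one group, so the backbone's three channels begin as low-,
  mid- and high-band renderings (the analogue of a radiologist's
  lung/soft-tissue/bone windows). Global averaging — every output
  channel the mean of all K windows — was tried first and collapses the
  initialization advantage: all three channels carry the same staircase
  tone curve and per-band contrast is attenuated by 1/K. For K < 3 the
  init falls back to plain averaging. The ablation modes
  Kaiming-initialize the mixer.
* **Backbone.** Pluggable. The built-in `"tiny"` backbone needs no
  pretrained weights: each normalized channel is encoded by five
  radial-basis units centered along the output gray scale (bandwidth 40
  gray values), each bin map is average-pooled to an 8×8 grid, and a
  one-hidden-layer MLP (width 32) produces the logits. The soft
  binning matters: it lets the classifier express "this region contains
  mid-gray tones", which pooled means cannot, while remaining
  differentiable so gradient reaches the window parameters. A deep
  pretrained convolutional backbone fills the same slot at full scale;
  the backbone interface (`init`/`forward`/`backward`) accepts such an
  implementation unchanged.

## Training protocol

Binary cross-entropy over the 14 labels (uncertain `-1` labels are
mapped to 0 by default; `"ones"` and `"ignore"` policies are available,
and uncertain/missing cells never enter AUC evaluation), AdamW
(weight decay 0.01) at learning rate 1e-4, batch size 32. The learning
rate is divided by 10 when the validation loss has not improved for 3
consecutive epochs (strict decrease beyond 1e-6; the counter restarts
after a reduction, so a long plateau cuts the rate every 3 epochs);
training stops after 5 consecutive epochs without improvement;
`max_epochs` (default 100) is only a safety bound. The returned model
is the checkpoint with the highest mean validation AUC, where the mean
skips classes whose validation labels are single-valued (the log
records how many classes contributed). Runs are deterministic given the
seed and data order.

## Evaluation

AUC is computed in the Mann–Whitney form from midranks (ties count
1/2), so it is exact and invariant under monotone score transforms;
single-class inputs are undefined rather than silently 0.5. Confidence
intervals are nonparametric bootstrap percentile intervals (default
10,000 resamples, 95%), resampling *images* with replacement — all
classes share each resample's indices. A class with a single-valued
outcome in some resample is skipped in that resample rather than
redrawn; redrawing would condition the bootstrap distribution on class
balance and bias narrow-prevalence intervals. BCa corrections are not
applied. A simulation in the test suite checks that the interval covers
the large-sample AUC of a known score generator in at least 93% of 200
replications at 2000 images.

## Fixed-window grid search

The candidate grid is level 100 plus levels 250–3500 in steps of 250,
crossed with widths 500–3000 (75 windows, level-major). Ranking every
window per class by retraining a classifier is a GPU-scale job; at desk
scale `grid_search_probe()` ranks them with a ridge-regularized linear
probe on block-wise gray-tone histograms of the windowed image (4×4
spatial grid × 5 intensity bins). The identical feature map applied to
both arms of any comparison isolates the effect of the intensity
transform itself. `select_init_windows()` takes the class-wise top 3 by
validation AUC, breaks ties deterministically (smaller width, then
smaller level), forms the union, and appends the full-range window
(2048, 4096) exactly once. The package's default initialization list
(`default_window_init()`) is the published 14-window set for real
chest-radiograph data; it is reproduced verbatim rather than re-derived
because the printed list cannot be reconstructed from the published
per-class tables alone.

## The synthetic generator

`generate_dataset()` emulates the one property of real radiographs this
package is about: class evidence confined to narrow, class-specific
intensity bands. Each image is a smooth random field (three random
low-frequency cosine modes) histogram-equalized onto the full 12-bit
range — every background has the same, uniform intensity distribution,
the analogue of histogram-standardized acquisition. Each positive class
adds one sharp-edged plateau blob (random center, radius 12–25% of the
image side) whose interior intensities are `level_k + contrast·(G'-1/2)`
for a plateau profile `G'`, i.e. the lesion occupies the upper half of
its class band; Gaussian pixel noise (sd 60) is added and pixels are
clipped and rounded. Defaults: 14 bands of width 400 with levels evenly
spread over [250, 3800], lesion contrast 200, prevalence 0.3 per class.
The soft rim of the blob is kept thin deliberately: a wide blend sweeps
through every intensity between background and target and pollutes all
intervening bands, destroying band specificity.

With these defaults the generator satisfies its design property: a
linear probe on images windowed to class k's band separates class k
better than the identical probe on full-range 8-bit images for at least
12 of the 14 classes at n = 1000 (typically all 14). Bit-depth reduction to 8 bits collapses the 401 distinct in-band
values to about 26, which is the quantization mechanism being studied.

What the generator does *not* emulate: anatomy, spatial correlation
between findings, view variation, label noise, or intensity
calibration drift. Passing tests on this data show that the
implementation behaves as the windowing theory predicts when the
band-signal premise holds; they say nothing about AUC values on real
chest-radiograph collections, which require the full-scale data and a
pretrained deep backbone.

## Desk-scale studies and problem sizes

The test suite runs three studies chosen to fit a single CPU:

* **Direction of effect.** 2000 training / 400 validation images at
  32×32, 10 epochs, batch 32, five seeds. WindowNet is initialized from
  the package's own grid-search selection on this data (the same
  pipeline the full-scale experiment prescribes: single-window grid →
  class-wise top 3 + full range → multi-window initialization), then
  compared at equal budget to the unclamped ablation and to an 8-bit
  full-range baseline. The assertion is on medians over seeds; in the
  frozen configuration WindowNet led on every seed (median validation
  mean AUC 0.703 vs 0.674 vs 0.664).
* **Window movement.** Single-band data (band level 1000, width 400),
  WindowNet started from deliberately mis-set windows — (2600, 1200),
  (3400, 700), (1550, 600), all with zero overlap with the informative
  band — for 10 epochs at learning rate 3e-3. The protocol rate of 1e-4
  is calibrated to full-scale step counts (hundreds of thousands of
  AdamW updates); at ~600 desk-scale steps it moves window parameters
  by fractions of a gray value, so the movement study raises the rate.
  The movement direction is the same at 1e-4, 1e-3 and 3e-3; the higher
  rate only makes it resolvable. After training, the nearest window's
  overlap with the band is positive (≈14 intensity units in the frozen
  run), and all three levels drift toward the band.
* **Bootstrap coverage.** 200 replications of 2000 images with scores
  from a unit-variance two-normal model (true AUC `pnorm(1/sqrt(2))`),
  400 resamples each; coverage of the 95% interval must be ≥ 93%.

## Numerical notes and limitations

* Equivalence and recovery tolerances: 1e-5 absolute on the 0–255
  scale and 1e-6 relative, respectively; both hold with large margin in
  double precision.
* The min–max rescale makes a K=1 full-range WindowNet agree with the
  12-bit baseline only to sub-gray-level accuracy (factor 4096/4095),
  because the largest representable pixel is one below the window's
  upper limit.
* Bit-depth reduction uses the global linear rescale
  `floor(px·(2^t-1)/(2^s-1))`; how any particular public 8-bit release
  was derived is not in general documented, so this choice is an
  assumption.
* Image I/O reads 8/16-bit grayscale PNG and TIFF and writes 16-bit
  TIFF; DICOM pixel data must be exported to one of these first. No
  photometric inversion or rescale slope/intercept handling is applied.
* The window layer's gradient vanishes on pixels saturated by the
  clamp; windows far from all image intensity mass receive gradient
  only through their unsaturated background pixels, which is why the
  movement study keeps a mis-set window within reach of the band.
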
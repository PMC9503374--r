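---
title: "Graft-U-Net polyp segmentation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graft-U-Net polyp segmentation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Colorectal polyps are protrusions of abnormal tissue on the mucous
membrane of the gastrointestinal tract; segmenting them pixel-wise in
colonoscopy frames supports early detection and resection. `graftunet`
implements an encoder–decoder convolutional network for this task in
which every encoder stage carries a *graft* convolution branch in
parallel with the conventional branch, preceded by an optional CLAHE
contrast-enhancement step and followed by confusion-count evaluation
metrics. Everything — including training — runs on the CPU in plain R
(with small C kernels for the convolution gathers), so the whole
pipeline is reproducible from a seed with no external data or hardware.

```{r, eval = FALSE}
library(graftunet)
```

## CLAHE preprocessing

Contrast-limited adaptive histogram equalization divides a frame into a
grid of equal, non-overlapping tiles (8×8 by default), equalises each
tile's gray-level histogram after clipping it, and blends the per-tile
mappings bilinearly at every pixel. Inner pixels blend four tile
mappings, border pixels two, corner pixels one (via index clamping).
The clip limit follows Reza's formula

$$\beta = \frac{M}{N}\Bigl(1 + \frac{\alpha}{100}(S_{max} - 1)\Bigr),$$

with $M$ the pixels per tile, $N$ the number of gray levels, clip
factor $\alpha \in [0, 100]$ and maximum transformation slope
$S_{max} \ge 1$. We note that these symbol roles are the only reading
under which the $\alpha = 0$ floor $M/N$ (a perfectly flat clipped
histogram) is meaningful, and adopt it even though the roles of $M$ and
$N$ are sometimes stated the other way around. Clipped mass is
redistributed uniformly across bins, iterating until no bin exceeds
$\lceil\beta\rceil$; total counts are conserved exactly, with
sub-remainder counts placed one-by-one into the lowest-index bins with
room (a deterministic tie-break).

Numerical choices worth knowing:

* **Tile mapping.** A tile's mapping is
  $v \mapsto \mathrm{round}\bigl((N-1)\,\mathrm{cdf}(v)/M\bigr)$ on the
  clipped histogram. A *degenerate* tile whose pixels all share one
  gray level maps identically; this makes constant frames exact fixed
  points of the whole operation instead of being stretched to an
  arbitrary level.
* **Colour handling.** The default `"lab"` mode converts sRGB to Lab,
  equalises the quantised lightness channel only, and converts back,
  preserving mucosal hue; `"rgb"` mode equalises each channel
  independently (and is integer-exact, which the tests exploit).
* **Grid fit.** Frames whose sides are not multiples of the tile grid
  are padded by edge reflection, equalised, and cropped back.
* **Defaults.** $\alpha = 50$, $S_{max} = 4$, $N = 256$, 8×8 tiles —
  conventional CLAHE territory; the method's authorship does not pin
  specific values, so these are package defaults, not reproductions.

Preprocessing is an explicit pipeline stage (`preprocess_dataset()` or
the `preprocess` flag of the training config), never an implicit one,
and it never touches masks.

## The network

`arch_config()` describes the graph; `build_network()` builds it and
symbolically propagates the input shape through every layer, producing
a trace that — for the default 512×512×3 input with filter depths
8/16/32/48/64 — reproduces the published 81-row layer table exactly
(`verify_against_table2()` returns zero mismatches). Every convolution
and pooling extent in the trace is an instance of the closed form

$$G_{out} = \Bigl\lfloor\frac{I - f + 2p}{S}\Bigr\rfloor + 1 .$$

**Encoder.** Five down-sample blocks. Each consists of a stem
convolution (3×3, "same" padding, stride 1) raising the channel count
to the stage depth, *two parallel branches* — the conventional branch
$\lambda$ and the graft branch $\vartheta$, each conv + batch-norm +
ReLU fed the stem output — and their element-wise sum
$H(x) = \lambda + \vartheta$, followed by 3×3 max-pooling with stride 2
and same padding (the only pooling geometry that reproduces the exact
halving of the tabulated shapes). The layer table lists three
convolution groups per stage; reading group one as the stem and groups
two/three as the parallel branches is the only interpretation
consistent with both the row count and the two-branch description, and
is what we implement. The element-wise sum is likewise the only
shape-consistent reading of the branch-merging formula.

**Skips and decoder.** The skip source of each decoder stage is the
*post-addition, pre-pool* map $H(x)$ of the mirrored encoder stage —
forced by the concatenation channel counts (64+64=128, 64+48=112,
48+32=80, 32+16=48, 16+8=24). The bottleneck is a single conv + BN +
ReLU group without a graft pair. Each decoder stage up-samples 2×,
concatenates with its skip along channels, and convolves down to the
mirrored depth; a final 3×3 convolution to one channel plus a sigmoid
yields the probability map, strictly inside (0, 1), at input
resolution.

**Batch normalisation** is implemented as
$\hat f_i = (f_i - \mu)/\sqrt{\sigma^2_{batch} + \sigma}$ with
$\sigma = 10^{-5}$, i.e. with a square root over the variance; the
variant without the root does not produce unit variance, so the
standard form is used and the deviation documented here.

**Squeeze-and-excitation.** A channel-attention gate (global max-pool
squeeze, bottleneck of width $\max(1, c/4)$, ReLU, expansion, sigmoid)
can be placed after each encoder stage's branch addition and before
pooling. It is *off by default* because the published layer table does
not list these layers — with the flag off the trace matches the table;
with `se_enabled = TRUE` the gates participate in training and
inference.

**Up-sampling.** The default is parameter-free nearest-neighbour 2×
up-sampling, which preserves channel counts exactly as the tabulated
shapes require; a learned 2×2 stride-2 transposed convolution is
available via `upsample = "transposed"`.

Weight initialisation is He-uniform and seedable. A note on layer
counting: the trace follows the 81 tabulated rows; summaries elsewhere
sometimes quote a 74-layer figure, a discrepancy we document rather
than resolve.

## Training

Nothing in the method's description fixes the loss or optimiser, so the
package's defaults are the minimal assumptions consistent with a
sigmoid head: binary cross-entropy (a soft Dice loss is available
behind `loss = "dice"`), Adam at learning rate $10^{-4}$, batch size 4,
40 epochs, no augmentation. Gradients are computed by a hand-written
reverse pass over the layer graph; the input gradient of a stride-1
same convolution is computed as another same convolution with
spatially flipped, transposed kernels, so only max-pooling needs a
scatter. The shipped tests validate the forward pass against
independent per-element references and the whole training loop against
its reproducibility and learnability contracts.
Training is bit-reproducible for a fixed seed: the seed drives weight
initialisation and batch shuffling, and inference uses batch-norm
running statistics (momentum 0.9), so a saved model predicts
deterministically.

## Synthetic study conditions

The generator (`synthetic_config()`, `generate_frame()`,
`generate_dataset()`) emulates the paired-folder layout of public
polyp datasets — one folder of frames, one of identically named binary
masks. A frame is a pink-red mucosa background with low-frequency tint
variation and a vignette darkening toward one random corner (the
lumen), optional bright specular ellipses (never part of the mask),
and 1–3 polyp blobs: ellipses with a low-order radial Fourier
perturbation, dome-shaded, brighter and redder than the surrounding
tissue. The mask is the exact union of the polyp supports. Two
invariants are enforced by construction: masks are strictly binary at
every stage, and the mean luminance inside the mask exceeds the mean
outside by at least `min_contrast` (default 0.10) — after shading,
vignette and highlights are applied, any deficit is added back to the
polyp region with a margin absorbing the zero-mean pixel noise
(`noise_sd`, default 5 gray levels). This contrast floor is what makes
the task learnable by construction and hence makes the end-to-end
training test meaningful.

What the generator does *not* emulate: real mucosal texture,
instrument artefacts, blur, stool, masking of polyps by tissue folds,
and the enormous shape/size/appearance variability of clinical frames.
A model passing the synthetic end-to-end test has demonstrated that the
architecture, gradients and pipeline work — not that it reaches
clinical-grade accuracy on real colonoscopy data.

Problem sizes were chosen so the whole suite runs comfortably on one
CPU: test frames are 64×64 (the smallest extent the five-stage
architecture pools cleanly, 512 being reserved for real-data runs), and
the end-to-end check trains on 60 frames for 30 epochs, three seeds,
reaching per-image mean Dice above 0.9 in a few minutes per seed.

## Metrics

Six confusion-count metrics: Dice $2tp/(2tp+fp+fn)$, IoU
$tp/(tp+fp+fn)$, recall, precision, $F_2 = 5pr/(4p+r)$, accuracy.
Predictions binarise at a default threshold of 0.5 (unspecified
upstream; 0.5 is the natural choice for a sigmoid output). Zero
denominators score 1 when prediction and truth are both empty of
positives (the ideal is vacuously met — this keeps all-background
frames scoreable) and 0 otherwise.

`evaluate_set()` always reports **both** aggregation modes:
`per_image_mean` (average of per-image metrics — the convention behind
"mean Dice") and `global_counts` (metrics of the pooled counts). Under
pooled counts Dice and IoU are functionally dependent,
$\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$; per-image means are
not. Published mean-Dice/mean-IoU pairs for this architecture violate
the pooled identity, so the aggregation actually used upstream is
unknowable from the numbers alone — which is exactly why both modes are
exposed rather than guessed between.

## Overlays and I/O

Datasets are indexed from paired folders with identical filenames;
unmatched files are reported by name. The 70/30 split is random by
seed (whether the original split was random or sequential is not
stated; a seeded random split is at least reproducible). Frames resize
bilinearly; masks resize by nearest neighbour and are re-binarised so
no fractional labels can appear. `render_overlay()` draws the
prediction contour in blue and the ground-truth contour in red over the
frame — where figure captions and text disagree on this colour
assignment, the in-text assignment (blue = prediction) is implemented.
Contours are one-pixel boundaries under 8-neighbourhood erosion with
the frame border counting as background.

## Known limitations

* CPU training at 512×512 is possible but slow; the package is sized
  for method study and small experiments, not GPU-scale benchmarking.
* Benchmark results on the public Kvasir-SEG / CVC-ClinicDB datasets
  are out of scope: they require downloading external data and long
  training runs, and the headline numbers are not reconstructible from
  the stated formulas alone (see the aggregation note above).
* The CLAHE clip-factor and slope actually used upstream are unstated;
  the defaults here are conventional, not reproductions.
* Whether tile-mapping interpolation was used upstream at all is
  unstated; standard CLAHE bilinear blending is assumed.
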
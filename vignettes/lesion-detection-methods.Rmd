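---
title: "Methods: phantoms, enhancement, segmentation, and detection metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantoms, enhancement, segmentation, and detection metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(buslesion)
```

`buslesion` implements a complete desk-scale working model of a
breast-ultrasound lesion-detection study: synthetic speckled phantoms
stand in for clinical image collections, a three-step enhancement chain
raises lesion/background contrast, lesion shape masks become detection
bounding-box labels, a recurrent-residual attention U-Net
(R2AttU-Net) provides the segmentation behind the enhancement, and
standard object-detection metrics (IoU, precision, recall, PR curves,
AP, mAP) score externally supplied detector predictions. This vignette
explains each model, its assumptions and tunable parameters, the
numerical choices made, and what the package's tests do and do not
demonstrate about clinical data.

## Synthetic phantoms

Clinical breast ultrasound is characterized by multiplicative speckle,
low lesion/background contrast, and hypoechoic (darker-than-background)
lesions whose margins are smooth when benign and irregular when
malignant. The phantom generator emulates exactly these properties and
nothing more:

* **Geometry.** Each lesion is a filled ellipse with uniformly drawn
  semi-axes (9–16 % of the frame side), random orientation and
  position. Malignant lesions perturb the boundary radius by
  `spiculation_amplitude` × (0.75 · sinusoid with `spiculation_lobes`
  lobes + 0.25 · a smooth random periodic component from low-order
  Fourier terms). Benign lesions have amplitude 0 by construction, and
  the constructor enforces amplitude > 0 for malignant specs. Lesions
  are rejected and re-drawn until they are pairwise disjoint (with a
  one-pixel separation) and clear of the border; a bounded retry count
  turns a geometrically infeasible spec into an explicit placement
  error.
* **Echo model.** The clean field is `background_level` outside the
  lesion and `background_level * lesion_contrast` inside
  (`lesion_contrast < 1` gives a hypoechoic lesion), smoothed with a
  Gaussian point-spread of `blur_sigma` pixels (replicate borders, so
  flat fields stay flat).
* **Speckle.** The field is multiplied by i.i.d. Gamma noise with
  shape `1/s^2` and scale `s^2` — unit mean and standard deviation
  `s = speckle_scale` — and clipped to `[0, 1]`. A Gamma field
  generalizes the squared-Rayleigh (exponential) intensity model of
  fully developed speckle while exposing dispersion as a single knob.

Defaults (`background_level` 0.5, `lesion_contrast` 0.5,
`speckle_scale` 0.3, `blur_sigma` 1.5, malignant amplitude 0.25 with 7
lobes) were fixed once as a plausible low-contrast, high-noise regime;
no public quantitative noise statistics exist for the clinical
collections this emulates, so these are testability choices, not fitted
values. Mid-gray background also keeps `[0, 1]` clipping from biasing
the unit-mean noise (clipping mass is negligible below
`background_level · (1 + 3s) < 1`), which the Monte-Carlo mean test
relies on.

A `(spec, seed)` pair determines a sample bit-for-bit. Datasets written
by `generate_dataset()` derive one RNG stream per sample from
`(master seed, index)`, so a dataset is reproducible and individual
samples do not depend on generation order. On disk the layout follows
the public breast-ultrasound collections: an 8-bit grayscale PNG per
case plus a same-stem `_mask.png` (stored `{0, 255}`, read back
`{0, 1}`, hence lossless), with annotations in CSV and COCO-style JSON.

**What phantoms do not model:** beamforming geometry, attenuation with
depth, acoustic shadowing and posterior enhancement, heterogeneous
tissue texture, or multiple echogenicity classes. Tests passing on
phantoms therefore certify the *computational* pipeline — not clinical
detection performance.

```{r phantom, eval = FALSE}
sample <- generate_phantom(phantom_spec(lesion_class = "malignant", seed = 7))
autoplot(sample)
```

## Contrast enhancement

Preprocessing is CLAHE followed by anisotropic diffusion
(`preprocess()`), with segmentation-based enhancement (SBE) as the
third step once a lesion mask is available.

### CLAHE

The image is divided into an `N × N` tile grid. Each tile's gray-level
histogram (`n_bins`, default 256) is clipped where the equalization
mapping's slope would exceed `clip_threshold` `T`, expressed as a
multiple of the uniform tile-histogram height — `T = 1` forces the
identity mapping's slope, `Inf` disables clipping. Clipped excess is
redistributed uniformly over all bins in a single pass (the
redistribution may push a bin marginally back over the limit; we do not
iterate, so the slope bound holds up to one-bin discretization). The
tile mapping is the normalized CDF of the clipped histogram, and each
pixel's output is the bilinear blend of the four surrounding tile
mappings (clamped at the borders), which removes tile-boundary
blocking. With one tile and no clipping this reduces exactly to global
histogram equalization — the package's tests exploit that limit against
an independently coded oracle. Defaults `N = 8`, `T = 2` follow common
practice; the source method description does not specify them.

### Anisotropic diffusion

Each iteration updates a pixel by `strength / 4` times the sum over its
four neighbours of `c(d) · d`, where `d` is the neighbour-minus-center
difference and `c(d) = exp(-(d/k)^2)` is the conduction coefficient:
near 1 across flat regions (smoothing) and near 0 across strong edges
(edge preservation). The gradient threshold `k` separates "noise"
differences (diffused) from "edge" differences (kept); useful values
sit near the noise amplitude, and for the default phantoms
(speckle × mid-gray background) that is around 0.15–0.3.

Two deliberate numerical choices:

* **Sign convention.** The iterative expression as printed in the
  method's source adds flux proportional to (center − neighbour), which
  *sharpens* — each pixel moves away from its neighbourhood. We
  implement the standard Perona–Malik smoothing sign
  (neighbour − center), treating the printed form as a typographical
  slip, and keep an `as_printed = TRUE` flag that reproduces the
  literal update for comparison (it is the exact mirror image:
  `2 · img − standard`).
* **Boundaries and conservation.** Replicate (Neumann) borders make
  boundary fluxes vanish and interior fluxes pairwise antisymmetric, so
  each iteration conserves total intensity exactly (to accumulation
  rounding, < 1e-9 relative), which the tests assert.

On stability: the update is a convex combination of the pixel and its
neighbours only when `strength ≤ 1` (per-neighbour weight ≤ 1/4, the
classic discrete bound), and in that regime the output range can never
exceed the input range. Strengths up to 4 are accepted — the update
remains conservative — but can locally overshoot the range by an amount
of order `(strength − 1) ×` the local intensity gap, so the default is
`strength = 1` and the range-stability property is tested for
`strength ≤ 1`.

### Segmentation-based enhancement

SBE multiplies the image by a weight map that is `lesion_weight`
(default 1) inside the segmented lesion and `background_weight`
(default 0.6) outside. Dimming the background by 0.6 boosts the
lesion-to-background contrast ratio by exactly `1/0.6 ≈ 1.67` — pure
piecewise arithmetic, which the tests verify exactly on noiseless
phantoms.

The chain order is an open question in the source description: one
reading multiplies the weight map with the CLAHE+diffused image (the
three-step chain), the figure-level reading multiplies the *original*
image. The pipeline supports both (`sbe_on = "preprocessed"` or
`"original"`) and defaults to the preprocessed image, on the grounds
that the description presents SBE as the third step of one chain.

## The R2AttU-Net segmenter

The segmentation network combines a recurrent-residual encoder with an
attention-gated decoder:

* **Encoder level** (channels `base_channels · 2^(level-1)`, standard
  U-Net doubling — exact widths are not printed in the source, so the
  convention is assumed): a 1×1 projection to the level width, two
  recurrent convolution layers, and a residual shortcut around the
  pair, followed by 2×2 max pooling. A recurrent layer applies one
  shared 3×3 kernel `t` times; step `i` convolves (block input + step
  `i−1` output). `t = 2` follows the R2U-Net convention (the source is
  silent).
* **Decoder level**: 2×2 transposed-convolution upsampling (the
  Attention U-Net convention), an additive attention gate — 1×1
  projections of skip and gating signals, ReLU, 1×1 + sigmoid —
  producing per-pixel coefficients in `[0, 1]` that rescale the encoder
  skip, then concatenation and a double 3×3 convolution block.
* **Head**: 1×1 convolution to one channel; sigmoid gives the lesion
  probability.

Training uses the published recipe as defaults (Adam, learning rate
0.001, batch size 4, 200 epochs); the loss is binary cross-entropy
(computed stably on logits) with soft Dice optional — the source does
not state its loss. Inputs are min-max normalized to `[0, 1]` and
resized bilinearly to `input_size`; predicted masks are thresholded at
0.5 and mapped back to the original frame by nearest-neighbour
resizing.

The implementation is a self-contained small-scale CNN engine: im2col /
col2im convolution kernels in C++ with BLAS matrix products, a minimal
reverse-mode tape, and hand-written layer gradients — every gradient is
unit-tested against central-difference numerical differentiation, and
the parameter count of a reference configuration is checked against a
hand-derived closed form. Weight initialization and epoch shuffling are
seeded, so training is bit-reproducible on a fixed machine.

Desk-scale capacity is demonstrated by overfitting: a depth-3,
8-channel, `t = 2` model reaches mean training Dice ≥ 0.9 on eight
64×64 phantoms within 200 epochs (about 70 in practice) in a few
minutes on one CPU. This certifies that the architecture and optimizer
can fit the task at small scale; it says nothing about generalization
to held-out clinical images.

## Detection labels and metrics

A lesion mask becomes a detection label by scanning all non-zero pixels
for the extreme column/row coordinates: corners
`(x_min, y_min)`–`(x_max, y_max)`, 0-based inclusive, with
`w = x_max − x_min` and `h = y_max − y_min` following the source's
literal definition (no `+ 1`). Areas for IoU are computed on the
inclusive pixel grid, `(w + 1)(h + 1)`, so a single-pixel box has area
1, not 0. Multi-lesion images can be boxed per 8-connected component or
as one global box (how the original labels handled them is unstated;
both modes are provided, per-component is the default).

Matching follows modern detection practice: predictions below the
confidence threshold are dropped, the rest are matched greedily in
descending confidence to the unmatched same-class ground-truth box of
highest IoU, and a match counts as TP only when IoU exceeds 0.5
strictly (boundary IoU = 0.5 is FP). Duplicates of an already-matched
box are FP. Two false-negative definitions coexist:

* `standard` (default): every unmatched ground-truth box is FN, so
  TP + FN equals the ground-truth count and recall is well defined;
* `paper_literal`: only ground-truth boxes with *zero* IoU against
  every retained same-class prediction are FN — the literal published
  definition, under which boxes overlapped at 0 < IoU ≤ 0.5 are
  unaccounted.

Precision is TP/(TP+FP) and recall TP/(TP+FN), with 0/0 defined as 1
(no ground truth, no predictions). The PR curve sweeps every distinct
prediction confidence; AP integrates the curve either as the monotone
precision envelope over recall increments (`all_points`, the default
and the modern benchmark convention) or by the raw trapezoidal rule —
which interpolation the original evaluation used is unstated, so both
are exposed. mAP is the unweighted mean over the classes present.

## Pipeline

`run_pipeline()` chains the stages: phantom generation (or an existing
dataset), a seed-reproducible train/validation/test split with sizes
proportional to 8:1:1 by largest-remainder rounding (optionally
stratified by class to within one item), CLAHE + diffusion, lesion
segmentation (trained R2AttU-Net or oracle ground-truth masks), SBE,
label generation, and evaluation of externally supplied predictions.
The detector itself is out of scope — the published system uses an
existing detection toolbox — so predictions enter through a standard
results interface (CSV or COCO-results JSON), and
`oracle_predictions()` manufactures perfect or jittered predictions
from the ground truth to exercise the chain. Boxes detected on a
resized working frame are mapped back to original-image coordinates by
per-axis scaling with rounding and clamping; the map-up-then-back round
trip is exact to one pixel per corner (no such bound can hold when the
first leg is a severe downscale, which destroys pixel information).
Every stage logs its parameters, seed, and output file hashes to a JSON
log; reports contain no timestamps, so reruns with the same
configuration and seed are byte-identical.

## Problem sizes used in the tests

The test-suite and acceptance-script problem sizes are the package's
chosen desk-scale study conditions: oracle comparisons run on hundreds
of randomized small images, masks, and box pairs; the overfitting check
uses eight 64×64 phantoms (depth 3, 8 base channels, `t = 2`); the
end-to-end pipeline run uses fifty 128×128 phantoms with a 64-pixel
working frame and a small (depth-2, 4-channel) segmenter. The published
headline numbers on the clinical collections (mAP around 0.9 on the
combined dataset) require those datasets plus GPU-scale detector
training and are out of scope here; nothing in this package should be
read as reproducing them.

## Known limitations

* Phantoms omit every acoustically structured artifact (shadowing,
  enhancement, depth attenuation); enhancement parameters tuned on them
  will not transfer to clinical images unchanged.
* CLAHE redistributes clipped mass in one pass; mappings may exceed the
  slope limit by up to one bin's worth.
* The segmenter trains on one CPU at desk scale; it is deliberately not
  optimized for large images or datasets.
* `paper_literal` matching can make recall exceed what standard
  accounting would give (FN is smaller by construction); it exists for
  fidelity, not for reporting.
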
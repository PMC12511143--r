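---
title: "Methods: a ghost-inception, wavelet-convolution detector for bark-beetle images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a ghost-inception, wavelet-convolution detector for bark-beetle images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bark beetles (subfamily Scolytinae) caught in traps span a wide range of body
sizes, and several of the six commonly monitored categories — Boerner,
Leconte, Linnaeus, Acuminatus, Armandi, Coleoptera — look alike: similar
browns, similar elongated bodies, textures that differ only subtly.  A
detector for such imagery must resolve very small objects (a few percent of
the image side) and very large ones in the same scene, and must separate
classes whose visual evidence is mostly textural.  `giwtnet` implements a
lightweight single-stage detector built for exactly this regime, together
with everything needed to verify its architectural claims on a desk: an
analytic cost model, a parameter-accounting engine checked against a
published layer table, detection metrics, a synthetic scene generator, and a
CPU training loop.

## The architecture

The network is a small-width (multiplier 0.5) single-stage detector with
three modifications to the standard backbone–neck–head template.

**GIConv.** Each of the four stride-2 downsampling convolutions in the
backbone is replaced by a ghost-inception convolution: a `k x k` stride-2
convolution produces only half of the output channels (the "core" map), and
a four-branch Inception block computes the other half from the core map at
multiple scales (1x1; 1x1 then 3x3; 1x1 then two 3x3; 3x3 max-pool then
1x1, each branch emitting a quarter of the core width).  With branch widths
fixed this way, the block's multiply–accumulate (MAC) cost is exactly
$\tfrac{15}{8} H w c^2$ (branches $\tfrac14, \tfrac{13}{32}, \tfrac{31}{32},
\tfrac14$), and the whole layer costs

$$S \;=\; \frac{\text{GIConv MACs}}{\text{standard conv MACs}}
      \;=\; \frac12 + \frac{15\,n}{32\,k^2 c},$$

independent of spatial size.  At $k = 3$ and $n = 2c$ this is $0.604$: the
layer needs about 60% of a standard convolution's computation.  The package
computes this ratio both in closed form (`cost_ratio()`) and by
instrumenting the constructed layer (`count_macs()`); the two agree exactly.

**WTConv inside C3K2 stages.** Distinguishing similar textures benefits from
a large receptive field, but growing a dense kernel is quadratic in
parameters.  The wavelet-transform convolution takes an orthonormal 2-D Haar
decomposition of the feature map (`haar_dwt2()`), applies a *small*
depthwise convolution jointly to the four frequency bands at each pyramid
level, and recomposes from the deepest level upward through the inverse
transform, adding a depthwise-convolved base path at full resolution.  One
level of decomposition doubles the span of input pixels that influence an
output pixel, so the receptive field grows as $2^L (k-1) + 1$ while
parameters grow only linearly in $L$ (each level adds $4Ck^2 + 4C$).  The
bottlenecks of the split-transform-concat stages (C3K2) carry these
operators in place of their dense convolutions, giving the C3K2_WT stages.

A note on the receptive-field count: `wtconv_receptive_field()` returns
$2^L(k-1)+1$, the span of the equivalent dilated convolution, which is the
number usually quoted for wavelet convolutions.  Because the Haar pyramid
is a *block* transform rather than an à-trous dilation, a perturbation
trace of the actual cascade measures a span up to $2^L - 1$ pixels larger
(40 rather than 33 at $L = 3$, $k = 5$), depending on where the pixel falls
within its alignment block.  The tests assert the measured span within that
slack; the growth law — doubling per level against linear parameter cost —
is unaffected.

**SE attention between neck and head.** Each of the three fused feature maps
exported by the neck passes through a squeeze-and-excitation block (global
average pool, `c -> c/r` bottleneck with `r = 16`, sigmoid gate) before the
detection head, letting the head reweight channels that discriminate between
look-alike classes.  An alternative placement on the backbone taps is kept
behind `network_spec(se_position = "backbone")` for placement comparisons.

The head is anchor-free: per cell it predicts 6 class logits and four
16-bin distribution-focal distributions whose expectations, scaled by the
stride, are the distances from the cell centre to the box sides.

## Conventions pinned by the reference layer table

Every convolution in the network is bias-free and followed by per-channel
batch normalization (2 learnable parameters per channel) and SiLU.  This
convention is not arbitrary: the published layer table's stem row (928
parameters) equals $3\cdot32\cdot9 + 2\cdot32$ only under it, and the four
GIConv rows (11,296 / 81,728 / 326,272 / 713,984), the SPPF row (656,896)
and the attention-stage row (990,976) then all follow exactly from the
stated constructions.  `summarize()` enumerates a built model layer by
layer and `compare_to_reference()` diffs it against `table2_reference()`;
the six pinned rows must match exactly for the comparison to pass.

The published C3K2_WT stage counts (26,080 / 103,360 / 293,632 / 1,127,936)
are *not* reproducible from any stated configuration: neither the WTConv
kernel size, nor the level count, nor which of the two bottleneck
convolutions is replaced is recorded.  Rather than guess a "true" setting,
`calibrate_wtconv_config()` enumerates candidates (k in {3,5,7}, L in
{1,2,3}, both-vs-second replacement, scales on/off) and reports each
candidate's four stage counts beside the targets with deviations, flagging
the closest without adopting it.  The package default (k = 5, L = 1, base
path on, per-channel scales, no bias) follows the WTConv design the
architecture cites; both knobs stay exposed in `network_spec()`.

One related discrepancy: the reference table's spatial column (160 down to
10) implies a 320x320 input under the standard five stride-2 stages, while
the training recipe resizes inputs to 640.  Spatial sizes here are simply
parameterised by input size; the table comparison runs at 320 so the
spatial column matches, and training defaults to 640.

## Numerical choices

* **Wavelet normalization.** The Haar filters are orthonormal
  ($(1,1)/\sqrt2$, $(1,-1)/\sqrt2$), so analysis conserves energy, synthesis
  is the exact inverse, and — usefully for training — the adjoint of the
  transform equals its inverse, which gives the backward pass for free.  A
  constant map of value $v$ therefore has $LL \equiv 2v$ and vanishing
  high-frequency bands.
* **Odd sizes.** Inputs with odd height or width are padded by edge
  replication before each decomposition and cropped after recomposition, so
  reconstruction stays exact at every level.
* **Initialisation.** Kernels use fan-in uniform bounds, per-channel scales
  start at 1, the class-head bias starts at the logit of a 1% prior and the
  box-head bias at 1; all draws are ordered by construction, so
  `build_model(spec, seed)` is bit-reproducible.
* **Stride.** The wavelet cascade itself is always stride 1; downsampling is
  carried by the primary convolution of GIConv (or a following layer).
* **Degenerate inputs.** Zero-area boxes evaluate to IoU 0 with a warning;
  classes without ground truth are excluded from mAP means with a message;
  `0/0` precision or recall is defined as 0.
* **FLOP convention.** GFLOPs are twice the instrumented MACs of
  convolutions and fully-connected layers; normalization, activations,
  pooling and the token-space attention products are excluded, matching
  common detector reporting.  Totals therefore scale with input pixel count
  up to the (constant) SE contribution.

## Detection metrics

Matching is class-wise and confidence-ordered: each detection claims the
highest-IoU unmatched ground truth of its class at or above the threshold;
unmatched detections are false positives, unmatched ground truths false
negatives.  Average precision integrates the precision envelope at the 101
recall points $0, 0.01, \dots, 1$ (the modern detector convention; the
published equations do not fix an interpolation rule, and the exact
all-point envelope stays available via `interpolation = "exact"`).  mAP@50
is the class-mean AP at IoU 0.5; mAP@50~95 averages the class-mean AP over
the ten thresholds $0.50, 0.55, \dots, 0.95$.  Operating points follow
common practice where the recipe is silent: confidence 0.001 with NMS IoU
0.7 for the AP sweep, confidence 0.25 with NMS IoU 0.45 for reported
precision/recall/F1.

## The synthetic scene generator

No accession exists for the original trap-image set, so the generator
emulates its statistical structure rather than its appearance: six classes
with distinct but confusable hue/texture prototypes (a `texture_confusability`
knob interpolates prototypes toward their mean), a strongly bimodal size
distribution (small bodies 2–6% of the image side, large 10–25%, mixed by
`size_mix`), oriented elliptical bodies on a textured background, and a
multiplicative illumination gain varied across images.  Boxes are tight
axis-aligned hulls of the rotated ellipses.  Datasets are written as PNG
images with Pascal-VOC XML annotations (1-based inclusive coordinates) and
split manifests; the default desk-scale counts 64/8/8 keep the spirit of the
published 1693:245:245 split.  Mosaic (random-centre four-image tiling, boxes
clipped and dropped below 10% surviving area) and mixup (convex pixel blend,
box union with source weights) follow common detector practice; the original
recipe names both without parameters, so the probabilities (mosaic 1.0,
mixup 0.15, uniform weight 0.3–0.7) are configuration, not a claim.

What passing tests on these scenes show — and what they do not: the scenes
exercise every pipeline contract (annotation round-trips, assignment,
losses, decoding, metrics) and the learnability of the architecture, but
they are rendered ellipses, not beetles; success here says nothing about
accuracy on real trap imagery, which is explicitly out of scope.

## Training

The published recipe is the default configuration: SGD with momentum 0.937,
weight decay 0.0005, batch size 32, 300 epochs, initial learning rate 0.01
under cosine annealing (floor 1% of the initial rate, 3 warmup epochs), and
early stopping on the validation loss with patience 100 (strict
improvement resets the counter; validation-loss monitoring follows the
recipe text, though a mAP-based fitness blend is the wider convention).
Loss weights follow the baseline detector family: CIoU box loss 7.5,
binary cross-entropy class loss 0.5, distribution-focal loss 1.5.  The
assigner is a centre-prior one-to-many rule: each box goes to one scale by
size (longer side at or below 18.75% of the input to stride 8, at or below
50% to stride 16, else 32), claiming its centre cell plus 8-neighbour cells
whose centres fall inside the box; contested cells keep the smaller object.

Problem sizes in the test suite are deliberately miniature: the unit tests
run layers on 6–16 pixel maps, and the learnability check overfits 8
synthetic 256x256 scenes with the width-0.25 model variant for at most 300
iterations and asks for train-set mAP@50 of at least 0.5 — a wiring and
trainability check, not a benchmark.  The full-width model and 640-pixel
inputs remain the defaults for real use.

## Known limitations

* The forward/backward engine is double-precision, single-threaded CPU R
  with Rcpp kernels; it is meant for desk-scale verification and small
  studies, not for GPU-scale training.
* The C3K2_WT parameter ambiguity above means the model's total parameter
  count deviates from the published total by a few percent under any single
  WTConv setting; the comparison utility reports the deviation rather than
  asserting it away.
* The C2PSA attention stage is specified only by name in the source
  architecture; its internals here follow the baseline detector family, and
  happen to reproduce the published 990,976-parameter row exactly.
* The generator emulates statistics, not morphology; results on synthetic
  scenes do not transfer to real Scolytinae imagery.
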
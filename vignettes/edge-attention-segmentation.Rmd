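---
title: "Edge-attention segmentation networks: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-attention segmentation networks: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Binary medical image segmentation asks for a pixelwise foreground mask —
a tongue body in a face photograph, retinal vessels in a fundus image,
lung fields in a CT slice. Plain encoder–decoder networks of the U-Net
family recover such masks well in the interior but blur object boundaries,
because boundary evidence lives in shallow, high-resolution features that
are progressively discarded on the way down the encoder. The architecture
implemented here counteracts that with an explicit *edge module* running
alongside the encoder–decoder backbone, extracting edge-attention maps
from the shallow stages and feeding edge features back into the final
prediction, with an auxiliary edge-prediction head supervised early.

The forward pass, as built by `new_meanet()`:

1. **Encoder.** Four encoding blocks E1..E4 with 2×2 max pooling between
   them, so E1 is at full resolution and E4 at 1/8. Each block is a 3×3
   convolution, then asymmetric 3×1 and 1×3 convolutions (a cheap
   factorised approximation of a second 3×3), each followed by ReLU and
   batch normalisation, plus a 1×1-convolution residual path; the two
   paths are summed. Input height and width must be divisible by 8.
2. **EFE.** The configured encoder stages (E1 and E2 by default) are each
   mapped to `attention_maps` = 16 channels with a 3×3 convolution
   (ReLU + BN); branches from deeper stages are bilinearly upsampled by
   the needed power of two; the branches are summed into the attention
   stack A.
3. **MAG.** Each single-channel attention map multiplies all channels of
   the shallow features X1 = E1 and the products are summed — because the
   product broadcasts, this equals `(Σ_m A_m) ⊗ X1`, and the
   implementation uses that collapsed form while the triple-loop
   definition is kept as a test oracle. A squeeze-and-excitation block
   then gates the channels: global average pooling to `z`, a reducing
   linear map `W2` (bottleneck `max(1, floor(C/16))`), ReLU, an expanding
   map `W1`, sigmoid. The gated tensor feeds two 1×1-convolution heads:
   Y1 (edge features for the decoder, `stage_widths[1]` channels) and Y2
   (a one-channel edge logit map for early supervision).
4. **Decoder.** Three cascaded decoding blocks: D3 fuses E3 with E4, D2
   fuses E2 with D3, D1 fuses E1 with D2. In each block the low-level
   input passes a 1×1 convolution; the high-level input passes a 1×1
   convolution, bilinear ×2 upsampling, then global max pooling and two
   1×1 layers (ReLU, then sigmoid) that produce per-channel weights in
   [0, 1] which rescale the upsampled features; the branches are added
   (concatenation with a 1×1 projection is available via
   `decoder_combine`).
5. **Fusion.** D1's output and Y1 are concatenated (or added, via
   `fuse_mode`) and a final 3×3 convolution plus sigmoid yields the
   segmentation probability map; the edge probability is the sigmoid of
   Y2. Both outputs are at the input resolution.

The training objective is `α·L_Dice + (1−α)·L_BCE` with α = 0.3: the Dice
term supervises the edge head (edge labels are a thin, heavily imbalanced
class, which Dice handles gracefully), the cross-entropy term the
segmentation head. A `supervision = "joint_both"` switch instead applies
the full mixed loss to each head against its own target, since the joint
loss is described as serving all segmentation tasks; the split form is the
default reading.

## Where the published description is open, and what this package does

Several details are not pinned down by the published description; the
choices below are this package's own, each behind a configuration switch
where reasonable:

* **Stage widths** default to (64, 128, 256, 512) — the classical U-Net
  progression, consistent with "mapped into 16 channels" being a strong
  reduction from E1/E2.
* **Downsampling** is 2×2 max pooling, the standard choice in this model
  family.
* **Batch-norm placement** follows the repeated phrase "followed by one
  ReLU and one batch normalisation": conv → ReLU → BN.
* **Excitation order** is exactly as printed: the reducing weight is
  applied first, then ReLU, then the expanding weight, then sigmoid.
* **Y1 injection point.** The arrow from the edge module into the
  decoding path is ambiguous; the final-fusion reading ("the predicted map
  and edge map are combined, and then a convolution operation is
  performed") is adopted: Y1 joins after the last decoding block, by
  concatenation by default.
* **Y2 supervision resolution** is E1's, which equals the input
  resolution in this architecture, so the question of upsampling the edge
  head never arises in practice.
* **Global max pooling** in the decoder gate is over all spatial
  positions (the "global context features" reading), not windowed.
* **Edge ground truth** is nowhere specified; the width-1 morphological
  gradient of the mask is used (`derive_edge_map()`, with `inner`/`outer`
  variants). The gradient is symmetric under mask complement, which makes
  the label independent of which class is called foreground.
* **Division-unfriendly inputs** raise an error naming the
  divisibility-by-8 requirement rather than being silently padded, so
  every tensor shape in a run is exactly reproducible.
* **Weight initialisation** is Kaiming-uniform from a seeded generator;
  biases and batch-norm offsets start at zero, gains at one.
* **Ratio vs k-fold protocol**: both an 8:1:1 split and k-fold
  cross-validation are described for the same data; `make_splits()`
  implements both and the caller chooses.
* **No learning-rate schedule** is mentioned; the rate is constant by
  default with an optional cosine decay.

## Losses and metrics: numerical conventions

* Dice loss uses a smoothing constant `smooth_eps = 1e-6` in the
  denominator; cross-entropy clips predictions to
  `[clip_eps, 1 − clip_eps]`, `clip_eps = 1e-7`. Both guards are numerical
  safety only and sit well below any quantity of interest.
* Dice is computed per image and averaged over the batch; cross-entropy
  is a per-pixel mean, so batch size does not rescale the loss.
* All five evaluation metrics are computed per image and aggregated as
  mean ± sd, matching the per-image-then-mean form of the printed
  formulas. Images whose ground truth has no foreground leave sensitivity
  and Dice undefined (0/0) and are excluded from those means with a
  warning rather than silently biasing the aggregate.
* AUC is the Mann–Whitney statistic via midranks (ties count one half);
  it is invariant under strictly monotone transforms of the scores.
* The BF score extracts boundary points as mask pixels with a background
  4-neighbour (8-connectivity optional; pixels at the image border count
  the outside as background) and matches them within a Euclidean
  tolerance θ. The binarisation threshold (0.5) and θ (0.75 % of the
  image diagonal, the usual contour-matching convention) are defaults of
  this package, not published values, and both are exposed in the
  configuration. At 64×64 the default θ is under one pixel, which makes
  the BF score a deliberately strict measure on small phantoms.

## The numerical core

No deep-learning framework is used: the package authors its own
reverse-mode automatic differentiation on a linear tape, with
RcppArmadillo kernels for the hot operations (im2col + GEMM convolution
with adjoints for input, kernel and bias; 2×2 max pooling; factor-2
bilinear upsampling with half-pixel centres and clamped edges; per-channel
batch normalisation). Everything runs in double precision. Batch
normalisation uses biased batch variance for normalisation, keeps
unbiased running statistics with momentum 0.1, and uses the running
statistics in evaluation mode — so evaluation forward passes are
deterministic functions of the weights, verified bitwise in the tests.
Adam follows the standard bias-corrected form with ε = 1e-8.

Every differentiation primitive is tested against central finite
differences, and whole-network gradients are spot-checked the same way.
One caveat inherited from ReLU gating: with unlucky initialisations a
squeeze-and-excitation bottleneck (or a decoder gate) can start with all
its ReLU units inactive for a given batch, in which case its weights
receive a zero gradient until other parameters move. The gradient-flow
checks in the test suite therefore run on batches where the gates are
active — they verify that no branch of the computation graph is
structurally disconnected, not that ReLUs never saturate.

## What the phantom generator emulates — and what it does not

`generate_phantom()` produces three regimes, mirroring the kinds of data
the architecture targets:

* `blob` — one large compact foreground object with a Fourier-perturbed
  radius on a cluttered background (tongue-like);
* `vessel` — thin branching curvilinear trees, 1–3 px wide, drawn by a
  seeded random walk with branching (retinal-vessel-like; foreground
  fraction on 64×64 images stays within roughly 1–25 %);
* `lung_pair` — two mirrored smooth regions with optional interior holes
  (lung-CT-like).

Intensities follow a two-level model (foreground 0.7, background 0.3)
with additive Gaussian noise and clutter, clipped to [0, 1]. The
parameters were chosen once so that toy problems are learnable in minutes
on a CPU. The phantoms exercise every code path — shapes, losses,
metrics, augmentation, I/O — but they are deliberately *not*
photometrically realistic: no texture, no illumination gradients, no
annotation noise, no domain shift. A network that overfits eight phantoms
demonstrates that the architecture, gradients and optimiser work
together; it says nothing about accuracy on clinical data, which would
require the real datasets and far longer training.

Augmentation applies one jointly sampled geometric transform to image,
mask and edge label. All transforms are exact — quarter-turn rotations,
horizontal/vertical flips, integer translations (images padded with the
background intensity, labels with 0) — so masks remain binary with no
resampling artefacts; arbitrary-angle rotation with interpolation is
intentionally omitted.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run everything at desk scale,
chosen to keep a full run in the low minutes: oracle comparisons on 2–8 px
tensors, metric property sweeps on 6×6 masks (hundreds of random
instances), block and pipeline tests on 16–32 px phantoms with reduced
widths (4–64 channels), and the learning check with the full default
architecture on eight 64×64 blob phantoms, batch size 4, at most 200
optimiser steps with early stopping once the monitored Dice reaches 0.95
(typically 12–30 steps are needed). The headline published accuracies on
real tongue/vessel/lung datasets are out of scope here: they require the
original data and long GPU training.

## Known limitations

* Single foreground class and 2-D inputs only; no multi-class or
  volumetric support.
* No pretrained backbones; the encoder is always trained from scratch.
* Stride-1 convolutions with "same" padding only — sufficient for this
  architecture, not a general convolution library.
* Training is single-threaded apart from BLAS; there is no GPU path, so
  the package is meant for experimentation and verification at moderate
  image sizes rather than production-scale training.
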
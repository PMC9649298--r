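---
title: "MC-UNet: model, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MC-UNet: model, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mcunet)
```

## The segmentation problem

Retinal fundus photographs show the vascular tree of the eye; its
morphology (branching, widths, tortuosity) carries diagnostic signal for
ophthalmic and systemic disease. Segmenting vessels pixel-by-pixel is hard
because the tree spans scales from ~5 px trunks down to 1 px, low-contrast
microvessels, and because annotated data is scarce (the public datasets
hold 20–40 images each). `mcunet` implements a compact U-shaped
encoder/decoder tailored to this regime, together with everything needed
to exercise it end to end — metrics, data handling, a training loop and a
procedural data generator — with no external downloads.

## The network

The backbone is a four-level U-shape with three skip connections. Every
stage is a *double convolution block*: two rounds of 3×3 convolution
(1-pixel zero padding, extents preserved) → DropBlock → batch
normalisation → ReLU. Levels are connected by 2×2 max-pooling on the way
down and learned 2×2 transposed convolution on the way up, with
same-resolution encoder features concatenated into the decoder. A final
1×1 convolution and sigmoid produce a per-pixel vessel probability.
Channel widths start at `base_channels = 16` and double per level
(16/32/64/128).

At the bottleneck, two branches run in parallel on the deepest feature
`F`:

* **Spatial attention.** Channel-wise max- and mean-pooled maps of `F`
  are stacked into a 2-channel descriptor; a 7×7 convolution (with bias)
  and a sigmoid produce a single-channel gate `att ∈ (0,1)` that
  multiplies `F` elementwise:
  `SA = F · σ(f⁷([max_c F ; mean_c F]))`.
* **Context.** A *dense atrous convolution* (DAC) module runs four
  cascades of 3×3 dilated convolutions built from rates (1, 3, 5) —
  rate 1; rate 3 then 1×1; rates 1,3 then 1×1; rates 1,3,5 then 1×1 —
  each followed by ReLU and added residually onto the input, so zero
  weights leave the feature unchanged. Its output feeds *multikernel
  pooling* (MKP): max-pooling with windows 2, 3, 5 and 6 (stride equal to
  the window, ceiling mode at ragged borders), a 1×1 convolution to one
  channel per window, nearest-neighbour upsampling back to the bottleneck
  extents, and concatenation with the input (4 extra channels).

The two branch outputs are concatenated along channels (128 + 132 = 260 at
the defaults) and reduced back to the decoder width by a 3×3 convolution.
A dilated convolution with rate *r* samples its input with *r*-pixel gaps
between taps, `y[i] = Σ_k x[i + r·k] w[k]`; at `r = 1` it is exactly
standard convolution, and a 3×3 kernel at rate 5 sees an 11×11 field, so
the cascade covers local detail through near-global context without any
further downsampling.

## Where the design was open, and what we chose

Several architectural details are not pinned down by the published
description; the package fixes them as follows, and exposes each in
`model_config()` so alternatives remain testable.

* **Fusion: concatenation vs summation.** The prose describes
  concatenating the attention and context branches while the symbolic
  form writes a sum; concatenation is the default (`fusion_mode =
  "concat"`) because the two branches have different widths (the MKP
  output carries 4 extra channels), and a `"sum"` mode — projecting the
  context branch first — exists for ablation.
* **DAC wiring.** The four-branch cascade follows the dense-atrous design
  the module descends from, restricted to the named rates (1, 3, 5);
  branch topology is a constructor argument (`new_dac(..., branches=)`).
  Inside branches we apply ReLU but no batch norm. The residual
  accumulation realises the sum over branch outputs.
* **Attention input.** Both the attention and the context branch consume
  the raw bottleneck feature (parallel form); the alternative of feeding
  attention with the DAC output is expressible through the layer API but
  is not the default.
* **Double vs single conv per stage.** Two units, the standard U-shape
  choice; `double_conv = FALSE` switches to one.
* **Ordering within a unit.** Conv → DropBlock → BN → ReLU, matching the
  listing order of the components.
* **DropBlock.** Neither block size nor keep probability is published;
  defaults are `block_size = 7`, `keep_prob = 0.82`, conventional for
  this backbone family, applied symmetrically in encoder and decoder and
  inert at inference. The block size is clipped to the feature extent on
  small maps. Survivors are rescaled by (total/kept) so the expected
  activation mass is conserved.
* **Decoder upsampling.** Learned 2×2 transposed convolution by default;
  `upsample = "nearest"` (resize + 3×3 conv) is available.
* **Channel widths.** Unpublished; `base_channels = 16` puts the
  attention-only backbone at ~0.63 M parameters, the regime of the
  published parameter table (0.54 M), and the full network at ~1.87 M,
  comfortably under the 7.76 M five-level U-Net it is compared against.
  The published 2.36/2.37 M counts for the DAC variants cannot be matched
  exactly without the unpublished widths; the test suite prints achieved
  counts next to the published ones and asserts the strict ordering
  backbone < +MKP < +DAC < full, which is width-independent.

## Numerical choices

* Batch normalisation uses biased batch statistics during training
  (ε = 1e-5, running-stat momentum 0.1) and running statistics at
  inference, so inference is deterministic.
* Max-pooling breaks ties by first occurrence in column-major order; the
  MKP pools use ceiling mode, clipping the last window at the border, so
  the 6×6 window works on a 48×48 bottleneck (ceil(48/6) cells).
* Nearest-neighbour upsampling maps target index *i* to source index
  `floor(i·h/H)`, which keeps upsampled pooled maps piecewise constant
  over aligned pooling cells.
* Convolution padding is zero padding of `r·(k−1)/2`, so every block
  preserves spatial extents and skip concatenation needs no cropping; an
  even kernel with size-preserving padding is rejected as a
  configuration error.
* Inputs with extents not divisible by `2^(depth−1)` are reflect-padded
  by `preprocess()` and predictions cropped back; `forward()` refuses
  them with a pointer to `predict_image()`.
* Metrics with zero denominators (degenerate images) return 0 with a
  warning rather than erroring; AUC on single-class truth is an error
  because no ranking statistic exists.
* Training minimises binary cross-entropy computed from logits (the
  `log(1+exp(−|z|))` form), optionally plus soft Dice; Adam with
  learning rate 1e-3, β = (0.9, 0.999). Divergence (non-finite loss)
  aborts with a diagnostic rather than continuing.

## The synthetic generator

`synthetic_config()` / `make_dataset()` emulate the *structure* of fundus
data: a circular field of view on black background with a radially
brighter disc, a branching vascular tree grown by random walks seeded on
the FOV boundary (stroke width tapering from ~4 px trunks to 1 px
microvessels at branch events), vessels darker than background by a
configurable contrast, additive Gaussian noise, and 8-bit quantisation.
Defaults were fixed once by a 100-seed calibration: the vessel fraction
inside the FOV spans 0.08–0.17 (mean 0.135), the class balance of real
vessel ground truth, and every mask contains a tree spanning most of the
FOV diameter.

What the generator does **not** emulate: optic disc and macula, lesions
and pathology, colour and illumination variation between cameras, JPEG
artefacts, inter-expert annotation ambiguity. Tests passing on synthetic
data therefore demonstrate that the architecture, gradients, metrics and
pipelines are correct and that the network can learn vessel-like
structure — not that it reaches any particular accuracy on real fundus
photographs, which is out of scope here.

## Problem sizes used by the tests

The suite exercises real geometry where it matters (the DRIVE raster
565×584 in padding tests; a 48×48, 128-channel bottleneck for the MKP
channel contract) and small instances elsewhere: oracle checks on ≤ 8×8
features, training tests on 32×32 and 64×64 synthetic images with
`base_channels` 4–8. The end-to-end capacity check trains the full
architecture at `base_channels = 8` on four 64×64 synthetic images for
200 Adam steps and asserts pooled training Dice ≥ 0.90; for this check
DropBlock is disabled (`keep_prob = 1`) since the point is capacity, and
structured dropout exists precisely to impede overfitting. The
`tests/testthat/test-acceptance.R` file groups these system-level
properties; `scripts/acceptance.R` recomputes the same quantities from a
fresh seed and writes them as JSON.

## Known limitations

* CPU-only and written for clarity over speed: convolution is im2col +
  BLAS GEMM per sample; training at the public datasets' full resolution
  is possible but slow.
* No patch extraction or augmentation pipelines; full padded images are
  the training unit.
* The loader reads PNG and TIFF rasters (the synthetic writer emits
  PNG); GIF and PPM mask dialects of the original archives need a prior
  conversion step.
* Single-image batch normalisation statistics are noisy; training with
  `batch_size ≥ 2` is recommended.
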
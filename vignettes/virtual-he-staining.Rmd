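---
title: "Virtual H&E staining of CLE images: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual H&E staining of CLE images: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hestain)
```

## The model

Confocal laser endomicroscopy (CLE) produces grayscale in-vivo micrographs
whose diagnostic reading is hampered by occluding artifacts (motion blur,
red blood cells, background noise) and by the absence of the hematoxylin and
eosin (H&E) color vocabulary pathologists are trained on. `hestain`
transforms a CLE frame toward H&E appearance by pixel-space style transfer:

* **content representation** `C(x)`: the activation array of one deep
  convolutional layer (`Conv4_2` by default) applied to image `x`. Deep
  activations encode the spatial arrangement of structures while being
  insensitive to exact pixel values.
* **style representation** `S(x)`: Gram matrices
  `G^l = F^l (F^l)^T` (channels × channels, summed over all spatial
  positions) at five rectified layers `ReLU1_1 … ReLU5_1`. A Gram matrix is
  invariant to spatial rearrangement, which makes it a texture statistic and
  is exactly why a *single*, un-co-localized H&E micrograph suffices as the
  style source.
* **objective**: with target image `t`, content source `c`, style source
  `s`,

  `L(t) = ½‖C(t) − C(c)‖² + α Σᵢ wᵢ ‖Gⁱ(t) − Gⁱ(s)‖² / (4 Cᵢ² Mᵢ²)`

  where `Cᵢ` and `Mᵢ` are channel and position counts of style layer `i`.
  The per-layer `1/(4C²M²)` normalization is the classical one for
  Gram-based style distances; it makes the style term comparable across
  layers of different width and resolution. A plain-MSE alternative is
  selectable (`style_norm = "mse"` in `total_loss()` /
  `transfer_config()`).
* **optimization**: the network weights stay fixed; only the target image's
  pixels move. L-BFGS-B (`stats::optim`) minimizes `L` with box constraints
  `[0, 1]` on every pixel.

Assumptions worth stating: the backbone's features must be informative
enough that matching Gram statistics transports color/texture while the
deep-layer content term anchors structures; the style image is assumed to be
a typical H&E field, since its global texture statistics become the target
for *every* content image; and content images are treated as
single-channel (grayscale replicated to three equal channels before
extraction).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 100 | weight of the style loss relative to the content loss (dimensionless). Large values prioritize H&E appearance; the content term anchors structure. |
| `layer_weights` | 0.2 × 5 | per-layer style weights `wᵢ`, one per style layer; equal weighting spreads the style constraint over all scales. |
| `n_iterations` | 1600 | L-BFGS iteration budget for production runs. Tests and examples use 10–50 iterations at 24–64 px, which already halve the loss; the full budget is for full-resolution clinical-quality output. |
| `init` | `"content"` | target initialization. Content copy is deterministic and starts the content term at exactly 0; `"noise"` (seeded) is available for experiments. |
| `crop_fraction` | 0.5 | center-crop applied to content images before stylization/evaluation, keeping a manageable number of structures per field. The crop window is centered with any one-pixel slack placed bottom/right. |
| backbone | `build_test_backbone(0)` | five conv blocks (3×3, zero-padded "same", bias-free, rectified, 2× average pooling between blocks; block 4 has a second conv so `Conv4_2` exists), He-scaled Gaussian weights drawn deterministically from the seed. |
| `lbfgs_memory` | 20 | L-BFGS correction pairs retained. |

The pretrained 19-layer production extractor is loaded from a user-supplied
weights file (`load_pretrained_backbone()`); a missing file is a hard,
instructive error — never a silent fallback to random weights — so that
results are always attributable to a known extractor. Its preprocessing is
per-channel standardization with the ImageNet statistics; the test backbone
uses identity preprocessing.

## Numerical choices

* **Pixel constraint.** Box constraints in the optimizer (rather than
  clamping after each step) keep the iterates feasible and make saving
  well-defined; saved PNGs quantize with round-half-away-from-zero, so a
  save/load round trip is within 1/255 per channel.
* **Iteration count.** "Iterations" are optimizer steps (`maxit`), not
  function evaluations. There is no stopping criterion other than the
  budget and the optimizer's own convergence test; a non-finite loss aborts
  with the iteration index and term values.
* **Loss trace.** The optimizer offers no per-step callback, so every
  function evaluation is logged and the reported iterate trace is the
  strictly-improving subsequence (capped at the iteration budget, keeping
  the initial point). It contains every accepted L-BFGS-B step — the line
  search enforces sufficient decrease — so the trace is non-increasing by
  construction, and the first/last entries are the true initial/final
  losses. The full evaluation log is kept on the result object.
* **Style image scale.** Gram statistics are resolution-sensitive, so the
  style image is bilinearly resized to the content image's working
  resolution before its representation is captured. One shared scale is the
  simplest defensible choice.
* **Pooling.** 2× average pooling: it gives smooth gradients to the pixel
  optimization (max pooling's subgradients are sparse and noisier) and is a
  standard choice for Gram-based transfer.
* **Padding.** Zero-padded "same" convolutions. At small test sizes the
  border contribution to Gram statistics is non-negligible, which is why
  translation-covariance checks run on interior crops.
* **Determinism.** With content-copy initialization the whole pipeline is
  deterministic up to floating-point reduction order; tests therefore use
  tolerance-based comparisons for optimization outputs and bit-exact ones
  only where the arithmetic is genuinely identical (color coding, cropping,
  quantized PNG round trips).
* **Feature-map layout.** Feature maps are stored `H' × W' × C` (R's native
  array layout); the Gram computation flattens positions into an `M × C`
  matrix and uses one `crossprod`.

## Rating analysis

Each rating event scores one stylized image on two 0–6 axes: structures
added (unreal = negative, hard-to-notice made visible = positive) and
artifacts removed (critical structures removed = negative), 3 meaning no
impact. Design choices:

* **Neutral means.** A per-image mean of exactly 3 is "neutral", excluded
  from both improvement (mean > 3) and degradation (mean < 3); a third
  status is the only reading that partitions images exactly.
* **Seven categories.** Images are classified by the (added, removed)
  status pair: both improved; both degraded; one axis degraded (the
  degraded axis names the category, regardless of the other axis); one axis
  improved with the other neutral; all-neutral. These categories partition
  the image set, so their counts always sum to the number of images — a
  property the tests assert. Mixed improved/degraded images land in the
  degraded cell of the offending axis, treating any degradation as the
  clinically salient event.
* **Chi-square.** The "more improved than not" contrast is a one-way
  chi-square of the two-bin counts (improved vs. not improved) per axis
  against uniformity — the minimal reading of a one-way test; the function
  accepts any number of bins.
* **Paired t.** Pairing is by rating event (rater × image); two-sided
  p-values; a zero-variance difference vector raises a degenerate-test
  error instead of returning an infinite statistic.
* **Modal combination ties** break toward the larger added score, then the
  larger removed score, and are flagged in the output.

## Synthetic data: what it does and does not show

The generators make the pipeline fully testable without any external data,
and each emits a ground-truth manifest (cell/nucleus parameters, artifact
records, planted categories) so recovery tests have an exact oracle.

* `make_cle_image()` emulates the *structure* of a fluorescein CLE frame:
  dark noisy background, bright elliptical cellular texture, dark disk
  artifacts (red-blood-cell-like) and bright streaks (motion-blur-like)
  covering a target area fraction. Default fixture size is 256 px (64 px in
  tests and the acceptance run, for desk-scale runtimes).
* `make_he_style_image()` emulates the H&E *gamut*: pink-dominant
  low-frequency eosin texture with purple elliptical nuclei; the generator
  asserts mean(red) > mean(green).
* `make_rating_table()` plants, by construction: a per-image category
  (defaults led by 84/100 improved-both; planted counts must sum to the
  image count, so exact per-image category recovery is guaranteed), a modal
  score cell per color group (defaults gray (5,4), green (5,5), red (5,4),
  intact (5,4)), and rater jitter with probability `dispersion` (default
  0.15) that is clamped so it can never move an image out of its planted
  category region; neutral axes use zero-sum jitter so the mean stays
  exactly 3.

What passing tests on these fixtures show: the representations, loss,
optimizer, color codings, and every statistic behave correctly and recover
planted truth exactly. What they do not show: that stylized real CLE images
gain diagnostic quality — that is a human-rater question about real tissue,
outside what synthetic fixtures can establish. The synthetic images contain
no real optical physics, no vendor noise model, and far simpler morphology
than glioma tissue.

## Known limitations

* The random test backbone is a functioning extractor, not a perceptually
  trained one; stylization quality (as opposed to optimization correctness)
  requires the pretrained weights file. Some random weight draws have
  nearly-dead deep layers, leaving an irreducible style-loss floor — the
  packaged default (seed 0) does not.
* Video is handled only as frame-wise batch application; there is no
  temporal consistency term.
* Feed-forward (trained) style networks and cycle-consistent GANs are out
  of scope; this package implements the optimization-based method.

## Problem sizes

Unit tests run at 16–64 px with 3–15 iterations; the acceptance run uses a
64 px pair for 50 iterations (a few seconds on one CPU) and a 4-image
end-to-end batch at 20 iterations. These sizes are chosen so the whole
suite runs in well under a minute of optimization time while still
exercising every layer of the five-block backbone (64 px → 4 px at the
deepest style layer).
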
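---
title: "Classifying multiphoton virtual histology with physics-based domain adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multiphoton virtual histology with physics-based domain adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Label-free multimodal multiphoton microscopy images fresh tissue in four
intrinsic-contrast channels — third-harmonic generation (THG: interfaces,
vesicles, lipid boundaries), NADH and FAD autofluorescence (cellular
metabolism), and second-harmonic generation (SHG: collagen) — producing
"virtual slides" without staining. `mphisto` implements a tile-based
deep-learning pipeline that classifies such slides as cancer or normal, and a
physics-based degradation model that adapts a classifier trained on
high-quality benchtop data to the lower-quality images a portable
intraoperative system produces.

The pipeline is exercised end to end on a bundled synthetic-slide simulator,
because suitable clinical multiphoton cohorts are not publicly deposited.
Everything below — models, parameters, numerical conventions, and what the
synthetic benchmark can and cannot show — is the package's own account of its
choices.

## Pipeline overview

1. **Cohort**: slides carry subject identity; a subject owns several slides
   and exactly one diagnosis. All splitting is *by subject*
   (`split_cohort()`), because tiles within a subject are correlated; a
   slide- or tile-level split would leak subject identity into the test set
   and inflate accuracy.
2. **Adipocyte exclusion** (`train_segmenter()`, `segment()`,
   `keep_tile()`): a U-Net-style encoder–decoder labels lipid pixels; tiles
   with adipocyte fraction at or above 50% are excluded everywhere
   (training, validation, testing). The cut is strict: a tile at exactly
   50% is excluded.
3. **Classifier** (`train_classifier()`): a ResNet-20-style CNN over
   4-channel tiles, trained with class-balanced mini-batches of four
   rejection-sampled crops, binary cross-entropy, and Adam
   (learning rate 5e-4, beta1 0.9, beta2 0.999, epsilon 1e-8). Descriptions of this
   optimiser configuration that pair "weight decay 0.9, momentum 0.999"
   with epsilon 1e-8 are read as Adam's beta1/beta2 — a literal L2 weight
   decay of 0.9 would shrink every weight by 90% per step and is not a
   trainable configuration. Model selection keeps the checkpoint with the
   best validation tile AUC.
4. **Evaluation** (`predict_tiles()`, `slide_score()`, `roc_auc()`):
   per-tile probabilities on a non-overlapping grid form a heatmap; the
   slide score is the arithmetic mean of retained-tile probabilities; AUC is
   the Mann–Whitney statistic with half-credit ties.
5. **Domain adaptation** (`degradation_config()`, `degrade_slide()`,
   `run_ablation()`): training tiles are artificially degraded so the model
   generalises to the degraded domain.
6. **Interpretability** (`extract_features()`, `tsne_canvas()`, `cam()`):
   512-d penultimate features, an exact t-SNE canvas, and class activation
   maps located against the simulator's ground-truth object geometry.

## Architecture

The trunk is the classic 20-layer residual network for small inputs: three
stages of three basic blocks at 16/32/64 filters. Two adaptations were
needed, and both are deliberate:

* **Stem**: the original 20-layer residual design takes 32-px RGB inputs; our tiles are
  256-px and 4-channel. The stem widens the first convolution to 4 input
  channels and reduces resolution early (stride-2 convolution + 2x2
  max-pool) so that 256-px tiles are tractable on one CPU. The residual
  trunk is untouched.
* **Head**: a 1x1 convolutional projection to 512 maps, batch-norm, ReLU,
  global average pooling, then a single linear cancer neuron. The pooled
  512-vector is the penultimate feature. Because global pooling and a 1x1
  convolution commute, this is identical to "GAP then a 512-d linear
  projection", but keeping the projection convolutional makes the head
  exactly the GAP+linear structure class activation mapping requires: the
  CAM is the weighted sum of the 512 final maps under the output neuron's
  weights. The output layer is zero-initialised, so an untrained model
  predicts p = 0.5 and starts at cross-entropy ln 2 exactly.

The network is fully convolutional up to the global pooling, so one trained
model accepts 128-, 256- or 512-px tiles, and equally the 4x-downsampled
tiles of the degraded domain.

Training runs on a small CPU CNN engine built into the package
(im2col convolution over BLAS, batch normalisation, hand-derived backward
passes, Adam). The engine is deliberately minimal; its gradients are tested
against finite differences for every layer type.

## The degradation model

Four physical effects convert a clean benchtop slide into an
intraoperative-like one, composed in the fixed, documented order
**blur → jitter → noise → downsample** (each stage re-clips and re-quantises
to 8 bits, since the pipeline carries 8-bit slides between stages):

* **PSF blur.** The portable system's point-spread function has a FWHM 10%
  larger than the clean system's. The measured PSF is not available, so an
  isotropic Gaussian surrogate is used — the standard diffraction
  approximation. Because Gaussian widths add in quadrature, the incremental
  kernel has FWHM `base * sqrt(1.1^2 - 1)`, yielding a net system FWHM of
  `1.1 * base`. The clean-system FWHM defaults to 2 um at the default
  1 um/px sampling.
* **Vibration jitter.** Floor vibrations in an operating room displace the
  line scanner: each image row is shifted horizontally by a uniform integer
  in ±2 px with probability 0.1, identically in all four channels (they are
  acquired simultaneously); edge pixels are replicated. Whole-frame ("pixel")
  shifting, as distinct from line shifting, is ambiguous as a description;
  it is
  implemented as an optional whole-frame shift (`frame_shift_px`), off by
  default.
* **Ambient light.** Broadband room light adds per-channel white Gaussian
  noise before quantisation (default sigma 25 grey levels per channel).
  No measured sigma is available, so this is configuration, not a constant. The
  default is chosen so the degraded domain is *visibly* degraded: after 4x
  block-mean downsampling a sigma of only a few grey levels would average
  away almost completely, leaving a "degraded" domain statistically
  indistinguishable from the clean one and emptying the domain-adaptation
  experiment of content. Clipping at zero also lifts the dark background,
  reproducing the background haze of ambient light.
* **Downsampling.** 4x4 block means; a 512-px, 1-um/px crop becomes a
  128-px, 4-um/px tile covering the same 512-um field of view. The clean
  pixel size of 1 um/px is fixed by this arithmetic.

The composition order is a convention (the four effects are physically
independent and no canonical order exists); blur-before-noise is physically right (optics act on
signal, ambient light adds at the detector), and downsampling last keeps the
convention that it is applied to both domains at train and test time.

## The synthetic cohort

The simulator generates what the classifier needs to be tested *against*,
with exact ground truth:

| component | channels | geometry | cancer / normal density (per mm^2) |
|---|---|---|---|
| tumor-cell clusters | NADH + FAD | clusters of 6–12 Gaussian blobs (sigma 2–4 px) | 45 / 0 |
| vesicle clusters | THG | 4–10 puncta of radius 1–3 px | 60 / 6 |
| collagen fibers | SHG | smoothed random-walk polylines | 30 / 30 |
| elastin fibers | NADH + FAD (coincident) | shorter, straighter polylines | 10 / 10 |
| ducts / vessels | NADH + FAD | annuli, radius 15–40 px | 1 / 15 |
| adipocytes | THG | disks (radius 15–60 um), speckled interior, bright rim | 6 / 6 |

Densities and sizes are simulator conventions — only qualitative
descriptions of these tissue components exist — chosen so that (a) cancer evidence is object
*shape and configuration*, not raw channel brightness alone: normal ducts
and vessels share the tumor clusters' channels and intensity range, so a
classifier must distinguish rings from blob clusters, mirroring the observed
association of false positives with normal ducts and vessels; (b) a
256-px tile of a cancer slide contains about three tumor-cell clusters and
four vesicle clusters in expectation, so very few cancer tiles are
evidence-free; and (c) both classes share fibers and adipocytes as
background. Background noise is Gaussian (sigma 5) before quantisation.

Each subject draws one log-normal density multiplier (sd 0.15 on the log
scale) applied to all its slides. This induces the intra-subject correlation
that makes subject-level splitting necessary, and it is testable: the
between-subject mean square of slide object counts exceeds the
within-subject mean square.

Seeds: a single master seed; subject and slide streams are derived by stable
string hashing (`derive_seed()`), so cohorts regenerate bit-identically and
slides are independent of cohort composition.

`null_phenotype_pair()` gives both classes the normal phenotype; training on
such a cohort must produce a held-out tile AUC statistically
indistinguishable from 0.5. This null calibration guards against leakage
through any channel other than the planted class difference.

**What the simulator does not emulate**: optical forward physics, mosaicking
seams, histology-realistic texture, intra-tumour heterogeneity, or
pathologist label noise. Passing the synthetic benchmark shows the
*framework* is correct (no leakage, operators exact, adaptation mechanics
work); it does not certify clinical accuracy on real tissue, and clinical
AUC values cannot be reproduced without clinical data.

## Problem sizes and budgets used in tests

The test-suite and acceptance runs use deliberately small problem sizes,
chosen as the smallest that still exercise every claim: the end-to-end
benchmark uses the default cohort of 10 + 10 subjects with 3 slides each at
1024^2 px and a few hundred Adam iterations (the training contract defaults
to a 10,000-iteration budget with validation checkpointing; the synthetic
contrast saturates far earlier); the ablation uses a 6 + 6-subject cohort at
512^2 px with 256-um fields of view. The field of view matters more than
pixel count: with 128-um tiles a downsampled arm sees sub-pixel objects and
mostly evidence-free labels, which measures label noise, not domain
adaptation.

## Numerical conventions and degenerate inputs

* Coordinates are row-major, origin top-left, 0-based tile origins,
  half-open tile windows; boundary tiles that do not fit entirely inside a
  slide are discarded.
* Non-8-bit TIFF sources are linearly min-max rescaled per channel to
  0..255.
* `keep_tile()` is strict (`fraction < 0.5`); the boundary tile at exactly
  one half flips to excluded.
* AUC ties get half credit; a single-class score set is an error, not NaN.
* A slide with zero retained tiles has no slide score; it is flagged and
  excluded from slide-level ROC rather than silently dropped.
* `gaussian_psf()` warns and returns a near-delta kernel when the requested
  FWHM is below half a pixel; `downsample()` crops to the nearest multiple
  with a warning on non-divisible inputs.
* Training aborts with the last stable checkpoint and a warning if the loss
  becomes non-finite.

## Open design points resolved here

* **Validation selection metric**: tile AUC rather than validation loss;
  loss-based selection is more
  sensitive to calibration than to ranking, and all downstream statistics
  are rank-based.
* **Heatmap stride**: non-overlapping tiles by default; overlapping stride
  is exposed as configuration.
* **t-SNE**: exact (O(n^2)) implementation, Euclidean distance, perplexity
  30, PCA pre-reduction to 50 components, early exaggeration 4 for 100
  iterations, learning rate 100, momentum 0.5 -> 0.8 at iteration 250,
  seed-pinned initialisation. No approximate-neighbour t-SNE implementation
  is available in this dependency set, and the tile counts involved (tens to
  hundreds) do not need one.
* **Segmenter**: depth-3 encoder–decoder, base 8 filters, per-pixel binary
  cross-entropy, ~400 Adam steps on 64-px crops with half the crops centred
  on lipid pixels (the positive class is rare by area). Ground-truth masks
  can be supplied in place of predicted masks anywhere downstream, so the
  classifier modules are testable independently of segmentation quality.

## Known limitations

* The CNN engine is CPU-only and double-precision; it is built for
  correctness and small-cohort experiments, not for training at clinical
  scale.
* The degradation model is a surrogate: Gaussian PSF, row-shift jitter and
  additive Gaussian ambient light approximate, but do not measure, a real
  portable system.
* Slide-level aggregation is the plain mean of tile probabilities; no
  calibration or confidence intervals (e.g. DeLong) are provided.
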
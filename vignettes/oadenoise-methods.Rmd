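---
title: "Residual-learning denoising for LED-based optoacoustic tomography: models, assumptions and design choices"
author: "oadenoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-learning denoising for LED-based optoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Optoacoustic (photoacoustic) tomography reconstructs maps of optical
absorption from ultrasound waves excited by pulsed light. LED-based
full-ring systems are affordable and portable, but LEDs deliver sub-mJ
pulse energies, so the reconstructed cross-sections carry two kinds of
degradation: stochastic noise (thermal, electromagnetic interference) and
*structured ring artifacts*. The rings have a simple geometric origin — a
parasitic spike recorded by one detector element at one time sample is
smeared by the reconstruction operator onto the circle of matching
time-of-flight radius centered on that element. Because these artifacts are
more stationary than the anatomy, a network trained to *predict the
artifact component* of an image (residual learning) and subtract it is a
conservative corrector: when the network is unsure it predicts little noise
and the input passes through largely unchanged, which limits hallucination
in low-SNR regions.

`oadenoise` implements this pipeline end to end in R: synthetic generation
of paired clean/artifact images, dataset construction by weighted mixing,
the squeeze-and-excitation U-Net (SE-UNet) and the BatchNorm UNet baseline
with a hand-written training engine, interchangeable loss-evaluation
modules, acquisition-side preprocessing (background subtraction, motion
rejection, frame averaging), and full-reference quality metrics (VIF,
PSNR, SSIM, CNR).

## Synthetic data: what it emulates and what it does not

Real training data for this problem pairs high-SNR reference images from a
solid-state-laser system with measured noise-only acquisitions from the
LED system. Neither can ship with a package, so the `phantoms` module
generates both halves synthetically:

* **Clean anatomy** (`make_phantom()`): a smooth elliptical tissue body
  (default semi-axes 14 × 11 mm in a 40 mm field of view, background
  intensity 0.25) containing non-overlapping bright disks (default 6, radii
  0.6–1.6 mm, intensities 0.6–1) standing in for vessel cross-sections.
  Values are constructed directly in [0, 1].
* **Structured artifacts** (`make_ring_noise()`): boxcar spikes planted at
  seeded random (detector, time) positions in an empty sinogram of a
  64-element, 40 mm-radius circular array, reconstructed by delay-and-sum
  backprojection, plus white noise (σ = 0.04 on the normalized scale) and
  salt-and-pepper corruption (1% of pixels). The spike density and
  amplitude statistics of real interference are uncharacterized; the
  defaults (12 spikes of width 2 at 40 MS/s) were chosen once for visual
  similarity to published ring-artifact images and are config-exposed, not
  calibrated against any measured target.

A training example mixes one clean and one artifact image as
`mixed = w * noise + (1 - w) * signal`, where the noise level `w ∈ [0, 1]`
weights the artifact image; `w = 0.5` gives signal and artifacts equal
weight. Both inputs are in [0, 1], so the convex combination needs no
re-normalization and the algebra is exactly invertible — the basis of the
oracle tests. Training draws `w` uniformly from [0.1, 0.9]; validation and
test use the fixed grid {0.3, 0.5, 0.7}, the regime representative of real
LED acquisitions.

What passing tests on these phantoms shows is that the *method* works:
the residual network can isolate structured-plus-stochastic corruption
that is linearly mixed with smooth anatomy, and the metrics behave as
their definitions demand. What it cannot show is performance on real
tissue: measured artifacts are only approximately additive, their
morphology is richer than backprojected boxcar spikes, and anatomy has
texture the phantoms lack.

## The network and the training target

One code path implements both architectures. Each level applies two 3×3
convolutions, each followed by batch normalization and the configured
activation; 2×2 max pooling descends, transposed convolutions ascend with
skip concatenation, and a final linear 1×1 convolution produces the output
(no activation — noise residuals are signed). With `use_se = TRUE` a
squeeze-and-excitation block (global average pool → channels/r → channels,
sigmoid gate, default r = 8) recalibrates channels after every block and
the activation is Mish, `x·tanh(softplus(x))`; with `use_se = FALSE` and
leaky-ReLU (slope 0.01) the same code is the BatchNorm UNet baseline. The
published architecture's exact depth and widths are not stated anywhere we
could follow; the defaults (depth 4, base 32 channels, doubling per level)
are our own and the desk-scale experiments in the tests use depth 3 /
base 16 at 64×64.

The training target is `w * noise` — the artifact component *as present in
the mixture* — so that a perfect predictor makes the subtraction
`restored_raw = mixed − predicted` equal `(1 − w) * signal` exactly; the
pure-noise target is recovered at `w = 1`. This choice keeps the
subtraction algebra exact and testable end to end.

Training is plain Adam (lr 1e-3, cosine decay, batch 8) with early
stopping on validation loss (patience 10) and best-checkpoint restore,
fully driven by one master seed through `derive_seed()`. The engine is
compiled (im2col + BLAS sgemm in single precision with hand-written
backpropagation); a batch-8 gradient step on the depth-3/base-16 SE-UNet
at 64×64 costs about a quarter second on one CPU core, so the desk-scale
experiments below run in minutes.

## Loss-evaluation modules

The loss compares inferred and actual noise images. Four mathematical
modules (`mse`, `mae`, `1 − ssim`, `1 − ms_ssim`; SSIM window 11, Gaussian
σ 1.5, K1 = 0.01, K2 = 0.03 on data range 1, five-scale MS-SSIM with the
standard weights) and a perceptual module are provided, all with analytic
gradients (verified against central differences in the tests).

The perceptual module measures the L2 distance between feature maps of a
convolutional extractor, averaged over tapped stages. Pretrained weights
are not bundled: the default extractor `random_pyramid` is a fixed
three-stage pyramid (8/16/32 channels, leaky-ReLU 0.1, 2× average pooling
between stages, all stages tapped) with seeded random weights.
VGG19/VGG16-style stage topologies (and a stage-width-matched plain
pyramid standing in for ResNet50) are available and accept a user-supplied
weights file; which intermediate layers the original work tapped is not
stated, so the default taps are the stage-2/3/4 outputs.

Two normalization choices matter and were made deliberately:

* **Per-channel feature normalization.** Each feature channel is
  normalized by the target's channel RMS before the distance. With random
  weights a few channels would otherwise dominate the loss and collapse
  its effective rank; per-channel balancing (as LPIPS-style losses use)
  makes every feature direction contribute.
* **Input standardization by batch-level target statistics.** Both images
  are standardized by the mean/sd of the *target* batch (constants in the
  gradient). Using the prediction's own statistics would make the loss
  blind to the predicted noise's overall amplitude, which the subtraction
  step relies on; using per-image statistics up-weights examples with
  faint noise by the inverse of their sd and destabilizes training. An
  `input_norm = "image"` option retains the per-image variant.

A caveat the experiments make visible: with *random* features the
perceptual loss behaves like a frequency-weighted MSE. It trains the
SE-UNet to a healthy PSNR gain, but it does not reliably reproduce the
advantage over plain MSE (in VIF at high noise) that a *pretrained* VGG19
extractor is reported to deliver — that ordering rests on semantic
features a download-free package cannot ship.

## Preprocessing

`subtract_background()` is exact signed subtraction. `motion_reject()`
computes the Pearson correlation matrix over flattened frames, k-means
clusters its rows (k = 2, deterministic farthest-point seeding, Lloyd
iterations), keeps the cluster with the highest mean intra-cluster
pairwise correlation and averages the kept frames. Two numerical choices:
"second-order k-means" is read as k-means applied to the
correlation-coefficient matrix (the most direct reading; the term is not
defined precisely in the source literature), and near-ties in the
keep-cluster criterion (within 0.01) are broken toward the larger cluster,
because a small cluster of mutually consistent motion frames can be
exactly as internally tight as the clean cluster. Constant frames cannot
enter a correlation and are rejected with a warning. `average_frames()` is
the arithmetic mean; averaging N i.i.d.-noise frames shrinks the noise
standard deviation by √N, which the tests check stochastically.

## Metrics and evaluation conventions

**VIF** follows the printed pixel-domain form: per scale and per
non-overlapping 8×8 block, with reference variance σ²GT, processed
variance σ²P and covariance σGT·P, the gain is `g = σGT·P / max(σ²GT, ε)`
and the distortion variance `σ²v = max(σ²P − g·σGT·P, 0)`; the score is
the ratio of `Σ log10(1 + g²σ²GT/(σ²v + σ²n))` to
`Σ log10(1 + σ²GT/σ²n)` over blocks and scales (4 scales, 5-tap binomial
smoothing before 2× decimation). The visual-noise constant σ²n and the
block/scale settings are unstated in the source; σ²n = 2 (the conventional
choice for this metric family) and the settings above are pinned in
`vif_config()`. Scales too coarse to contain one block are skipped;
partial border blocks are dropped; `vif(x, x) = 1` exactly, and a constant
reference is a defined error. `psnr()` uses `10·log10(range²/MSE)` with an
infinity sentinel; `cnr()` is `(μROI − μbg)/σbg` with the unbiased σ — the
source does not print its CNR formula, so the most common convention is
used and the ROI rectangles are echoed into every report for provenance.

Two scale conventions keep comparisons meaningful. After subtraction the
restored image is dark (it estimates `(1 − w)·signal`), so the package
applies global brightness/contrast restoration (BCR): subtract the 1st
percentile, divide by the 99th−1st span, clip to [0, 1]; constant images
map to zeros. BCR is invariant to positive affine maps, which has two
consequences used throughout the tests: (i) quality scores of a
BCR-restored image must be computed against the *BCR-normalized*
reference — against the raw reference, VIF's gain factor rewards plain
amplification and can exceed 1; (ii) PSNR of the restored image is
computed on the scale-aligned form `restored_raw/(1 − w)` against the
clean signal, because the percentile span of a mostly-dark image is a
noisy normalizer that would dominate the comparison.

`pairwise_variability()` quantifies how repeatable repeated noise-only
acquisitions are (pairwise SSIM/PSNR over a seeded subsample of frame
pairs, with mean, sd and 5th/95th percentiles) — the synthetic analogue of
the background-variability analysis that motivates learning the artifact
distribution rather than subtracting a single background frame.

## Experiment harness and reproducibility

`run_config()` validates a single YAML-expressible configuration (errors
name the offending field, e.g. `trainer.epochs`); `run_experiment()` runs
the stages simulate → build-dataset → train → denoise/evaluate (and
compare-losses), each writing a config snapshot, manifest and outputs
under `output_dir/<stage>/`. A stage re-run under an identical
configuration is detected by content hash and skipped, leaving
byte-identical outputs. Every random draw in the package flows from the
master seed through `derive_seed(master, label)`, a deterministic label
hash, so a full pipeline run is reproducible end to end from
`(config, seed)` with no hidden global RNG state.

The desk-scale problem sizes used by the test suite and the acceptance
script — 64×64 grids, a 64-element ring, 200 training triplets (100 in the
loss-comparison harness), 30 epochs, depth-3/base-16 networks, three
training seeds — are the package's chosen study conditions for a
single-CPU run; the same code paths accept the published 480×480 image
size and deeper configurations unchanged.

## Known limitations

* The linear mixing model ignores reconstruction nonlinearity and
  artifact–anatomy interaction present in measured data.
* The random-weight perceptual extractor preserves the mechanism of
  feature-space losses but not the semantic selectivity of pretrained
  ones; loss-module rankings obtained with it need not match those
  obtained with pretrained extractors.
* No-reference metrics (NIQE, BRISQUE) are reported only through an
  external implementation if the user configures one; their natural-scene
  models are out of scope.
* The delay-and-sum backprojector is noise-synthesis plumbing, not a
  reconstruction method; model-based inversion is deliberately absent.
* Training uses single-precision arithmetic; run-to-run determinism is
  guaranteed on a given platform/BLAS, and histories are reproducible per
  seed, but bitwise identity across different BLAS builds is not promised.
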
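# oadenoise

Residual-learning denoising for LED-based optoacoustic (photoacoustic)
tomography images, in R.

Low-cost optoacoustic scanners that excite tissue with LEDs instead of
solid-state lasers deliver sub-mJ pulse energies, so their reconstructed
cross-sections are degraded by stochastic noise and by *structured ring
artifacts*: a parasitic spike recorded at one detector element and one
time sample backprojects onto a circle of matching time-of-flight radius.
`oadenoise` is for researchers working on such systems who need a fully
reproducible, download-free testbed for the standard remedy: train a
convolutional network to **predict the artifact component** of an image
and subtract it.

## The method

Training pairs are synthesized by pixel-wise weighted mixing of a clean
signal image and a pure artifact image,

```
I_mixed = w * I_noise + (1 - w) * I_signal,        0 <= w <= 1,
```

where the noise level `w` sets the artifact weight (`w = 0.5` means equal
weight). A squeeze-and-excitation U-Net (SE blocks for channel-wise
recalibration, Mish activations, batch normalization; the same code with
SE off and leaky-ReLU is the BatchNorm UNet baseline) is trained to infer
the noise component `w * I_noise` under an interchangeable
loss-evaluation module — perceptual feature-extractor losses or
MSE / MAE / SSIM / MS-SSIM. Denoising is subtraction followed by global
brightness/contrast restoration (BCR):

```
I_restored = BCR(I_mixed - I_hat_noise).
```

Quality is quantified with VIF (visual information fidelity,
`VIF = Σ log10(1 + g²σ²GT/(σ²v+σ²n)) / Σ log10(1 + σ²GT/σ²n)` over scales
and local blocks), PSNR, SSIM and the contrast-to-noise ratio
`CNR = (μ_ROI - μ_bg)/σ_bg`. Acquisition-side preprocessing — background
subtraction, motion rejection by k-means clustering of the frame
correlation matrix, frame averaging — is included, as is a sinogram-level
simulator that manufactures realistic ring artifacts by backprojecting
seeded spikes through a delay-and-sum reconstructor. Everything, including
network training, runs on a plain CPU with no external downloads (the
training engine is compiled Rcpp/RcppArmadillo).

## Worked example

```r
library(oadenoise)

# 1. simulate paired data: vessel phantoms + ring artifacts
geom    <- array_geometry(n_elements = 64, radius = 40)
signals <- lapply(1:40, function(i) make_phantom(phantom_config(grid_size = 64, seed = i)))
noises  <- lapply(1:40, function(i)
  make_ring_noise(geom, spike_noise_config(n_spikes = 12, seed = 100 + i), grid_size = 64))

# 2. build train/val/test triplets (training w ~ U[0.1, 0.9]; test w grid 0.3/0.5/0.7)
ds <- build_dataset(signals, noises, split_spec(30, 4, 6),
                    augmentation_config(factor = 2), seed = 1)

# 3. fit the SE-UNet residual denoiser with the perceptual loss
fit <- fit_denoiser(ds$train, ds$val,
                    network = network_config(depth = 3, base_channels = 16,
                                             activation = "mish", use_se = TRUE),
                    loss    = loss_spec("perceptual"),
                    control = trainer_config(epochs = 10, seed = 1))
print(fit)
#> Residual-noise denoiser (SE-UNet, depth 3, base 16, perceptual loss)
#>   118,917 parameters; trained 10 epoch(s), best at epoch 10
#>   final train loss 0.38653, val loss 0.34643

# 4. denoise a held-out triplet and score it
tp  <- ds$test[[2]]                      # a w = 0.5 test mixture
r   <- predict(fit, tp)                  # noisy, predicted_noise, restored_raw, restored
roi <- auto_roi(tp$signal)
round(c(psnr_mixed    = psnr(tp$signal, tp$mixed),
        psnr_restored = psnr(tp$signal, r$restored_raw / (1 - tp$w)),
        cnr_mixed     = cnr(tp$mixed, roi),
        cnr_restored  = cnr(r$restored, roi)), 2)
#>    psnr_mixed psnr_restored     cnr_mixed  cnr_restored
#>         20.88         23.00          5.00          6.22
```

At this ten-epoch toy scale the restored image already gains ~2 dB PSNR
over the noisy mixture (the restored PSNR is computed on the scale-aligned
subtraction, since a perfect predictor recovers `(1 - w) * signal`), and
the vessel contrast-to-noise ratio rises because the background artifact
energy has been subtracted away. The desk-scale experiments in the test
suite (200 training triplets, 30 epochs, three seeds) reach gains of
5–7 dB.

`run_experiment(run_config("cfg.yaml"), "all")` drives the same pipeline
from a single YAML file with one master seed (stages: simulate,
build-dataset, train, denoise, evaluate, compare-losses; re-runs are
content-hash cache hits), and `inst/cli/oadenoise` exposes the stages and
single-image denoising as a command-line tool.

## Methods documentation

The methods vignette (`vignettes/oadenoise-methods.Rmd`) describes the
models and their assumptions, what the synthetic generator does and does
not emulate, every pinned numerical constant (VIF blocks/scales/σ²n, SSIM
window, BCR percentiles), and the design decisions taken where the
underlying publications leave choices open.
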
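Package: oadenoise
Title: Residual-Learning Denoising for LED-Based Optoacoustic Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, training and evaluation toolkit for suppressing
    structured ring artifacts and stochastic noise in reconstructed
    optoacoustic (photoacoustic) tomography images from low-cost LED-based
    full-ring systems. Provides synthetic phantom and ring-artifact
    generation via sinogram spike backprojection, paired-dataset
    construction by weighted noise mixing, a squeeze-and-excitation U-Net
    trained to predict the noise component (residual learning) with
    interchangeable loss-evaluation modules (perceptual feature-extractor
    losses, MSE, MAE, SSIM, MS-SSIM), motion rejection by correlation
    clustering, and image-quality metrics including visual information
    fidelity (VIF), PSNR, SSIM and contrast-to-noise ratio.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    tiff,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
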
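Package: zspeed
Title: Accelerated CEST MRI by Optimal Frequency-Offset Selection and
    Learned Z-Spectrum Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to shorten chemical exchange saturation transfer (CEST)
    MRI acquisitions by sampling only a sparse, optimised subset of
    saturation-frequency offsets and reconstructing the dense Z-spectrum
    afterwards.  A genetic algorithm searches for the fixed-size offset
    subset whose cubic-spline reconstruction of the dense Z-spectrum has
    minimal root-mean-square error; three small one-dimensional
    convolutional networks (an autoencoder and two U-Nets, implemented
    in-package) then learn to reconstruct dense 101-point Z-spectra from
    the sparse, zero-masked measurements.  Includes a multi-pool Lorentzian
    Z-spectrum and 4D phantom simulator, WASSR-style B0 estimation and
    correction, Gaussian-noise and pixel-subsample augmentation, MTR
    mapping, spectrum and map quality metrics (RMSE, MAE, Pearson r, PSNR,
    SSIM), and acquisition-time accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    RNifti,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
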
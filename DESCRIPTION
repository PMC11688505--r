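Package: gbpcct
Title: Grating-Based Phase-Contrast CT Simulation and Self-Supervised Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates phase-stepping acquisitions of a Talbot-Lau grating
    interferometer CT on synthetic soft-tissue phantoms, retrieves transmission
    and differential-phase sinograms by pixel-wise sinusoid fitting (including
    the patchwise variant), reconstructs attenuation and electron-density
    tomograms by filtered back projection with Ram-Lak and Hilbert filters,
    denoises tomograms with the self-supervised Noise2Inverse scheme using a
    small dilated-convolution network trained on angle-split reconstructions,
    and scores results with reference-based image quality metrics (PSNR, SSIM,
    Canny edge-preservation ratios) and radially averaged noise power spectra.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
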
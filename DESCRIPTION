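Package: cubeprep
Title: Hyperspectral Cube Preprocessing: Segmentation, Double-Plate
    Reflectance Correction and Spatial-Spectral Savitzky-Golay Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Preprocessing chain for line-scan hyperspectral images of
    seeds and similar samples: band selection by spectral angle, PCA-based
    segmentation with mask intersection, additive-noise estimation and
    reflectance inversion from two standard reflectance plates of known
    reflectance, the classical black-and-white normalization baseline,
    one-dimensional Savitzky-Golay spectral smoothing and its
    four-direction two-dimensional spatial extension (TSG) applied per
    band, image-quality metrics (entropy, SNR, clarity, PSNR, SSIM), and a
    config-driven pixel-classification pipeline with accuracy and Cohen's
    kappa evaluation. Includes a synthetic line-scan scene generator with
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jsonlite,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
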
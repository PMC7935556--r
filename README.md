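# cubeprep

Preprocessing for line-scan (pushbroom) hyperspectral images of seeds and
similar lab samples, aimed at pixel-level classification — e.g. separating
healthy from fungus-infected wheat seeds. The package covers the whole
chain from raw sensor digital numbers (DN) to an evaluated classifier, and
ships a synthetic scene generator with full ground truth so everything is
testable without instrument data.

## What it implements

**Radiometric model.** Every DN is modelled as
`f(x,y,λ) = L(y,λ)·ρ(x,y,λ) + ξ(y,λ) + ε`, where `x` is the scan
direction, `y` the detector-row direction, `L` the illumination gain,
`ρ` the true reflectance, `ξ` an additive structured term (dark current)
constant along the scan axis at fixed `(y,λ)`, and `ε` sensor noise.

**Double-plate correction.** Two reflectance plates of known reflectance
R₁, R₂ (2% and 98%) scanned alongside the sample give per-(row, band)
profiles f₁, f₂, from which the additive term has the closed form

    ξ(y,λ) = (R₁·f₂(y,λ) − R₂·f₁(y,λ)) / (R₁ − R₂)

Subtracting ξ and dividing by the noise-subtracted 98%-plate profile
inverts DN to reflectance, cancelling illumination row by row. With zero
sensor noise the recovery is algebraically exact; the classical
black-and-white normalization `R(f − f_min)/(f_ref − f_min)` is provided
as the baseline it outperforms when dark current drifts between
acquisitions.

**Segmentation.** Bands are scored by the spectral angle
`θ = arccos(⟨t, r⟩ / ‖t‖‖r‖)` of each flattened band image against a
reference direction; the top-20 bands are averaged and thresholded (Otsu).
A second mask comes from thresholding a principal-component score image of
the pixel spectra. The final mask is their intersection, which can only
remove false positives.

**SG / TSG filtering.** 1D Savitzky–Golay kernels are derived from the
least-squares projection `B = X(XᵀX)⁻¹Xᵀ` (center row), verified against
per-window polynomial fits. The TSG kernel lays those coefficients along
the horizontal, vertical and diagonal directions of a `(2m+1)²` window
(`b[⌊√(i²+j²)⌋]/4` per direction) and filters every band spatially, by
direct sparse convolution or 2D FFT.

**Quality metrics and evaluation.** Per-band histogram entropy, SNR
(20·log₁₀(μ/σ)), clarity (mean gradient magnitude), PSNR and SSIM; pixel
datasets with a 9:1 train/test split, an RBF-SVM classifier, and accuracy
plus Cohen's kappa `(p_o − p_e)/(1 − p_e)`.

## Worked example

```r
library(cubeprep)

spec  <- sceneSpec(seed = 1L)          # default phantom study conditions
scene <- renderScene(spec)
scene$cube
#> HyperCube: 150 x 80 x 270 (dn)
#>   wavelengths: 400.0 .. 1000.0 nm (270 bands)
#>   value range: [25.58, 3171]

# double-plate correction: 2% and 98% plates flank the scan
corr <- doublePlateCorrect(scene$cube, spec@plates[[1]], spec@plates[[3]])

# recovered reflectance of the 50% target plate, averaged per band
spec50 <- apply(cubeData(corr$reflectance)[69:81, , ], 3, mean)
mean(spec50)                 # 0.50002
mean((spec50 - 0.5)^2)       # 7.69e-08  -- mean square error vs truth

# segmentation against ground truth
seg <- segmentPipeline(corr$reflectance, region = plateFreeMask(spec))
maskIoU(seg$mask, scene$truth@foregroundMask)
#> [1] 1

# comparative pipeline: no filtering vs spectral SG vs spatial TSG
res <- runPipeline(pipelineConfig(seed = 1L))
res$summary
#>   filtering test_accuracy total_accuracy kappa
#> 1      none             1              1     1
#> 2        sg             1              1     1
#> 3       tsg             1              1     1
```

The 50%-plate MSE of ~8e-8 says the additive-noise estimate and
reflectance inversion recover the known calibration spectrum to well under
1e-4 squared reflectance despite a structured noise field at 5% of full
scale. The IoU of 1.0 means the intersected two-branch mask reproduced the
stamped seed pixels exactly at the default noise level. The two-class
phantom is spectrally easy, so all three filtering variants classify it
perfectly; the variants matter on noisier or lower-contrast data (see the
vignette).

A command-line wrapper with `simulate`, `segment`, `correct`, `filter`,
`metrics`, `classify` and `run` subcommands is in
`inst/scripts/cubeprep-cli.R`.

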
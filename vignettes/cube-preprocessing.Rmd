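---
title: "Preprocessing line-scan hyperspectral cubes: segmentation, double-plate correction and TSG filtering"
author: "cubeprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing line-scan hyperspectral cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A line-scan (pushbroom) imaging spectrometer records one field-of-view line
per exposure while the sample moves underneath. `cubeprep` stores such data
as a `HyperCube` in canonical `(x, y, band)` order: `x` is the scan
direction, `y` the detector-row (line) direction, and the third axis the
spectral band with a strictly increasing wavelength grid.

Every raw digital number (DN) is modelled as

$$ f(x, y, \lambda) \;=\; L(y, \lambda)\,\rho(x, y, \lambda) \;+\;
   \xi(y, \lambda) \;+\; \varepsilon $$

with `L` the illumination-times-gain field of the line sensor, `rho` the
true reflectance, `xi` an additive structured term (dark current and
related detector-row effects) and `eps` i.i.d. sensor noise. Two
assumptions carry the whole correction theory:

1. at a fixed (detector row, band) the additive term is the same at every
   scan position, because every scan position is recorded by the same
   physical detector element;
2. the illumination gain does not depend on the scan position, so it
   cancels between two surfaces measured at the same (row, band).

Both are properties of the acquisition geometry, not of the sample.

# Double-plate correction

Two calibrated reflectance plates (2% and 98% here) cross the full
field-of-view line at the two ends of the scan, so every detector row sees
both plates in every acquisition. Averaging each plate over its scan
columns gives per-(row, band) profiles $f_1, f_2$, and the model above
yields a closed-form additive-noise estimate

$$ \hat\xi(y, \lambda) = \frac{R_1 f_2(y,\lambda) - R_2 f_1(y,\lambda)}
   {R_1 - R_2}, $$

which is exact (not asymptotic) whenever the profile means equal their
model values. Subtracting $\hat\xi$ and dividing by the noise-subtracted
98%-plate profile, scaled by its known reflectance, inverts DN to
reflectance row by row. `doublePlateCorrect()` chains these steps:

```{r}
library(cubeprep)
spec <- sceneSpec(seed = 1L)
scene <- renderScene(spec)
corr <- doublePlateCorrect(scene$cube, spec@plates[[1]], spec@plates[[3]])
```

With the sensor-noise term switched off the recovery is an algebraic
identity — the test suite asserts reconstruction of the true reflectance
cube to below 1e-12 for arbitrary noise fields and illumination. The
classical black-and-white normalization
(`blackWhiteCorrect()`, $ref = R\,(f - f_{min})/(f_{ref} - f_{min})$) is
kept as the baseline; it relies on a dark frame recorded at a different
time, so when the additive term drifts between acquisitions its error grows
while the double-plate estimate, recorded simultaneously with the sample,
does not.

Numerical guards: the two plate reflectances must differ by at least 1e-6;
calibration DN at or below a configurable floor (default 1e-9) raises an
error instead of producing infinities; plate reflectance may be a scalar or
a per-band curve. A plate that does not span all detector rows cannot
measure the rows it does not cover; profiles are then filled by nearest
neighbor along `y` with a warning.

Reflectance cubes are never clipped to [0, 1] automatically — correction
legitimately produces slightly out-of-range values, and silent clipping
would bias downstream statistics.

# Segmentation

Seeds on a bright stage are segmented by intersecting two masks.

*Branch 1 (spectral angle).* Each band image, flattened to a vector, is
scored by its angle to a reference direction,
$\theta = \arccos(\langle t, r\rangle / \|t\|\|r\|)$. The default reference
is the all-ones direction, making the angle a scale-invariant measure of
spatial heterogeneity: a uniform band has angle 0, a structure-rich band a
large angle. (The literal "first basis axis" reading and a mean-image
reference remain selectable; the ones reference is the degenerate-safe
interpretation of comparing an image against a featureless one.) The
`k = 20` highest-angle bands are averaged — averaging suppresses
uncorrelated noise — and the mean image is thresholded (Otsu by default,
dark foreground).

*Branch 2 (PCA).* Pixel spectra are decomposed by PCA (pixels are
observations, bands variables, centering by the mean spectrum, no
scaling). Eigenvector signs are arbitrary, so each component is oriented to
give its score image non-negative skewness — a pure reproducibility
convention. One component image is thresholded to give the second mask.
Which component carries the objects is data-dependent and, in the original
procedure, was chosen by inspecting the component images. The default
`pcIndex = "auto"` mechanizes that inspection: among the first six
components it picks the one whose thresholded mask agrees best (IoU) with
branch 1. On corrected data, where illumination is already cancelled, the
foreground contrast typically lands in PC1; on uncorrected data with strong
global brightness variation it often lands in PC2. An explicit integer
reproduces a manual choice. The PC-branch threshold polarity defaults to
`"minority"`: under the skewness convention the side of the threshold is
not meaningful, while the objects of interest are the minority of pixels.

The final mask is the logical AND of the branches, which can only shrink
the foreground — false positives must survive both views to survive at
all. When the scene contains known equipment footprints (the reflectance
plates), pass `region = plateFreeMask(spec)` so thresholds and the PCA are
estimated from the stage area only; pixels outside the region are
background by definition.

An entropy-based single-band selection (`selectBandByEntropy()` +
`thresholdSegment()`) is included as the baseline that the two-branch
procedure improves on.

# Savitzky–Golay and TSG filtering

`sgProjectionMatrix(m, n)` builds the least-squares projection
$B = X(X^TX)^{-1}X^T$ onto polynomials of order `n` over window positions
$-m..m$; `sgKernel(m, n)` takes its center row. The design matrix is
evaluated on a rescaled abscissa (`x/m`) and factored by QR — the
projection is invariant to the rescaling, which keeps high orders
well-conditioned; `n = 2m` short-circuits to the exact identity, since the
full-order fit interpolates. Tests verify every kernel up to `m = 10`
against an independent per-window polynomial fit and against the classical
published weight tables.

The TSG kernel extends the 1D coefficients to a `(2m+1)^2` spatial window
along four directions (horizontal, vertical, both diagonals): the center
gets `b[0]`, an offset `(i, j)` on exactly one direction gets
`b[floor(sqrt(i^2 + j^2))]/4`, everything else 0. Two constructions are
deliberately pinned down because the four-direction description alone
leaves them open:

* diagonal offsets whose distance index exceeds `m` (e.g. `(3, 3)` with
  `floor(sqrt(18)) = 4`) have no 1D coefficient; they get weight 0,
  keeping the support inside the declared window;
* as a consequence the raw grid can sum to slightly less than one
  (226/231 at `m = 3, n = 4`), i.e. a DC gain below unity that would darken
  every filtered band by ~2%. The default `renormalize = TRUE` divides by
  the grid sum; the raw construction stays available and is recorded in the
  kernel object.

`tsgFilter()` convolves every band with this kernel, via a direct sparse
sum over the four directions or a 2D FFT on a padded image; both routes
agree to 1e-8 and are tested against each other. Boundary handling is
mirror reflection by default (zero padding is kept for the convolution
identity and for inspection). Spectral-domain smoothing
(`sgFilterSpectra()`) supports mirror padding or evaluating the edge
windows' own least-squares fits (the off-center rows of `B`).

A practical caveat the tests document: on scenes whose error budget is
dominated by sharp reflectance steps rather than noise, spatial smoothing
lowers flat-region noise variance but *raises* whole-frame RMSE against the
true reflectance, because the kernel smears the steps. The filter helps
exactly when noise dominates; quality metrics below make that visible.

# Quality metrics

The five metrics are implemented under fixed, stated conventions, since
several coexist in the literature: entropy is Shannon entropy (bits) of a
256-bin histogram over the image's own range; SNR is
$20\log_{10}(\mu/\sigma)$ of the pixel values; clarity is the mean
central-difference gradient magnitude; PSNR is
$10\log_{10}(peak^2/MSE)$ with the reference maximum as default peak
(identical images report `Inf`); SSIM uses the standard
luminance–contrast–structure form with an 11×11 Gaussian window
(σ = 1.5) and stabilizers $(0.01\,peak)^2$, $(0.03\,peak)^2$. The peak for
SSIM defaults to the maximum over both images, which makes the measure
symmetric in its arguments. `qualityReport()` assembles per-band rows plus
arithmetic band averages and serializes to a fixed-column TSV.

# The phantom generator

`sceneSpec()`/`renderScene()` emulate the acquisition this package is
written for, so that every stage is testable with zero external data:

* a 270-band, 400–1000 nm sensor with a 12-bit full scale of 4095 DN —
  the band count and range of the motivating instrument;
* illumination with a mild parabolic fall-off (12% at the extreme detector
  rows), flat across bands: the simplest shape with the right physics
  (line sensors are brightest mid-line);
* a structured additive field built from four random low-frequency
  sinusoids over (row, band), strictly constant along the scan axis,
  positive, with amplitude 5% of full scale — mimicking temperature-driven
  dark-current structure;
* i.i.d. Gaussian sensor noise at 0.5% of full scale;
* a bright flat stage (reflectance 0.90), 2%/50%/98% plates as full-height
  bands at scan start / mid-scan / scan end, and 12 elliptical seed blobs
  of two spectral classes ("healthy": dark visible region with a logistic
  red edge; "infected": brighter, flatter — peak separation at least 0.1
  reflectance in the 600–750 nm window), each with a radial brightness
  gradient emulating the 3D shading that defeats plain thresholding.

No quantitative noise magnitudes were available to copy, so the amplitudes
above were fixed once at values a practitioner would call realistic for a
temperature-drifting line sensor, and all tests run against them. All
randomness flows from one integer seed; rendering restores the session RNG
state. Ground truth (`SceneTruth`) exposes the true reflectance cube, the
noise field, the illumination field, the blob mask/labels and a dark-frame
realization, so tests can do parameter recovery rather than golden-file
comparison.

What the phantom does *not* emulate — and hence what passing tests cannot
certify about real data: mixed pixels at seed boundaries, pushbroom
geometric distortion, wavelength-dependent illumination, detector
nonlinearity, and any biological variability within a seed class beyond a
single smooth spectrum per class.

# Classification pipeline

`buildPixelDataset()` draws, per cube and class, a fixed number of
train/test pixels (9:1 by default) from labelled foreground without
replacement; features are raw spectra or projections onto the first six
principal components fitted on the training split only. The classifier is
a radial-kernel SVM (`e1071::svm`, cost 1, features scaled internally) —
a deliberately off-the-shelf choice, since the classifier is not the
contribution. `evaluateClassifier()` reports the test-split confusion
matrix, test accuracy, "total" accuracy — interpreted as accuracy over the
pooled train+test predictions, the two-column reporting style of the
motivating protocol — and Cohen's kappa
$(p_o - p_e)/(1 - p_e)$ from the test confusion matrix.

`runPipeline()` chains simulate → double-plate correct → segment → filter
→ dataset → SVM → evaluate, runs the filtering stage in three variants
(none / spectral SG with `m = 7, n = 3` / spatial TSG with `m = 3, n = 4`,
the conventional parameter choices for each) on byte-identical upstream
inputs, and writes every artifact with a JSON manifest of parameters,
seeds and file hashes; identical configs produce identical hashes.

```{r}
res <- runPipeline(pipelineConfig(seed = 20260101L), outDir = "artifacts")
res$summary
```

# Sizes, conventions, limitations

* All index ranges in the package are 1-based and inclusive
  (`c(first, last)`), the R convention.
* The default phantom is 150 × 80 pixels × 270 bands; the test suite uses
  a 100 × 40 × 60 reduction for per-module tests and the full default for
  the end-to-end checks, with 180 + 20 samples per class for the
  classification stage — tenfold reductions of the motivating protocol's
  4500/500 that keep every distributional property intact.
* Entropy conventions: histogram entropy of an 8-bit-style binning is
  bounded by 8 bits; published band-averaged entropies far above that
  scale must come from an unstated definition, so only directional
  comparisons (filtered vs unfiltered) are meaningful here, not absolute
  values.
* The ENVI reader supports interleaves bsq/bil/bip, little-endian files,
  and preserves unknown header keys verbatim; the array container is a
  one-line JSON header plus little-endian float64 payload and round-trips
  bit-for-bit. Neither supports georeferencing, compression or out-of-core
  streaming.
* The SVM stage offers no hyperparameter search by design; accuracy
  comparisons between filtering variants are made at fixed classifier
  settings so that only the preprocessing differs.
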
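#' @import methods
NULL

#' HyperCube: a hyperspectral data cube
#'
#' Container for a line-scan hyperspectral cube stored in canonical
#' \code{(x, y, band)} axis order, where \code{x} is the scan direction (the
#' axis along which the stage moves and along which detector dark-current
#' noise is constant at fixed \code{(y, band)}) and \code{y} is the
#' field-of-view line (detector row) direction.
#'
#' Values are either raw sensor digital numbers (\code{valueKind = "dn"}) or
#' reflectance fractions (\code{valueKind = "reflectance"}). Reflectance
#' values are not clipped to \eqn{[0, 1]} on construction or I/O: radiometric
#' correction can legitimately produce slightly out-of-range values, so
#' clipping is left as an explicit operation by the caller.
#'
#' @slot data numeric 3D array, dimensions \code{(nx, ny, nbands)}.
#' @slot wavelengths numeric vector of per-band wavelengths in nm, strictly
#'   increasing, length \code{nbands}.
#' @slot valueKind \code{"dn"} or \code{"reflectance"}.
#' @slot metadata free-form named list (source interleave, dtype, provenance).
#'
#' @seealso [HyperCube()] for the user constructor, [readCube()],
#'   [writeCube()], [cropCube()].
#' @exportClass HyperCube
setClass("HyperCube",
  representation(
    data = "array",
    wavelengths = "numeric",
    valueKind = "character",
    metadata = "list"
  )
)

setValidity("HyperCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("'data' must be a 3D array (x, y, band)")
  if (any(d < 1L))
    return("all three extents must be >= 1")
  if (length(object@wavelengths) != d[3L])
    return(sprintf("length(wavelengths) [%d] != band count [%d]",
                   length(object@wavelengths), d[3L]))
  if (any(!is.finite(object@wavelengths)))
    return("wavelengths must be finite")
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (length(object@valueKind) != 1L ||
      !object@valueKind %in% c("dn", "reflectance"))
    return("valueKind must be one of 'dn', 'reflectance'")
  if (object@valueKind == "reflectance" && any(!is.finite(object@data)))
    return("reflectance cube contains non-finite values")
  TRUE
})

#' BinaryMask: a 2D foreground mask aligned to a cube's spatial grid
#'
#' @slot grid logical matrix indexed \code{(x, y)}; \code{TRUE} marks
#'   foreground pixels. Shape compatibility with a target [HyperCube-class]
#'   is checked by every operation that combines the two.
#'
#' @exportClass BinaryMask
setClass("BinaryMask", representation(grid = "matrix"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@grid))
    return("'grid' must be a logical matrix")
  if (any(is.na(object@grid)))
    return("'grid' must not contain NA")
  TRUE
})

#' PlateRegion: footprint and reflectance of a standard reflectance plate
#'
#' A calibrated Lambertian reference panel of known reflectance occupying a
#' rectangular footprint in the cube's spatial grid. Reflectance may be a
#' scalar (spectrally flat plate) or a per-band curve.
#'
#' @slot reflectance numeric; either length 1 or one value per band, all in
#'   \eqn{(0, 1]}.
#' @slot xInterval,yInterval integer length-2 vectors \code{c(first, last)},
#'   1-based inclusive, giving the plate's pixel footprint.
#'
#' @exportClass PlateRegion
setClass("PlateRegion",
  representation(
    reflectance = "numeric",
    xInterval = "integer",
    yInterval = "integer"
  )
)

setValidity("PlateRegion", function(object) {
  if (any(!is.finite(object@reflectance)) ||
      any(object@reflectance <= 0) || any(object@reflectance > 1))
    return("reflectance values must lie in (0, 1]")
  for (nm in c("xInterval", "yInterval")) {
    iv <- slot(object, nm)
    if (length(iv) != 2L || any(is.na(iv)) || iv[1L] < 1L || iv[2L] < iv[1L])
      return(sprintf("%s must be c(first, last) with 1 <= first <= last", nm))
  }
  TRUE
})

#' PlateProfile: per-(y, band) mean DN of a reflectance plate
#'
#' The column-mean signal of a plate, averaged over the plate's x (scan)
#' columns, one value for every (detector row, band) pair of the parent cube.
#' Rows outside the plate's y footprint are filled by nearest neighbor.
#'
#' @slot values numeric matrix \code{(ny, nbands)}.
#' @slot region the source [PlateRegion-class].
#'
#' @exportClass PlateProfile
setClass("PlateProfile",
  representation(values = "matrix", region = "PlateRegion"))

#' NoiseField: per-(y, band) additive noise estimate
#'
#' The additive dark-current-like noise term, constant along the scan axis at
#' fixed (detector row, band), as estimated from two calibration plates.
#'
#' @slot values numeric matrix \code{(ny, nbands)}, finite everywhere.
#'
#' @exportClass NoiseField
setClass("NoiseField", representation(values = "matrix"))

setValidity("NoiseField", function(object) {
  if (any(!is.finite(object@values)))
    return("noise field contains non-finite values")
  TRUE
})

#' SGKernel1D: Savitzky-Golay smoothing coefficients
#'
#' Symmetric window of \code{2m + 1} least-squares polynomial smoothing
#' weights of order \code{n}.
#'
#' @slot m integer half-window (window length \code{2m + 1}).
#' @slot n integer polynomial order, \code{n < 2m + 1}.
#' @slot coefficients numeric vector of length \code{2m + 1}; symmetric and
#'   summing to 1.
#'
#' @exportClass SGKernel1D
setClass("SGKernel1D",
  representation(m = "integer", n = "integer", coefficients = "numeric"))

setValidity("SGKernel1D", function(object) {
  if (object@n >= 2L * object@m + 1L)
    return("polynomial order n must satisfy n < 2m + 1")
  cf <- object@coefficients
  if (length(cf) != 2L * object@m + 1L)
    return("coefficients must have length 2m + 1")
  if (max(abs(cf - rev(cf))) > 1e-12)
    return("coefficients must be symmetric")
  if (abs(sum(cf) - 1) > 1e-12)
    return("coefficients must sum to 1")
  TRUE
})

#' TSGKernel2D: four-direction 2D Savitzky-Golay kernel
#'
#' The \code{(2m+1) x (2m+1)} spatial kernel built by laying the 1D
#' Savitzky-Golay coefficients along the horizontal, vertical and both
#' diagonal directions, indexed by offsets \eqn{(i, j) \in [-m, m]^2}.
#'
#' @slot m,n integer kernel parameters as in [SGKernel1D-class].
#' @slot grid numeric \code{(2m+1) x (2m+1)} weight matrix.
#' @slot renormalized logical; \code{TRUE} if the grid was divided by its sum
#'   so the kernel has unit DC gain.
#'
#' @exportClass TSGKernel2D
setClass("TSGKernel2D",
  representation(m = "integer", n = "integer", grid = "matrix",
                 renormalized = "logical"))

setValidity("TSGKernel2D", function(object) {
  k <- 2L * object@m + 1L
  if (!all(dim(object@grid) == c(k, k)))
    return("grid must be (2m+1) x (2m+1)")
  g <- object@grid
  if (max(abs(g - t(g))) > 1e-12 ||
      max(abs(g - g[k:1, k:1])) > 1e-12 ||
      max(abs(g - g[, k:1][k:1, ])) > 1e-12)
    return("grid must have 8-fold dihedral symmetry")
  TRUE
})

#' PCAResult: principal-component decomposition of a cube's pixel spectra
#'
#' Pixels are observations and bands are variables; data are centered by the
#' mean spectrum before decomposition. Component sign is fixed so that each
#' component score image has non-negative skewness (eigenvector sign is
#' arbitrary; a convention is required for reproducibility).
#'
#' @slot componentImages numeric 3D array \code{(nx, ny, k)} of score images.
#' @slot explainedRatio per-component fraction of total spectral variance;
#'   non-increasing, sums to 1 when all components are kept.
#' @slot meanSpectrum per-band mean used for centering.
#' @slot rotation \code{(nbands x k)} loading matrix (columns are unit
#'   eigenvectors after the sign convention).
#'
#' @exportClass PCAResult
setClass("PCAResult",
  representation(componentImages = "array", explainedRatio = "numeric",
                 meanSpectrum = "numeric", rotation = "matrix"))

#' SceneSpec: parameters of the synthetic line-scan scene
#'
#' Describes a phantom scene for the generator: a bright stage background,
#' darker elliptical seed blobs of two spectral classes, standard reflectance
#' plates crossing the field of view at the scan ends, a per-(y, band)
#' illumination gain field, a structured additive noise field constant along
#' the scan axis, and i.i.d. sensor noise. Build with [sceneSpec()].
#'
#' @slot nx,ny,nbands integer extents (scan, line, spectral).
#' @slot wavelengths per-band wavelength grid in nm.
#' @slot nBlobs number of seed blobs.
#' @slot blobRadiusRange integer c(min, max) semi-axis range in pixels.
#' @slot blobSpacing minimum center-to-center spacing in pixels.
#' @slot infectedFraction fraction of blobs labelled infected.
#' @slot plates list of [PlateRegion-class] objects (background plates).
#' @slot illumPeak illumination gain at the center detector row (DN per unit
#'   reflectance).
#' @slot illumFalloff fractional parabolic gain loss at the extreme rows.
#' @slot noiseAmplitude amplitude of the structured additive field, in DN.
#' @slot sensorSigma std of the i.i.d. zero-mean sensor noise, in DN.
#' @slot fullScale sensor full-scale DN (12-bit default, 4095).
#' @slot seed integer RNG seed; all randomness flows from it.
#'
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    nx = "integer", ny = "integer", nbands = "integer",
    wavelengths = "numeric",
    nBlobs = "integer", blobRadiusRange = "integer", blobSpacing = "numeric",
    infectedFraction = "numeric",
    plates = "list",
    illumPeak = "numeric", illumFalloff = "numeric",
    noiseAmplitude = "numeric", sensorSigma = "numeric",
    fullScale = "numeric",
    seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  if (length(object@wavelengths) != object@nbands)
    return("wavelengths length must equal nbands")
  if (any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  for (p in object@plates) {
    if (!is(p, "PlateRegion")) return("plates must be PlateRegion objects")
    if (p@xInterval[2L] > object@nx || p@yInterval[2L] > object@ny)
      return("plate footprint outside scene bounds")
  }
  if (object@infectedFraction < 0 || object@infectedFraction > 1)
    return("infectedFraction must lie in [0, 1]")
  if (object@noiseAmplitude < 0 || object@sensorSigma < 0)
    return("noise amplitudes must be non-negative")
  TRUE
})

#' SceneTruth: ground truth of a rendered phantom scene
#'
#' @slot reflectanceCube true reflectance [HyperCube-class] \eqn{\rho}.
#' @slot noiseField true structured noise \eqn{\xi(y, \lambda)} matrix
#'   \code{(ny, nbands)}.
#' @slot foregroundMask [BinaryMask-class], \code{TRUE} exactly where a seed
#'   blob was stamped.
#' @slot labels data.frame with one row per blob: \code{blob}, \code{class}
#'   (\code{healthy}/\code{infected}), center coordinates and semi-axes.
#' @slot labelMap integer matrix \code{(nx, ny)}: 0 background, otherwise the
#'   blob id.
#' @slot darkFrame realization of \eqn{\xi} + sensor noise with the
#'   illumination term zeroed, matrix \code{(ny, nbands)}.
#' @slot illumination the illumination gain field \eqn{L(y, \lambda)},
#'   matrix \code{(ny, nbands)}.
#'
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(
    reflectanceCube = "HyperCube",
    noiseField = "matrix",
    foregroundMask = "BinaryMask",
    labels = "data.frame",
    labelMap = "matrix",
    darkFrame = "matrix",
    illumination = "matrix"
  )
)

#' QualityReport: per-band image-quality metrics and their band averages
#'
#' @slot perBand data.frame with one row per band: \code{band},
#'   \code{wavelength}, \code{entropy} (bits), \code{snr_db},
#'   \code{clarity}, and, when a comparison cube was supplied,
#'   \code{psnr_db} and \code{ssim}.
#' @slot averages named numeric vector of arithmetic band means.
#'
#' @exportClass QualityReport
setClass("QualityReport",
  representation(perBand = "data.frame", averages = "numeric"))

#' PixelDataset: sampled pixel spectra with labels and a train/test split
#'
#' @slot features numeric matrix, one row per sampled pixel (raw spectrum or
#'   PCA scores).
#' @slot labels factor of class labels.
#' @slot split factor with levels \code{train}/\code{test}.
#' @slot provenance data.frame with \code{cube}, \code{x}, \code{y} per
#'   sample; no pixel appears in both splits.
#' @slot featureMode \code{"raw"} or \code{"pca"}.
#' @slot seed RNG seed used for sampling.
#'
#' @exportClass PixelDataset
setClass("PixelDataset",
  representation(features = "matrix", labels = "factor", split = "factor",
                 provenance = "data.frame", featureMode = "character",
                 seed = "integer"))

setValidity("PixelDataset", function(object) {
  n <- nrow(object@features)
  if (length(object@labels) != n || length(object@split) != n ||
      nrow(object@provenance) != n)
    return("features, labels, split and provenance must agree in length")
  key <- paste(object@provenance$cube, object@provenance$x,
               object@provenance$y)
  if (anyDuplicated(key))
    return("a (cube, x, y) pixel appears more than once across the splits")
  TRUE
})

#' EvalResult: classification evaluation statistics
#'
#' @slot confusion class-by-class count matrix on the test split (rows:
#'   truth, columns: prediction).
#' @slot testAccuracy fraction correct on the test split.
#' @slot totalAccuracy fraction correct over pooled train + test predictions.
#' @slot kappa Cohen's kappa on the test confusion matrix.
#'
#' @exportClass EvalResult
setClass("EvalResult",
  representation(confusion = "matrix", testAccuracy = "numeric",
                 totalAccuracy = "numeric", kappa = "numeric"))

setValidity("EvalResult", function(object) {
  if (any(object@confusion < 0))
    return("confusion counts must be non-negative")
  for (a in c(object@testAccuracy, object@totalAccuracy))
    if (a < 0 || a > 1) return("accuracies must lie in [0, 1]")
  if (object@kappa < -1 || object@kappa > 1)
    return("kappa must lie in [-1, 1]")
  TRUE
})
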
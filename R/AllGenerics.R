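# Generics and accessors for the core classes. Slot access from user code
# should always go through these.

#' @rdname HyperCube-class
#' @param object,x a \code{HyperCube}
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname HyperCube-class
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname HyperCube-class
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname HyperCube-class
#' @export
setGeneric("cubeMetadata", function(x) standardGeneric("cubeMetadata"))

#' @rdname BinaryMask-class
#' @param x a \code{BinaryMask}
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @export
#' @rdname HyperCube-class
setMethod("cubeData", "HyperCube", function(x) x@data)

#' @export
#' @rdname HyperCube-class
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

#' @export
#' @rdname HyperCube-class
setMethod("valueKind", "HyperCube", function(x) x@valueKind)

#' @export
#' @rdname HyperCube-class
setMethod("cubeMetadata", "HyperCube", function(x) x@metadata)

#' @export
#' @rdname BinaryMask-class
setMethod("maskGrid", "BinaryMask", function(x) x@grid)

#' @export
#' @rdname HyperCube-class
setMethod("dim", "HyperCube", function(x) dim(x@data))

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  wl <- object@wavelengths
  cat(sprintf("HyperCube: %d x %d x %d (%s)\n", d[1], d[2], d[3],
              object@valueKind))
  cat(sprintf("  wavelengths: %.1f .. %.1f nm (%d bands)\n",
              wl[1], wl[length(wl)], length(wl)))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@grid)
  cat(sprintf("BinaryMask: %d x %d, %d foreground pixels (%.1f%%)\n",
              d[1], d[2], sum(object@grid),
              100 * mean(object@grid)))
})

setMethod("show", "SGKernel1D", function(object) {
  cat(sprintf("SGKernel1D: m = %d, n = %d (window %d)\n",
              object@m, object@n, 2L * object@m + 1L))
  cat("  coefficients:", signif(object@coefficients, 6), "\n")
})

setMethod("show", "TSGKernel2D", function(object) {
  cat(sprintf("TSGKernel2D: m = %d, n = %d, %s (grid sum %.6f)\n",
              object@m, object@n,
              if (object@renormalized) "renormalized" else "unnormalized",
              sum(object@grid)))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d x %d, %d blobs, %d plates, seed %d\n",
              object@nx, object@ny, object@nbands, object@nBlobs,
              length(object@plates), object@seed))
})

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport band averages:\n")
  print(round(object@averages, 4))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: test accuracy %.4f, total accuracy %.4f, kappa %.4f\n",
    object@testAccuracy, object@totalAccuracy, object@kappa))
  print(object@confusion)
})

setMethod("show", "PixelDataset", function(object) {
  cat(sprintf("PixelDataset: %d samples (%d train / %d test), %d features, mode '%s'\n",
              nrow(object@features), sum(object@split == "train"),
              sum(object@split == "test"), ncol(object@features),
              object@featureMode))
})
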
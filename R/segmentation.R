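# coerce a region argument (BinaryMask or logical matrix) to a logical grid
.regionGrid <- function(region, dims) {
  g <- if (is(region, "BinaryMask")) region@grid else as.matrix(region)
  mode(g) <- "logical"
  if (!all(dim(g) == dims))
    stop("region shape does not match the image", call. = FALSE)
  g
}

# Segmentation by spectral angle + PCA with mask intersection.
#
# Branch 1 scores every band by the spectral angle between the flattened
# band image and a reference direction, averages the top-k most "angled"
# (structure-rich) bands and thresholds the mean image. Branch 2 thresholds
# a principal-component score image. The final mask is the intersection of
# the two branches.

#' Spectral angle of every band image against a reference direction
#'
#' For each band the flattened band image \eqn{t} is compared with a
#' reference vector \eqn{r} through
#' \eqn{\theta = \arccos(\langle t, r\rangle / (\|t\| \|r\|))}.
#' The default reference is the all-ones direction of pixel space, which
#' makes the angle a scale-invariant measure of spatial heterogeneity
#' (a uniform image has angle 0). \code{"mean"} compares against the
#' across-band mean image, \code{"axis"} against the first pixel basis
#' vector (the literal x-axis reading).
#'
#' @param cube a [HyperCube-class]
#' @param reference \code{"ones"}, \code{"mean"} or \code{"axis"}.
#' @param region optional [BinaryMask-class] (or logical matrix) restricting
#'   the comparison to a set of pixels, e.g. the stage area outside known
#'   equipment footprints.
#' @return data.frame with columns \code{band}, \code{wavelength},
#'   \code{angle} (radians). An all-zero band has no direction; its angle is
#'   defined as \eqn{\pi/2} with a warning.
#' @export
bandSpectralAngle <- function(cube, reference = c("ones", "mean", "axis"),
                              region = NULL) {
  stopifnot(is(cube, "HyperCube"))
  reference <- match.arg(reference)
  d <- dim(cube@data)
  X <- matrix(cube@data, d[1L] * d[2L], d[3L])
  if (!is.null(region)) {
    keep <- as.vector(.regionGrid(region, d[1:2]))
    X <- X[keep, , drop = FALSE]
  }
  npx <- nrow(X)
  r <- switch(reference,
    ones = rep(1, npx),
    mean = rowMeans(X),
    axis = c(1, rep(0, npx - 1L)))
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("reference vector is zero", call. = FALSE)
  tn <- sqrt(colSums(X^2))
  zero <- tn == 0
  if (any(zero))
    warning(sum(zero), " all-zero band(s); angle set to pi/2",
            call. = FALSE)
  cosv <- colSums(X * r) / (tn * rn)
  ang <- acos(pmin(1, pmax(-1, cosv)))
  ang[zero] <- pi / 2
  data.frame(band = seq_len(d[3L]), wavelength = cube@wavelengths,
             angle = ang)
}

#' Indices of the k largest band scores
#'
#' @param scores data.frame as returned by [bandSpectralAngle()] (any score
#'   column named \code{angle} or \code{score}).
#' @param k number of bands to keep.
#' @return integer band indices, sorted increasing; ties broken toward the
#'   lower band index.
#' @export
selectTopBands <- function(scores, k) {
  sc <- if (!is.null(scores$angle)) scores$angle else scores$score
  if (is.null(sc)) stop("no 'angle' or 'score' column", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > length(sc)) stop("k exceeds the band count", call. = FALSE)
  ord <- order(-sc, scores$band)
  sort(scores$band[ord[seq_len(k)]])
}

#' Band maximizing histogram image entropy
#'
#' Scores every band image with [imageEntropy()] and returns the index of
#' the maximum (ties toward the lowest index).
#'
#' @param cube a [HyperCube-class]
#' @param bins histogram bin count.
#' @return integer band index
#' @export
selectBandByEntropy <- function(cube, bins = 256L) {
  stopifnot(is(cube, "HyperCube"))
  ent <- vapply(seq_len(dim(cube@data)[3L]), function(b)
    imageEntropy(cube@data[, , b], bins), numeric(1))
  which.max(ent)
}

#' Pixelwise mean over a set of bands
#'
#' @param cube a [HyperCube-class]
#' @param bands non-empty integer band indices.
#' @return numeric \code{(nx, ny)} matrix
#' @export
meanBandImage <- function(cube, bands) {
  stopifnot(is(cube, "HyperCube"))
  bands <- as.integer(bands)
  d <- dim(cube@data)
  if (!length(bands)) stop("empty band list", call. = FALSE)
  if (any(bands < 1L | bands > d[3L]))
    stop("band index out of range", call. = FALSE)
  sub <- cube@data[, , bands, drop = FALSE]
  matrix(rowMeans(matrix(sub, d[1L] * d[2L], length(bands))), d[1L], d[2L])
}

#' Threshold an image into a binary mask
#'
#' Foreground is the set of pixels on the chosen side of the threshold:
#' \code{"below"} uses \eqn{v \le t}, \code{"above"} uses \eqn{v > t}
#' (strict), and \code{"minority"} picks whichever side has fewer pixels
#' (useful for score images such as principal components, whose sign is
#' conventional while the objects of interest are the minority of pixels).
#'
#' @param image numeric matrix.
#' @param method \code{"otsu"} (threshold from \code{EBImage::otsu} on a
#'   256-level histogram over the image's own range) or \code{"manual"}.
#' @param threshold required for \code{method = "manual"}.
#' @param foreground \code{"below"}, \code{"above"} or \code{"minority"}.
#' @param region optional [BinaryMask-class] or logical matrix; the
#'   threshold is computed from region pixels only and everything outside
#'   the region is background.
#' @return a [BinaryMask-class]; the chosen threshold is attached as
#'   attribute \code{"threshold"} of the grid.
#' @export
thresholdSegment <- function(image, method = c("otsu", "manual"),
                             threshold = NULL,
                             foreground = c("below", "above", "minority"),
                             region = NULL) {
  method <- match.arg(method)
  foreground <- match.arg(foreground)
  image <- as.matrix(image)
  keep <- if (is.null(region)) NULL else .regionGrid(region, dim(image))
  vals <- if (is.null(keep)) image else image[keep]
  if (method == "manual") {
    if (is.null(threshold))
      stop("manual method requires a threshold", call. = FALSE)
    thr <- threshold
  } else {
    rng <- range(vals)
    if (diff(rng) == 0)
      stop("image is constant; Otsu is undefined - supply a manual ",
           "threshold", call. = FALSE)
    thr <- EBImage::otsu(matrix(vals, 1L), range = rng, levels = 256L)
  }
  below <- vals <= thr
  fg <- switch(foreground,
    below = below,
    above = !below,
    minority = if (sum(below) <= sum(!below)) below else !below)
  if (is.null(keep)) {
    grid <- matrix(fg, nrow(image), ncol(image))
  } else {
    grid <- matrix(FALSE, nrow(image), ncol(image))
    grid[keep] <- fg
  }
  m <- BinaryMask(grid)
  attr(m@grid, "threshold") <- thr
  m
}

#' Principal-component decomposition of a cube's pixel spectra
#'
#' Pixels are observations, bands are variables; data are centered by the
#' mean spectrum (no scaling). Explained ratios are eigenvalue shares of the
#' total spectral variance, so they sum to 1 when all components are kept.
#' Each component's sign is fixed so its score image has non-negative
#' skewness.
#'
#' @param cube a [HyperCube-class]
#' @param nComponents number of components to keep (\code{<=} band count).
#' @param region optional [BinaryMask-class] or logical matrix; only region
#'   pixels enter the decomposition and score images are \code{NA} outside
#'   it.
#' @return a [PCAResult-class]
#' @export
pcaDecompose <- function(cube, nComponents, region = NULL) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  k <- as.integer(nComponents)
  if (k < 1L) stop("nComponents must be >= 1", call. = FALSE)
  if (k > d[3L]) stop("nComponents exceeds the band count", call. = FALSE)
  X <- matrix(cube@data, d[1L] * d[2L], d[3L])
  keep <- if (is.null(region)) NULL
          else as.vector(.regionGrid(region, d[1:2]))
  if (!is.null(keep)) X <- X[keep, , drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x
  rot <- pc$rotation
  for (j in seq_len(k)) {
    if (mean(scores[, j]^3) < 0) {
      scores[, j] <- -scores[, j]
      rot[, j] <- -rot[, j]
    }
  }
  if (is.null(keep)) {
    imgs <- array(scores, c(d[1L], d[2L], k))
  } else {
    imgs <- array(NA_real_, c(d[1L], d[2L], k))
    for (j in seq_len(k)) {
      sl <- matrix(NA_real_, d[1L], d[2L])
      sl[keep] <- scores[, j]
      imgs[, , j] <- sl
    }
  }
  new("PCAResult",
      componentImages = imgs,
      explainedRatio = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
      meanSpectrum = as.numeric(pc$center),
      rotation = rot)
}

#' Intersect two masks
#'
#' @param a,b [BinaryMask-class] objects of equal shape.
#' @return the logical AND as a [BinaryMask-class]
#' @export
intersectMasks <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  if (!all(dim(a@grid) == dim(b@grid)))
    stop("mask shapes differ", call. = FALSE)
  BinaryMask(a@grid & b@grid)
}

#' Mask a cube
#'
#' Sets every band of each background pixel to \code{fill}; foreground
#' pixels are unchanged. Metadata records that a mask was applied.
#'
#' @param cube a [HyperCube-class]
#' @param mask a [BinaryMask-class] matching the cube's spatial extents.
#' @param fill background value.
#' @return the masked [HyperCube-class]
#' @export
applyMask <- function(cube, mask, fill = 0) {
  stopifnot(is(cube, "HyperCube"), is(mask, "BinaryMask"))
  d <- dim(cube@data)
  if (!all(dim(mask@grid) == d[1:2]))
    stop("mask shape does not match the cube's spatial extents",
         call. = FALSE)
  data <- cube@data
  bg <- !mask@grid
  for (b in seq_len(d[3L])) {
    slice <- data[, , b]
    slice[bg] <- fill
    data[, , b] <- slice
  }
  meta <- cube@metadata
  meta$mask_applied <- TRUE
  meta$mask_foreground_pixels <- sum(mask@grid)
  HyperCube(data, cube@wavelengths, cube@valueKind, meta)
}

#' Intersection-over-union of two masks
#'
#' @param a,b [BinaryMask-class] objects of equal shape.
#' @return IoU fraction in \eqn{[0, 1]} (1 when both masks are empty).
#' @export
maskIoU <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  if (!all(dim(a@grid) == dim(b@grid)))
    stop("mask shapes differ", call. = FALSE)
  un <- sum(a@grid | b@grid)
  if (un == 0) return(1)
  sum(a@grid & b@grid) / un
}

#' Full spectral-angle + PCA segmentation pipeline
#'
#' Branch 1: score bands by spectral angle, average the top \code{k} bands,
#' threshold the mean image (result 1). Branch 2: threshold a
#' principal-component score image (result 2). The final mask is the
#' intersection (result 3).
#'
#' Which component image carries the objects of interest is data-dependent:
#' it is chosen by inspecting the component images (in the original
#' procedure, by eye). The default \code{pcIndex = "auto"} mechanizes that
#' inspection by picking, among the first \code{nCandidates} components, the
#' one whose thresholded mask agrees best (highest IoU) with the
#' spectral-angle branch; an explicit integer reproduces a manual choice.
#'
#' @param cube a [HyperCube-class]
#' @param k number of top-angle bands averaged in branch 1.
#' @param reference reference direction for [bandSpectralAngle()].
#' @param pcIndex integer principal-component index for branch 2, or
#'   \code{"auto"}.
#' @param nCandidates components scanned when \code{pcIndex = "auto"}.
#' @param thresholdMethod \code{"otsu"} or \code{"manual"}.
#' @param angleForeground polarity for the branch-1 threshold (default
#'   \code{"below"}: dark seeds on a bright stage).
#' @param pcForeground polarity for the branch-2 threshold (default
#'   \code{"minority"}: component sign is conventional, seeds are the
#'   minority of pixels).
#' @param angleThreshold,pcThreshold manual thresholds when
#'   \code{thresholdMethod = "manual"}.
#' @param region optional [BinaryMask-class] of pixels to analyze (e.g. the
#'   stage area between known plate footprints); everything outside is
#'   background.
#' @return list with \code{mask} (result 3, a [BinaryMask-class]) and
#'   \code{diagnostics} (selected bands and wavelengths, chosen component,
#'   thresholds, explained ratios, per-stage foreground counts).
#' @export
segmentPipeline <- function(cube, k = 20L, reference = "ones",
                            pcIndex = "auto", nCandidates = 6L,
                            thresholdMethod = "otsu",
                            angleForeground = "below",
                            pcForeground = "minority",
                            angleThreshold = NULL, pcThreshold = NULL,
                            region = NULL) {
  scores <- bandSpectralAngle(cube, reference, region = region)
  bands <- selectTopBands(scores, k)
  meanImg <- meanBandImage(cube, bands)
  result1 <- thresholdSegment(meanImg, thresholdMethod,
                              threshold = angleThreshold,
                              foreground = angleForeground,
                              region = region)
  auto <- identical(pcIndex, "auto")
  nc <- if (auto) max(as.integer(nCandidates), 2L)
        else max(as.integer(pcIndex), 2L)
  nc <- min(nc, dim(cube@data)[3L])
  pca <- pcaDecompose(cube, nc, region = region)
  segmentPc <- function(j)
    thresholdSegment(pca@componentImages[, , j], thresholdMethod,
                     threshold = pcThreshold, foreground = pcForeground,
                     region = region)
  if (auto) {
    cand <- lapply(seq_len(nc), segmentPc)
    agreement <- vapply(cand, function(m) maskIoU(m, result1), numeric(1))
    pcIndex <- which.max(agreement)
    result2 <- cand[[pcIndex]]
  } else {
    pcIndex <- as.integer(pcIndex)
    result2 <- segmentPc(pcIndex)
  }
  result3 <- intersectMasks(result1, result2)
  list(mask = result3,
       diagnostics = list(
         selectedBands = bands,
         selectedWavelengths = cube@wavelengths[bands],
         pcIndex = pcIndex,
         angleThreshold = attr(result1@grid, "threshold"),
         pcThreshold = attr(result2@grid, "threshold"),
         explainedRatio = pca@explainedRatio,
         result1Count = sum(result1@grid),
         result2Count = sum(result2@grid),
         result3Count = sum(result3@grid)))
}
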
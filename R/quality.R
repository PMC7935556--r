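# Image-quality metrics: per-band entropy, SNR, clarity (mean gradient
# magnitude), PSNR and SSIM, and a band-averaged report.
#
# Conventions (several exist in the literature; these are fixed here):
#   - entropy: Shannon entropy in bits of the 256-bin histogram over the
#     image's own value range;
#   - SNR: 20 log10(mean / sd) of the pixel values, in dB;
#   - clarity: mean central-difference gradient magnitude over interior
#     pixels ("average gradient" sharpness);
#   - PSNR peak defaults to the reference image's maximum.

#' Histogram Shannon entropy of an image
#'
#' Entropy \eqn{-\sum p \log_2 p} of the histogram over \code{bins}
#' equal-width bins spanning the image's value range; empty bins contribute
#' 0 and a constant image has entropy 0.
#'
#' @param image numeric matrix.
#' @param bins bin count (default 256).
#' @return entropy in bits
#' @export
imageEntropy <- function(image, bins = 256L) {
  v <- as.numeric(image)
  if (!length(v)) stop("empty image", call. = FALSE)
  rng <- range(v)
  if (diff(rng) == 0) return(0)
  idx <- pmin(bins, 1L + floor((v - rng[1L]) / diff(rng) * bins))
  p <- tabulate(idx, nbins = bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Single-image signal-to-noise ratio in dB
#'
#' \eqn{20 \log_{10}(\mu / \sigma)} of the pixel values. Invariant under
#' positive scaling of the image.
#'
#' @param image numeric matrix with non-zero mean and non-zero spread.
#' @return SNR in dB
#' @export
imageSnr <- function(image) {
  v <- as.numeric(image)
  mu <- mean(v)
  s <- stats::sd(v)
  if (s == 0 || mu == 0)
    stop("SNR undefined: zero mean or zero standard deviation",
         call. = FALSE)
  20 * log10(abs(mu) / s)
}

#' Image clarity (mean gradient magnitude)
#'
#' Mean over interior pixels of \eqn{\sqrt{g_x^2 + g_y^2}} with
#' central-difference gradients. A ramp of unit slope has clarity 1.
#'
#' @param image numeric matrix, both extents at least 3.
#' @return mean gradient magnitude
#' @export
imageClarity <- function(image) {
  image <- as.matrix(image)
  nx <- nrow(image); ny <- ncol(image)
  if (nx < 3L || ny < 3L)
    stop("image too small for central differences (need >= 3 x 3)",
         call. = FALSE)
  ix <- 2L:(nx - 1L); iy <- 2L:(ny - 1L)
  gx <- (image[ix + 1L, iy] - image[ix - 1L, iy]) / 2
  gy <- (image[ix, iy + 1L] - image[ix, iy - 1L]) / 2
  mean(sqrt(gx^2 + gy^2))
}

#' Peak signal-to-noise ratio in dB
#'
#' \eqn{10 \log_{10}(peak^2 / MSE)}; identical images give \code{Inf}.
#'
#' @param reference,test numeric matrices of equal shape.
#' @param peak peak signal value (default: the reference's maximum).
#' @return PSNR in dB (\code{Inf} for identical images)
#' @export
psnr <- function(reference, test, peak = max(reference)) {
  if (!all(dim(as.matrix(reference)) == dim(as.matrix(test))))
    stop("image shapes differ", call. = FALSE)
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

.gaussWeights <- function(window, sigma) {
  h <- (window - 1L) / 2L
  g <- exp(-((-h):h)^2 / (2 * sigma^2))
  g / sum(g)
}

# separable weighted local filter with mirror padding
.localFilter <- function(im, g) {
  m <- (length(g) - 1L) / 2L
  pad <- .padImage(im, m, "mirror")
  nx <- nrow(im); ny <- ncol(im)
  tmp <- matrix(0, nx, ncol(pad))
  for (j in seq_along(g))
    tmp <- tmp + g[j] * pad[(j):(j + nx - 1L), , drop = FALSE]
  out <- matrix(0, nx, ny)
  for (j in seq_along(g))
    out <- out + g[j] * tmp[, (j):(j + ny - 1L), drop = FALSE]
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the standard luminance-contrast-structure form,
#' Gaussian window (11 x 11, \eqn{\sigma = 1.5}) and stabilizers
#' \eqn{C_1 = (0.01 \cdot peak)^2}, \eqn{C_2 = (0.03 \cdot peak)^2}.
#'
#' @param reference,test numeric matrices of equal shape, extents at least
#'   the window size.
#' @param window odd window size.
#' @param sigma Gaussian window std in pixels.
#' @param peak dynamic range used in the stabilizers; defaults to the
#'   maximum over both images (making the measure symmetric in its
#'   arguments).
#' @return mean SSIM in \eqn{[-1, 1]}
#' @export
ssim <- function(reference, test, window = 11L, sigma = 1.5,
                 peak = max(reference, test)) {
  a <- as.matrix(reference); b <- as.matrix(test)
  if (!all(dim(a) == dim(b))) stop("image shapes differ", call. = FALSE)
  if (min(dim(a)) < window)
    stop("image smaller than the SSIM window", call. = FALSE)
  g <- .gaussWeights(as.integer(window), sigma)
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  mu1 <- .localFilter(a, g); mu2 <- .localFilter(b, g)
  s11 <- .localFilter(a * a, g) - mu1^2
  s22 <- .localFilter(b * b, g) - mu2^2
  s12 <- .localFilter(a * b, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Per-band quality report with band averages
#'
#' When only \code{original} is given, entropy, SNR and clarity are computed
#' per band of that cube. When \code{filtered} is also given, entropy, SNR
#' and clarity describe the filtered cube while PSNR and SSIM compare each
#' filtered band against the original.
#'
#' @param original a [HyperCube-class]
#' @param filtered optional [HyperCube-class] of identical extents.
#' @param bins entropy histogram bins.
#' @param peak PSNR/SSIM peak; default per band from the original.
#' @return a [QualityReport-class]
#' @export
qualityReport <- function(original, filtered = NULL, bins = 256L,
                          peak = NULL) {
  stopifnot(is(original, "HyperCube"))
  d <- dim(original@data)
  if (!is.null(filtered)) {
    stopifnot(is(filtered, "HyperCube"))
    if (!all(dim(filtered@data) == d))
      stop("cubes must share extents", call. = FALSE)
  }
  target <- if (is.null(filtered)) original else filtered
  nb <- d[3L]
  ent <- snr <- cla <- numeric(nb)
  ps <- ss <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    im <- target@data[, , b]
    ent[b] <- imageEntropy(im, bins)
    snr[b] <- imageSnr(im)
    cla[b] <- imageClarity(im)
    if (!is.null(filtered)) {
      ref <- original@data[, , b]
      pk <- if (is.null(peak)) max(ref) else peak
      ps[b] <- psnr(ref, im, peak = pk)
      ss[b] <- ssim(ref, im, peak = pk)
    }
  }
  perBand <- data.frame(band = seq_len(nb),
                        wavelength = original@wavelengths,
                        entropy = ent, snr_db = snr, clarity = cla)
  avg <- c(entropy = mean(ent), snr_db = mean(snr), clarity = mean(cla))
  if (!is.null(filtered)) {
    perBand$psnr_db <- ps
    perBand$ssim <- ss
    avg <- c(avg, psnr_db = mean(ps), ssim = mean(ss))
  }
  new("QualityReport", perBand = perBand, averages = avg)
}

#' Write a quality report as delimited text
#'
#' Tab-delimited table with columns \code{band, entropy, snr_db, clarity,
#' psnr_db, ssim} and a final \code{average} row.
#'
#' @param report a [QualityReport-class]
#' @param path output file.
#' @return invisibly \code{NULL}
#' @export
writeQualityReport <- function(report, path) {
  stopifnot(is(report, "QualityReport"))
  pb <- report@perBand
  cols <- c("band", "entropy", "snr_db", "clarity", "psnr_db", "ssim")
  for (cn in setdiff(cols, names(pb))) pb[[cn]] <- NA_real_
  pb <- pb[, cols]
  av <- report@averages
  avgRow <- data.frame(band = "average",
                       entropy = av[["entropy"]], snr_db = av[["snr_db"]],
                       clarity = av[["clarity"]],
                       psnr_db = if ("psnr_db" %in% names(av))
                         av[["psnr_db"]] else NA_real_,
                       ssim = if ("ssim" %in% names(av))
                         av[["ssim"]] else NA_real_)
  pb$band <- as.character(pb$band)
  utils::write.table(rbind(pb, avgRow), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}
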
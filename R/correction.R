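# Radiometric correction from standard reflectance plates.
#
# Model: measured DN f(x,y,l) = g(x,y,l) + xi(y,l), with g the true
# (illumination-weighted) DN and xi additive noise that is constant along
# the scan axis x at fixed (detector row, band). Two plates of known
# reflectance R1, R2 scanned alongside the sample give, per (y, l),
#
#   g1 / g2 = R1 / R2,   g1 + xi = f1,   g2 + xi = f2
#   =>  xi = (R1 * f2 - R2 * f1) / (R1 - R2)
#
# which is exact whenever the plate column means equal their model values.
# The derivation assumes the illumination gain cancels between the plates at
# equal (y, l), i.e. is independent of the scan position; the phantom
# generator obeys this by construction.

.expandReflectance <- function(R, nbands, what) {
  if (is(R, "PlateRegion")) R <- R@reflectance
  R <- as.numeric(R)
  if (length(R) == 1L) R <- rep(R, nbands)
  if (length(R) != nbands)
    stop(sprintf("%s must be a scalar or one value per band", what),
         call. = FALSE)
  R
}

#' Per-(row, band) mean profile of a reflectance plate
#'
#' Averages the cube over the plate's scan (x) columns, yielding one value
#' per (detector row, band). Detector rows outside the plate's y footprint
#' are filled by nearest neighbor along y, with a warning: the noise model
#' needs a value at every row, and a plate that does not span the full
#' field-of-view line cannot measure the rows it does not cover.
#'
#' @param cube a [HyperCube-class] in DN.
#' @param region the plate's [PlateRegion-class].
#' @return a [PlateProfile-class] with \code{(ny, nbands)} values.
#' @export
plateProfile <- function(cube, region) {
  stopifnot(is(cube, "HyperCube"), is(region, "PlateRegion"))
  d <- dim(cube@data)
  if (region@xInterval[2L] > d[1L] || region@yInterval[2L] > d[2L])
    stop("plate footprint outside cube bounds", call. = FALSE)
  xr <- region@xInterval[1L]:region@xInterval[2L]
  yr <- region@yInterval[1L]:region@yInterval[2L]
  sub <- cube@data[xr, , , drop = FALSE]
  vals <- colMeans(matrix(sub, length(xr), d[2L] * d[3L]))
  vals <- matrix(vals, d[2L], d[3L])
  if (length(yr) < d[2L]) {
    warning("plate does not span all detector rows; filling by nearest ",
            "neighbor along y", call. = FALSE)
    nearest <- vapply(seq_len(d[2L]), function(y)
      yr[which.min(abs(yr - y))], integer(1))
    vals <- vals[nearest, , drop = FALSE]
  }
  new("PlateProfile", values = vals, region = region)
}

#' Estimate the additive noise field from two calibration plates
#'
#' Solves the two-plate system for the additive term per (row, band):
#' \deqn{\xi(y,\lambda) = \frac{R_1 f_2 - R_2 f_1}{R_1 - R_2}}
#' where \eqn{f_1, f_2} are the plate column-mean profiles and
#' \eqn{R_1, R_2} the known plate reflectances (scalar or per-band). The
#' estimate is exact, not asymptotic, whenever the profile means equal their
#' model values.
#'
#' @param p1,p2 [PlateProfile-class] objects of the two calibration plates.
#' @param R1,R2 plate reflectances; scalar fractions, per-band curves, or
#'   omitted to take them from the profiles' regions.
#' @return a [NoiseField-class]
#' @export
estimateNoise <- function(p1, p2, R1 = NULL, R2 = NULL) {
  stopifnot(is(p1, "PlateProfile"), is(p2, "PlateProfile"))
  if (!all(dim(p1@values) == dim(p2@values)))
    stop("plate profiles must share extents", call. = FALSE)
  nb <- ncol(p1@values)
  R1 <- .expandReflectance(if (is.null(R1)) p1@region else R1, nb, "R1")
  R2 <- .expandReflectance(if (is.null(R2)) p2@region else R2, nb, "R2")
  if (any(abs(R1 - R2) < 1e-6))
    stop("degenerate calibration: |R1 - R2| < 1e-6 in at least one band",
         call. = FALSE)
  xi <- sweep(p2@values, 2L, R1, `*`) - sweep(p1@values, 2L, R2, `*`)
  xi <- sweep(xi, 2L, R1 - R2, `/`)
  new("NoiseField", values = xi)
}

#' Subtract a per-(row, band) noise field from a cube
#'
#' Broadcasts the noise field along the scan axis: \eqn{g = f - \xi}.
#'
#' @param cube a [HyperCube-class] in DN.
#' @param noise a [NoiseField-class] (or bare \code{(ny, nbands)} matrix).
#' @return the noise-subtracted [HyperCube-class] (still DN).
#' @export
subtractNoise <- function(cube, noise) {
  stopifnot(is(cube, "HyperCube"))
  vals <- if (is(noise, "NoiseField")) noise@values else as.matrix(noise)
  d <- dim(cube@data)
  if (!all(dim(vals) == d[2:3]))
    stop("noise field extents must be (ny, nbands)", call. = FALSE)
  nf <- aperm(array(vals, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  HyperCube(cube@data - nf, cube@wavelengths, "dn", cube@metadata)
}

#' Invert DN to reflectance against a noise-subtracted calibration plate
#'
#' With the additive term removed, the remaining DN is illumination times
#' reflectance, so dividing by the calibration plate's noise-subtracted
#' profile cancels the illumination row-by-row:
#' \deqn{\rho(x,y,\lambda) = R_{calib} \; g(x,y,\lambda) / g_{calib}(y,\lambda)}
#'
#' @param trueDn noise-subtracted [HyperCube-class].
#' @param calibProfile [PlateProfile-class] of the calibration plate,
#'   already noise-subtracted (a \code{(ny, nbands)} matrix is accepted).
#' @param Rcalib calibration plate reflectance (scalar or per-band); taken
#'   from the profile's region when omitted.
#' @param floor calibration DN below \code{floor} raises a calibration error
#'   rather than returning infinities.
#' @return a reflectance [HyperCube-class]
#' @export
reflectanceInvert <- function(trueDn, calibProfile, Rcalib = NULL,
                              floor = 1e-9) {
  stopifnot(is(trueDn, "HyperCube"))
  vals <- if (is(calibProfile, "PlateProfile")) calibProfile@values
          else as.matrix(calibProfile)
  d <- dim(trueDn@data)
  if (!all(dim(vals) == d[2:3]))
    stop("calibration profile extents must be (ny, nbands)", call. = FALSE)
  if (is.null(Rcalib)) {
    if (!is(calibProfile, "PlateProfile"))
      stop("Rcalib must be given when calibProfile is a bare matrix",
           call. = FALSE)
    Rcalib <- calibProfile@region@reflectance
  }
  Rcalib <- .expandReflectance(Rcalib, d[3L], "Rcalib")
  bad <- which(vals <= floor, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "non-positive calibration DN at %d (y, band) cells, e.g. (%d, %d)",
      nrow(bad), bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  gcal <- sweep(1 / vals, 2L, Rcalib, `*`)   # Rcalib / g_calib
  gx <- aperm(array(gcal, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  HyperCube(trueDn@data * gx, trueDn@wavelengths, "reflectance",
            trueDn@metadata)
}

#' Classical black-and-white normalization
#'
#' \deqn{ref = R (f - f_{min}) / (f_{ref} - f_{min})} with \eqn{f_{min}} the
#' dark frame (lens capped) and \eqn{f_{ref}} the white plate profile, both
#' per (row, band) and broadcast along the scan axis.
#'
#' @param cube DN [HyperCube-class].
#' @param whiteProfile \code{(ny, nbands)} matrix or [PlateProfile-class].
#' @param darkFrame \code{(ny, nbands)} matrix.
#' @param R white plate reflectance (scalar or per-band).
#' @return a reflectance [HyperCube-class]
#' @export
blackWhiteCorrect <- function(cube, whiteProfile, darkFrame, R = 0.98) {
  stopifnot(is(cube, "HyperCube"))
  w <- if (is(whiteProfile, "PlateProfile")) whiteProfile@values
       else as.matrix(whiteProfile)
  dk <- as.matrix(darkFrame)
  d <- dim(cube@data)
  if (!all(dim(w) == d[2:3]) || !all(dim(dk) == d[2:3]))
    stop("reference extents must be (ny, nbands)", call. = FALSE)
  denom <- w - dk
  if (any(denom == 0))
    stop("zero white-minus-dark denominator at some (y, band)",
         call. = FALSE)
  R <- .expandReflectance(R, d[3L], "R")
  scale <- sweep(1 / denom, 2L, R, `*`)
  sx <- aperm(array(scale, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  dkx <- aperm(array(dk, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  HyperCube((cube@data - dkx) * sx, cube@wavelengths, "reflectance",
            cube@metadata)
}

#' Per-band squared error between a corrected and a calibration spectrum
#'
#' @param corrected,calibration per-band reflectance spectra of equal
#'   length.
#' @param wavelengths wavelength grid matching the spectra; required when
#'   \code{window} is given.
#' @param window optional \code{c(lo, hi)} wavelength interval in nm; the
#'   mean is taken over in-window bands only.
#' @return list with \code{perBand} squared errors (full grid, NA outside
#'   the window) and \code{mse}, their mean over the window.
#' @export
correctionMse <- function(corrected, calibration, wavelengths = NULL,
                          window = NULL) {
  if (length(corrected) != length(calibration))
    stop("spectra must have equal length", call. = FALSE)
  se <- (corrected - calibration)^2
  keep <- rep(TRUE, length(se))
  if (!is.null(window)) {
    if (is.null(wavelengths))
      stop("wavelengths required when a window is given", call. = FALSE)
    keep <- wavelengths >= window[1L] & wavelengths <= window[2L]
    if (!any(keep)) stop("empty wavelength window", call. = FALSE)
  }
  list(perBand = ifelse(keep, se, NA_real_), mse = mean(se[keep]))
}

#' Full double-plate correction of a scene
#'
#' Convenience wrapper chaining [plateProfile()] on the two calibration
#' plates, [estimateNoise()], [subtractNoise()] and [reflectanceInvert()]
#' against the higher-reflectance plate.
#'
#' @param cube DN [HyperCube-class].
#' @param plateLow,plateHigh [PlateRegion-class] of the two calibration
#'   plates (e.g. 2% and 98%).
#' @return list with \code{reflectance} (corrected [HyperCube-class]),
#'   \code{noise} ([NoiseField-class]) and \code{calibProfile}.
#' @export
doublePlateCorrect <- function(cube, plateLow, plateHigh) {
  p1 <- plateProfile(cube, plateLow)
  p2 <- plateProfile(cube, plateHigh)
  xi <- estimateNoise(p1, p2)
  g <- subtractNoise(cube, xi)
  calib <- new("PlateProfile", values = p2@values - xi@values,
               region = plateHigh)
  refl <- reflectanceInvert(g, calib)
  list(reflectance = refl, noise = xi, calibProfile = calib)
}
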